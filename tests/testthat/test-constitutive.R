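test_that("strain energy vanishes at the reference state and is isotropic", {
  for (m in lib) {
    expect_identical(strain_energy(m, c(1, 1, 1)), 0)
    l <- c(1.3, 0.9, 1.1)
    w <- strain_energy(m, l)
    expect_equal(strain_energy(m, l[c(2, 3, 1)]), w)
    expect_equal(strain_energy(m, l[c(3, 1, 2)]), w)
    expect_gt(w, 0)
  }
  # direct evaluation of the one-term closed form, incompressible uniaxial
  expect_equal(strain_energy(mucosa, c(1.5, 1.5^-0.5, 1.5^-0.5)),
               (0.1 / 3.4) * (1.5^3.4 + 2 * 1.5^-1.7 - 3), tolerance = 1e-12)
  expect_equal(strain_energy(mucosa, c(1.5, 1.5^-0.5, 1.5^-0.5)), 0.0580,
               tolerance = 1e-3)
  expect_error(strain_energy(mucosa, c(1, 1, -0.5)), "positive")
})

test_that("uniaxial Cauchy stress matches the closed form and printed bounds", {
  expect_identical(uniaxial_cauchy_stress(mucosa, 1), 0)
  # mucosa stays below 1 MPa even at 50% strain
  expect_equal(uniaxial_cauchy_stress(mucosa, 1.5), 0.3467, tolerance = 1e-3)
  expect_lt(uniaxial_cauchy_stress(mucosa, 1.5), 1)
  expect_equal(uniaxial_cauchy_stress(cartilage, 1.1),
               0.109 * (1.1^16.63 - 1.1^-8.315), tolerance = 1e-12)
  expect_equal(uniaxial_cauchy_stress(cartilage, 1.1), 0.4825, tolerance = 1e-3)
  # sign follows the sign of (stretch - 1)
  expect_lt(uniaxial_cauchy_stress(mucosa, 0.8), 0)
  expect_error(uniaxial_cauchy_stress(mucosa, -1), "positive")
})

test_that("uniaxial stress is strictly increasing for all printed tissues", {
  lam <- seq(0.5, 2, by = 0.01)
  for (m in lib) {
    s <- uniaxial_cauchy_stress(m, lam)
    expect_true(all(diff(s) > 0), label = paste(m$label, "monotone"))
  }
})

test_that("tensor stress: reference state, objectivity, incompressible limit", {
  expect_equal(cauchy_stress_tensor(mucosa, diag(3)), matrix(0, 3, 3))
  U <- diag(c(1.2, 0.95, 0.9))
  R <- rotation_z(0.4)
  expect_equal(cauchy_stress_tensor(mucosa, R %*% U),
               R %*% cauchy_stress_tensor(mucosa, U) %*% t(R),
               tolerance = 1e-10)
  # uniaxial equilibrium at kappa = 1000 a reduces to the closed form
  for (m in list(mucosa, lib$smooth_muscle)) {
    F <- uniaxial_equilibrium_F(m, 1.5)
    s <- cauchy_stress_tensor(m, F)
    expect_equal(s[3, 3], uniaxial_cauchy_stress(m, 1.5), tolerance = 0.02)
    expect_lt(abs(s[1, 1]), 1e-8)
  }
  expect_error(cauchy_stress_tensor(mucosa, diag(c(1, 1, -1))), "determinant")
})

test_that("material tangent is the exact derivative of the stress", {
  set.seed(11)
  h <- 1e-6
  for (rep in 1:5) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.1), 3, 3)
    if (det(F) < 0.8 || det(F) > 1.2) next
    mt <- material_tangent(mucosa, F)
    scale <- max(abs(mt$A))
    for (k in 1:3) for (L in 1:3) {
      Fp <- F; Fp[k, L] <- Fp[k, L] + h
      Fm <- F; Fm[k, L] <- Fm[k, L] - h
      dP <- (material_tangent(mucosa, Fp)$P - material_tangent(mucosa, Fm)$P) / (2 * h)
      expect_lt(max(abs(dP - matrix(mt$A[, k + 3 * (L - 1)], 3, 3))) / scale,
                1e-4)
    }
  }
})

test_that("small-strain stiffness at identity is positive for all tissues", {
  # apply a tiny simple shear and check the shear response ~ mu * gamma
  gam <- 1e-6
  F <- diag(3); F[1, 2] <- gam
  for (m in lib) {
    s <- cauchy_stress_tensor(m, F)
    mu_apparent <- s[1, 2] / gam
    expect_equal(mu_apparent, shear_modulus(m), tolerance = 1e-3)
    expect_gt(mu_apparent, 0)
  }
})

test_that("malacia transforms replace the targeted tissue coefficients only", {
  soft <- apply_malacia(lib, "soft")
  expect_equal(soft$cartilage$a, 0.01)
  expect_equal(soft$cartilage$b, 11.05)
  expect_equal(soft$fibrous$a, lib$fibrous$a)
  expect_equal(soft$mucosa$a, lib$mucosa$a)
  expect_equal(soft$smooth_muscle$a, lib$smooth_muscle$a)

  muc <- apply_malacia(lib, "mucosa")
  expect_equal(muc$cartilage$a, 0.1)
  expect_equal(muc$cartilage$b, 3.4)
  expect_equal(muc$fibrous$a, 0.1)
  expect_equal(muc$fibrous$b, 3.4)
  expect_equal(muc$smooth_muscle$a, lib$smooth_muscle$a)

  post <- apply_malacia(lib, "posterior", a = 1, b = 1)
  expect_equal(post$smooth_muscle$a, 1)
  expect_equal(post$smooth_muscle$b, 1)
  expect_equal(post$cartilage$a, lib$cartilage$a)

  expect_error(apply_malacia(lib, "bogus"))
  expect_error(apply_malacia(lib, "posterior"), "requires")
})

test_that("material constructor enforces its invariants", {
  expect_error(ogden_material(-0.1, 3), "positive")
  expect_error(ogden_material(0.1, 0), "nonzero")
  expect_error(ogden_material(0.1, 3, bulk_modulus = -1), "positive")
  m <- ogden_material(0.1, 3.4)
  expect_equal(m$bulk_modulus, 100)  # 1000 * sum(a)
})
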