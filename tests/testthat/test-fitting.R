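test_that("noise-free refits recover the printed coefficients to 0.1%", {
  for (m in list(cartilage, mucosa)) {
    dat <- generate_stress_strain(m)
    fit <- fit_ogden(dat)
    expect_true(fit$converged)
    expect_equal(fit$material$a, m$a, tolerance = 1e-3)
    expect_equal(fit$material$b, m$b, tolerance = 1e-3)
    expect_gt(fit$r_squared, 0.99999)
  }
})

test_that("parameter recovery holds across the (a, b) design range", {
  set.seed(7)
  for (rep in 1:6) {
    a <- exp(stats::runif(1, log(0.01), log(1)))
    b <- stats::runif(1, 1, 20)
    m <- ogden_material(a, b)
    fit <- fit_ogden(generate_stress_strain(m))
    expect_equal(fit$material$a, a, tolerance = 1e-3)
    expect_equal(fit$material$b, b, tolerance = 1e-3)
  }
})

test_that("noisy data refit stays accurate", {
  for (m in list(cartilage, mucosa)) {
    dat <- generate_stress_strain(m, noise = "multiplicative",
                                  sd = 0.05, seed = 1)
    fit <- fit_ogden(dat)
    expect_gt(fit$r_squared, 0.95)
    expect_equal(fit$material$a, m$a, tolerance = 0.1)
    expect_equal(fit$material$b, m$b, tolerance = 0.1)
  }
})

test_that("degenerate fitting inputs raise the documented errors", {
  expect_error(fit_ogden(data.frame(strain = c(0, 0.1, 0.2),
                                    stress_mpa = c(0, 0, 0))), "degenerate")
  expect_error(fit_ogden(data.frame(strain = c(0, 0.1),
                                    stress_mpa = c(0, 1))), "3 distinct")
})

test_that("tidy and glance expose the fit in broom form", {
  fit <- fit_ogden(generate_stress_strain(mucosa))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("a", "b"))
  gl <- glance(fit)
  expect_named(gl, c("r.squared", "residual.norm", "converged", "nobs"))
  expect_true(gl$converged)
})

test_that("synthetic curve generation matches the closed form and is seeded", {
  cur <- generate_stress_strain(mucosa, strain = c(0, 0.25, 0.5))
  expect_equal(cur$stress_mpa, c(0, 0.1 * (1.25^3.4 - 1.25^-1.7),
                                 0.1 * (1.5^3.4 - 1.5^-1.7)), tolerance = 1e-12)
  expect_equal(cur$stress_mpa[2], 0.14512, tolerance = 1e-4)
  expect_equal(cur$stress_mpa[3], 0.34673, tolerance = 1e-4)
  # sd = 0 with a noise model requested is still the exact curve
  expect_equal(generate_stress_strain(mucosa, noise = "additive", sd = 0)$stress_mpa,
               generate_stress_strain(mucosa)$stress_mpa)
  n1 <- generate_stress_strain(mucosa, noise = "multiplicative", sd = 0.05, seed = 5)
  n2 <- generate_stress_strain(mucosa, noise = "multiplicative", sd = 0.05, seed = 5)
  n3 <- generate_stress_strain(mucosa, noise = "multiplicative", sd = 0.05, seed = 6)
  expect_identical(n1, n2)
  expect_false(identical(n1$stress_mpa, n3$stress_mpa))
})

test_that("stress-strain and tissue-library files round-trip", {
  tmp <- tempfile(fileext = ".csv")
  cur <- generate_stress_strain(cartilage, noise = "additive", sd = 0.01)
  write_stress_strain(cur, tmp)
  back <- read_stress_strain(tmp)
  expect_equal(back$stress_mpa, cur$stress_mpa, tolerance = 1e-12)
  expect_equal(back$tissue[1], "cartilage")

  tl <- tempfile(fileext = ".yaml")
  write_tissue_library(lib, tl)
  lib2 <- read_tissue_library(tl)
  for (role in names(lib)) {
    expect_equal(lib2[[role]]$a, lib[[role]]$a)
    expect_equal(lib2[[role]]$b, lib[[role]]$b)
    expect_equal(lib2[[role]]$bulk_modulus, lib[[role]]$bulk_modulus)
  }
})
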