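test_that("single-element reaction matches the closed-form Ogden stress", {
  r <- run_single_element(make_single_element_fixture(mucosa, 1.5))
  expect_equal(r$stress, r$reference, tolerance = 0.01)
  # stiffer tissue, smaller stretch; compressibility error stays within 2%
  rc <- run_single_element(make_single_element_fixture(cartilage, 1.1))
  expect_equal(rc$stress, rc$reference, tolerance = 0.02)
  # zero stretch target is the trivial reference
  f0 <- make_single_element_fixture(mucosa, 1)
  expect_identical(f0$reference_stress, 0)
})

# smooth low-amplitude displacement field: random per-node noise at these
# element sizes implies enormous strains, outside the solver operating range
smooth_field <- function(mesh, amp = 0.05) {
  X <- mesh$nodes
  as.vector(t(amp * cbind(sin(0.2 * X[, 3]) * cos(0.3 * X[, 2]),
                          cos(0.25 * X[, 3]) * sin(0.2 * X[, 1]),
                          sin(0.15 * X[, 1] + 0.2 * X[, 2]))))
}

test_that("assembled residual is the exact gradient of the total energy", {
  mesh <- test_mesh(6)
  am <- airwaycollapse:::assign_materials(mesh, lib, NULL)
  sys <- airwaycollapse:::fe_system(
    mesh$nodes, mesh$elems, am$materials, am$elem_mat,
    fixed = integer(), fixed_values = numeric(), facets = NULL,
    contact = FALSE)
  set.seed(3)
  n <- 3 * nrow(mesh$nodes)
  u <- smooth_field(mesh)
  asm <- sys$assemble(u, 0, want_K = FALSE)
  energy_at <- function(uu) sys$assemble(uu, 0, FALSE)$diag$energy
  h <- 1e-6
  idx <- sample(n, 12)
  for (k in idx) {
    up <- u; up[k] <- up[k] + h
    um <- u; um[k] <- um[k] - h
    g_fd <- (energy_at(up) - energy_at(um)) / (2 * h)
    expect_equal(asm$r[k], g_fd, tolerance = 1e-4 * max(1, abs(g_fd)))
  }
  # zero displacement gives an identically zero residual
  expect_equal(max(abs(sys$assemble(numeric(n), 0, FALSE)$r)), 0)
})

test_that("assembled tangent matches a finite difference of the residual", {
  mesh <- test_mesh(6)
  am <- airwaycollapse:::assign_materials(mesh, lib, NULL)
  sys <- airwaycollapse:::fe_system(
    mesh$nodes, mesh$elems, am$materials, am$elem_mat,
    fixed = integer(), fixed_values = numeric(),
    facets = mesh$lumen_facets, follower = TRUE, contact = FALSE)
  set.seed(4)
  n <- 3 * nrow(mesh$nodes)
  u <- smooth_field(mesh, amp = 0.03)
  lam <- 5
  asm <- sys$assemble(u, lam, want_K = TRUE)
  h <- 1e-6
  idx <- sample(n, 8)
  scale <- max(abs(asm$K))
  for (k in idx) {
    up <- u; up[k] <- up[k] + h
    um <- u; um[k] <- um[k] - h
    col_fd <- (sys$assemble(up, lam, FALSE)$r - sys$assemble(um, lam, FALSE)$r) / (2 * h)
    expect_lt(max(abs(col_fd - asm$K[, k])) / scale, 1e-4)
  }
})

test_that("element stiffness is symmetric at the reference state", {
  mesh <- test_mesh(6)
  am <- airwaycollapse:::assign_materials(mesh, lib, NULL)
  sys <- airwaycollapse:::fe_system(
    mesh$nodes, mesh$elems, am$materials, am$elem_mat,
    fixed = integer(), fixed_values = numeric(), facets = NULL,
    contact = FALSE)
  K <- sys$assemble(numeric(3 * nrow(mesh$nodes)), 0, TRUE)$K
  expect_lt(max(abs(K - Matrix::t(K))), 1e-10 * max(abs(K)))
})

test_that("follower pressure resultant equals pressure times luminal area", {
  mesh <- build_trachea_mesh(trachea_config(diameter = 10))
  f0 <- mesh$lumen_facets - 1L
  storage.mode(f0) <- "integer"
  u <- numeric(3 * nrow(mesh$nodes))
  pr <- airwaycollapse:::.asm_pressure_cpp(mesh$nodes, f0, u,
                                           40 * 98.0665e-6, TRUE, FALSE)
  # symmetric model: net resultant is zero
  expect_lt(max(abs(pr$ftot)), 1e-8)
  # flat muscle-side facets: resultant exactly p * D * L upward; arc facets:
  # resultant p * (projected chord area) downward
  p <- 40 * 98.0665e-6
  is_flat <- abs(mesh$nodes[mesh$lumen_facets[, 1], 2]) < 1e-9 &
    abs(mesh$nodes[mesh$lumen_facets[, 2], 2]) < 1e-9
  prf <- airwaycollapse:::.asm_pressure_cpp(
    mesh$nodes, f0[is_flat, , drop = FALSE], u, p, TRUE, FALSE)
  expect_equal(as.numeric(prf$ftot), c(0, p * 10 * 50, 0), tolerance = 1e-9)
  pra <- airwaycollapse:::.asm_pressure_cpp(
    mesh$nodes, f0[!is_flat, , drop = FALSE], u, p, TRUE, FALSE)
  expect_equal(as.numeric(pra$ftot), c(0, -p * 10 * 50, 0), tolerance = 1e-9)
  # the total load magnitude carried by the lumen is ~5.04 N at 40 cm H2O
  expect_equal(p * lumen_surface_area(mesh), 5.04, tolerance = 0.01)
  # zero pressure gives a zero vector
  p0 <- airwaycollapse:::.asm_pressure_cpp(mesh$nodes, f0, u, 0, TRUE, FALSE)
  expect_equal(max(abs(p0$f)), 0)
})

test_that("follower pressure rotates with a rigidly rotated configuration", {
  mesh <- test_mesh(6)
  f0 <- mesh$lumen_facets - 1L
  storage.mode(f0) <- "integer"
  n <- nrow(mesh$nodes)
  R <- rotation_z(0.7)
  xr <- mesh$nodes %*% t(R)
  u <- as.vector(t(xr - mesh$nodes))
  p <- 1e-3
  pr0 <- airwaycollapse:::.asm_pressure_cpp(mesh$nodes, f0, numeric(3 * n), p, TRUE, FALSE)
  prr <- airwaycollapse:::.asm_pressure_cpp(mesh$nodes, f0, u, p, TRUE, FALSE)
  fr0 <- matrix(pr0$f, ncol = 3, byrow = TRUE) %*% t(R)
  frr <- matrix(prr$f, ncol = 3, byrow = TRUE)
  expect_equal(frr, fr0, tolerance = 1e-9)
})

test_that("contact penalty is zero without penetration and linear in overlap", {
  # two parallel unit plates, cavity between them, pushed into overlap
  plate_pair <- function(gap) {
    nodes <- rbind(cbind(expand.grid(x = 0:1, y = 0:1), z = 0),
                   cbind(expand.grid(x = 0:1, y = 0:1), z = gap))
    nodes <- as.matrix(nodes)
    # lower facet normal +z (toward upper), upper facet normal -z
    facets <- rbind(c(1, 2, 4, 3), c(5, 7, 8, 6)) - 1L
    storage.mode(facets) <- "integer"
    airwaycollapse:::.asm_contact_cpp(nodes, facets, numeric(24), 100, 0.5, TRUE)
  }
  patent <- plate_pair(0.3)
  expect_equal(patent$n_active, 0L)
  expect_equal(max(abs(patent$f)), 0)

  d1 <- plate_pair(-0.02)
  expect_gt(d1$n_active, 0)
  fz_up <- sum(matrix(d1$f, ncol = 3, byrow = TRUE)[5:8, 3])
  expect_gt(fz_up, 0)  # pushes the upper plate away (apart)
  d2 <- plate_pair(-0.04)
  fz_up2 <- sum(matrix(d2$f, ncol = 3, byrow = TRUE)[5:8, 3])
  expect_equal(fz_up2 / fz_up, 2, tolerance = 1e-6)
  # magnitude: penalty * overlap * area within discretization factors
  expect_gt(fz_up, 0.5 * 100 * 0.02 * 1)
  expect_lt(fz_up, 3 * 100 * 0.02 * 1)
})

test_that("element strains report principal Green-Lagrange values", {
  mesh <- test_mesh(6)
  n <- nrow(mesh$nodes)
  expect_equal(max(abs(element_strains(mesh, numeric(3 * n)))), 0)
  # homogeneous uniaxial stretch 1.2 along z: max principal strain 0.22
  u <- as.vector(t(cbind(0, 0, 0.2 * mesh$nodes[, 3])))
  E <- element_strains(mesh, u)
  expect_equal(max(E[, 1]), 0.5 * (1.2^2 - 1), tolerance = 1e-9)
  expect_equal(min(E[, 1]), 0.5 * (1.2^2 - 1), tolerance = 1e-9)
  # rigid rotation gives zero strain (objectivity)
  R <- rotation_z(0.5)
  ur <- as.vector(t(mesh$nodes %*% t(R) - mesh$nodes))
  expect_lt(max(abs(element_strains(mesh, ur))), 1e-10)
})

test_that("ring under small external pressure matches thick-wall theory", {
  rf <- make_ring_fixture()
  out <- run_ring_fixture(rf)
  expect_lt(out$radial_displacement, 0)  # inward
  expect_equal(out$radial_displacement, out$reference, tolerance = 0.05)
  # linearity at small strain
  out2 <- run_ring_fixture(make_ring_fixture(pressure = 0.2))
  expect_equal(out2$radial_displacement / out$radial_displacement, 2,
               tolerance = 0.01)
})

test_that("truss arc-length reproduces the scanned limit load within 1%", {
  tr <- make_snapthrough_truss()
  sc <- truss_limit_load_scan(tr)
  rt <- run_truss_continuation(tr)
  expect_true(rt$limit_passed)
  expect_equal(rt$limit_load, sc$limit_load, tolerance = 0.01)
  expect_identical(rt$termination, "completed")
  # the traversed path stays on the analytic curve
  pre <- rt$states[rt$states$w > 1e-4 & rt$states$w < 2 * tr$rise, ]
  path_err <- abs(vapply(pre$w, tr$path, numeric(1)) - pre$load)
  expect_lt(max(path_err) / sc$limit_load, 0.01)
  # zero load leaves the apex in place
  st0 <- airwaycollapse:::newton_step(tr$system, 0, 0, solver_config(contact = FALSE))
  expect_true(st0$ok)
  expect_equal(st0$u[1], 0)
})

test_that("load control fails just above the truss limit load", {
  tr <- make_snapthrough_truss()
  lim <- truss_limit_load_scan(tr, 4001)$limit_load
  cfg <- solver_config(ds_init = lim / 10, ds_min = lim / 1e4,
                       du_max = 0.05 * tr$rise, contact = FALSE)
  below <- airwaycollapse:::solve_load_control(tr$system, 0.95 * lim,
                                               targets = 0.95 * lim, cfg)
  expect_identical(below$termination, "completed")
  above <- airwaycollapse:::solve_load_control(tr$system, 1.02 * lim,
                                               targets = 1.02 * lim, cfg)
  expect_identical(above$termination, "non_convergence_collapse")
})

test_that("solver runs are deterministic", {
  fx <- make_single_element_fixture(mucosa, 1.4)
  r1 <- run_single_element(fx, nsteps = 4)
  r2 <- run_single_element(fx, nsteps = 4)
  expect_identical(r1$u, r2$u)
})
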