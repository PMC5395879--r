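test_that("shoelace polygon area handles orientation and refinement", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(sq[4:1, ]), 1)
  # discretized semicircle-plus-chord, D = 10: inscribed-polygon area
  # 0.5 R^2 n sin(pi/n) converges to pi R^2 / 2 from below
  for (n in c(32, 64)) {
    th <- seq(0, pi, length.out = n + 1)
    poly <- rbind(cbind(5 * cos(th), 5 * sin(th)),
                  cbind(seq(-5, 5, length.out = 17)[2:16], 0))
    expect_equal(polygon_area(poly), 0.5 * 25 * n * sin(pi / n),
                 tolerance = 1e-9)
    expect_lt(polygon_area(poly), pi * 25 / 2)
  }
  expect_equal(0.5 * 25 * 32 * sin(pi / 32), 39.21, tolerance = 1e-3)
  expect_error(polygon_area(sq[1:2, ]), "n x 2")
})

test_that("self-intersecting loops fall back to the largest simple sub-loop", {
  # crossed square: two triangles of area 1 meeting at (1, 1)
  expect_warning(a <- polygon_area(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))),
                 "self-intersecting")
  expect_equal(a, 1, tolerance = 1e-9)
  # asymmetric bowtie: lobes of area 16/3 and 4/3; the larger one wins
  bow <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, -2))
  expect_warning(ab <- polygon_area(bow), "self-intersecting")
  expect_equal(ab, 16 / 3, tolerance = 1e-9)
})

test_that("pressure-to-force conversion is exact and linear", {
  expect_identical(pressure_to_force(0, 1285.4), 0)
  expect_equal(pressure_to_force(40, 1285.398), 5.042, tolerance = 1e-3)
  expect_equal(pressure_to_force(4, 1285.398),
               pressure_to_force(40, 1285.398) / 10, tolerance = 1e-12)
  expect_equal(pressure_to_force(7, 300), 7 * 98.0665e-6 * 300)
  expect_error(pressure_to_force(-1, 10), "non-negative")
})

fake_result <- function(mesh, pressures, scales,
                        termination = "completed") {
  states <- lapply(seq_along(pressures), function(i) {
    s <- scales[i]
    u <- as.vector(t((s - 1) * cbind(mesh$nodes[, 1], mesh$nodes[, 2], 0)))
    list(pressure = pressures[i], u = u, contact_active = FALSE, n_contact = 0L)
  })
  structure(list(states = states, termination = termination, mesh = mesh,
                 malacia = NULL),
            class = "simulation_result")
}

test_that("area-ratio curves are calibrated to the intact reference", {
  mesh <- test_mesh(6)
  res <- fake_result(mesh, 0, 1)
  cv <- area_ratio_curve(res)
  expect_equal(nrow(cv), 1)
  expect_identical(cv$area_ratio, 1)
  expect_identical(cv$force_n, 0)
  # uniform radial scaling s gives ratio s^2 (similarity)
  res2 <- fake_result(mesh, c(0, 4, 8), c(1, 0.9, 0.6))
  cv2 <- area_ratio_curve(res2)
  expect_equal(cv2$area_ratio, c(1, 0.81, 0.36), tolerance = 1e-9)
  expect_equal(cv2$force_n,
               pressure_to_force(c(0, 4, 8), lumen_surface_area(mesh)))
})

test_that("instability detection fires only on super-linear drops", {
  lin <- tibble::tibble(pressure_cmh2o = seq(0, 40, 4),
                        force_n = seq(0, 5, length.out = 11),
                        area_ratio = 1 - 0.012 * seq(0, 40, 4))
  expect_false(detect_instability(lin)$onset)
  # threshold independence on affine data, any slope
  set.seed(9)
  for (slope in c(0, -0.001, -0.02, -0.4)) {
    aff <- tibble::tibble(pressure_cmh2o = seq(0, 40, 4),
                          force_n = seq(0, 5, length.out = 11),
                          area_ratio = 1 + slope * seq(0, 40, 4))
    for (d in c(1e-6, 0.05, 0.2))
      expect_false(detect_instability(aff, delta = d)$onset)
  }
  # constant curve: no onset
  const <- tibble::tibble(pressure_cmh2o = seq(0, 16, 4),
                          force_n = seq(0, 2, 0.5), area_ratio = rep(1, 5))
  expect_false(detect_instability(const)$onset)
  # linear to step k, then a drop of 3 * delta: onset exactly at k
  d <- 0.05
  r <- 1 - 0.01 * (0:10)
  r[8:11] <- r[8] - 3 * d
  drop <- tibble::tibble(pressure_cmh2o = seq(0, 40, 4),
                         force_n = seq(0, 5, length.out = 11), area_ratio = r)
  rep <- detect_instability(drop, delta = d)
  expect_true(rep$onset)
  expect_equal(rep$step, 8)
  expect_gt(rep$deviation, d)
  # fewer than 3 points: not assessed
  expect_false(detect_instability(const[1:2, ])$assessed)
  # non-convergent termination without a detected drop: onset at final step
  repnc <- detect_instability(lin, termination = "non_convergence_collapse")
  expect_true(repnc$onset)
  expect_equal(repnc$step, nrow(lin))
})

test_that("max wall strain interpolates in force and uses the last crossing", {
  mesh <- test_mesh(6)
  res <- fake_result(mesh, c(0, 4, 8), c(1, 0.95, 0.9))
  expect_equal(max_wall_strain(res, 0), 0, tolerance = 1e-12)
  A <- lumen_surface_area(mesh)
  f4 <- pressure_to_force(4, A)
  s4 <- max(element_strains(mesh, res$states[[2]]$u)[, 1])
  expect_equal(max_wall_strain(res, f4), s4, tolerance = 1e-9)
  # midway between states: linear interpolation of the per-state maxima
  s8 <- max(element_strains(mesh, res$states[[3]]$u)[, 1])
  expect_equal(max_wall_strain(res, 1.5 * f4), (s4 + s8) / 2, tolerance = 1e-9)
  expect_error(max_wall_strain(res, 100), "beyond")
  # non-monotone force history: the last bracketing pair wins
  res2 <- fake_result(mesh, c(0, 8, 4, 2, 8), c(1, 0.9, 0.7, 0.5, 0.3))
  sA <- max(element_strains(mesh, res2$states[[4]]$u)[, 1])
  sB <- max(element_strains(mesh, res2$states[[5]]$u)[, 1])
  f6 <- pressure_to_force(6, A)
  w <- (6 - 2) / (8 - 2)
  expect_equal(max_wall_strain(res2, f6), (1 - w) * sA + w * sB,
               tolerance = 1e-9)
})

test_that("collapse-curve files are written in the documented format", {
  mesh <- test_mesh(6)
  cv <- area_ratio_curve(fake_result(mesh, c(0, 4), c(1, 0.8)))
  tmp <- tempfile(fileext = ".csv")
  write_collapse_curve(cv, tmp)
  back <- utils::read.csv(tmp)
  expect_named(back, c("pressure_cmH2O", "force_N", "area_ratio"))
  expect_equal(back$area_ratio, cv$area_ratio, tolerance = 1e-12)
})
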