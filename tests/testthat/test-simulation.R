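# end-to-end behavior on the coarse test-scale mesh; heavier paper-level
# sweeps live in test-acceptance.R. Expensive runs are computed once and
# shared across blocks.
sim_cache <- new.env(parent = emptyenv())
cached_run <- function(key, expr) {
  if (is.null(sim_cache[[key]])) sim_cache[[key]] <- force(expr)
  sim_cache[[key]]
}
sim_cfg <- solver_config(ds_init = 2, ds_min = 0.25, max_iter = 12)
intact12 <- function() cached_run("intact12", run_load_program(
  test_mesh(6), program = load_program(max_pressure = 12),
  config = sim_cfg))

test_that("a zero-pressure program returns the single reference state", {
  res <- run_load_program(test_mesh(6), program = load_program(max_pressure = 0),
                          config = sim_cfg)
  expect_identical(res$termination, "completed")
  expect_length(res$states, 1)
  expect_equal(max(abs(res$states[[1]]$u)), 0)
})

test_that("the intact model deflates monotonically with pressure", {
  res <- intact12()
  expect_identical(res$termination, "completed")
  cv <- area_ratio_curve(res)
  expect_identical(cv$area_ratio[1], 1)
  expect_equal(cv$pressure_cmh2o, seq(0, 12, 4))
  expect_true(all(diff(cv$area_ratio) < 0))
  expect_true(all(diff(cv$force_n) > 0))
  expect_false(detect_instability(cv)$onset)
})

test_that("the equilibrium path does not depend on the output cadence", {
  res4 <- intact12()
  res2 <- run_load_program(test_mesh(6),
                           program = load_program(max_pressure = 8,
                                                  output_interval = 2),
                           config = sim_cfg)
  u4 <- res4$states[[3]]$u   # state at 8 cm H2O
  u2 <- res2$states[[length(res2$states)]]$u
  expect_equal(res4$states[[3]]$pressure,
               res2$states[[length(res2$states)]]$pressure)
  expect_lt(max(abs(u4 - u2)) / max(abs(u4)), 1e-4)
})

test_that("simulation results are reproducible bit for bit", {
  r1 <- run_load_program(test_mesh(6), program = load_program(max_pressure = 4),
                         config = sim_cfg)
  r2 <- run_load_program(test_mesh(6), program = load_program(max_pressure = 4),
                         config = sim_cfg)
  expect_identical(r1$states[[2]]$u, r2$states[[2]]$u)
})

test_that("state export writes one VTK file per recorded state", {
  res <- intact12()
  d <- tempfile()
  write_states_vtk(res, d)
  expect_length(list.files(d, pattern = "\\.vtk$"), length(res$states))
  tmp <- tempfile(fileext = ".tsv")
  write_solver_log(res, tmp)
  expect_true(file.exists(tmp))
})
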