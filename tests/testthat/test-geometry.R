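test_that("malacic span lengths match the ring/gap arithmetic", {
  expect_equal(malacic_length(7, 2, 1), 20)
  expect_equal(malacic_length(5, 2, 1), 14)
  expect_equal(malacic_length(3, 2, 1), 8)
  expect_equal(malacic_length(1, 2, 1), 2)
  expect_equal(malacic_length(0, 2, 1), 0)
  expect_error(malacic_length(-1), "non-negative")
})

test_that("the default 50 mm model tiles into 17 rings and 16 gaps", {
  mesh <- build_trachea_mesh(trachea_config(diameter = 10))
  expect_equal(sum(mesh$bands$type == "cartilage"), 17)
  expect_equal(sum(mesh$bands$type == "fibrous"), 16)
  expect_setequal(unique(mesh$region),
                  c("cartilage", "fibrous", "muscle", "mucosa"))
  expect_error(trachea_config(length = 49.5), "not decomposable")
})

test_that("element volumes are positive and match analytic region volumes", {
  mesh <- build_trachea_mesh(trachea_config(diameter = 10))
  v <- airwaycollapse:::.elem_volumes_cpp(mesh$nodes, mesh$elems - 1L)
  expect_gt(min(v), 0)
  R <- 5; tm <- 0.2; tw <- 0.8; L <- 50; W <- 2 * (R + tm + tw)
  vol <- tapply(v, mesh$region, sum)
  ref <- c(
    cartilage = pi / 2 * ((R + tm + tw)^2 - (R + tm)^2) * 34,
    fibrous   = pi / 2 * ((R + tm + tw)^2 - (R + tm)^2) * 16,
    mucosa    = pi / 2 * ((R + tm)^2 - R^2) * L + tm * W * L,
    muscle    = tw * W * L)
  for (nm in names(ref))
    expect_equal(unname(vol[nm]), unname(ref[nm]), tolerance = 0.01)
})

test_that("the mucosa lining is 0.2 mm thick node-to-node everywhere", {
  mesh <- build_trachea_mesh(trachea_config(diameter = 8))
  # annulus: nodes at r = R and r = R + 0.2 along each ray
  r <- sqrt(rowSums(mesh$nodes[, 1:2]^2))
  on_arc <- mesh$nodes[, 2] > 1e-9
  expect_true(any(abs(r[on_arc] - 4) < 1e-8))
  expect_true(any(abs(r[on_arc] - 4.2) < 1e-8))
  # slab: mucosa row spans y in [-0.2, 0]
  yc <- rowMeans(matrix(mesh$nodes[mesh$elems, 2], nrow(mesh$elems), 8))
  muc_slab <- which(mesh$region == "mucosa" & yc < 0)
  ys <- mesh$nodes[as.vector(mesh$elems[muc_slab, ]), 2]
  expect_equal(sort(unique(round(ys, 8))), c(-0.2, 0))
})

test_that("the mesh is watertight and regions share interface nodes", {
  mesh <- build_trachea_mesh(trachea_config(
    diameter = 6, n_arc = 8, n_chord = 4))
  # count each element face; interior faces appear twice, boundary once
  faces <- list(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  keys <- character(0)
  for (f in faces) {
    sub <- mesh$elems[, f, drop = FALSE]
    keys <- c(keys, apply(sub, 1, function(x) paste(sort(x), collapse = "_")))
  }
  cnt <- table(keys)
  expect_true(all(cnt <= 2))
  # luminal facets are single-sided element faces
  lum_keys <- apply(mesh$lumen_facets, 1,
                    function(x) paste(sort(x), collapse = "_"))
  expect_true(all(cnt[lum_keys] == 1))
  # no duplicated coincident nodes anywhere (bonded interfaces)
  key <- apply(round(mesh$nodes, 8), 1, paste, collapse = "_")
  expect_equal(anyDuplicated(key), 0L)
})

test_that("luminal surface area approaches the analytic value", {
  mesh10 <- build_trachea_mesh(trachea_config(diameter = 10))
  expect_equal(lumen_surface_area(mesh10), pi * 5 * 50 + 10 * 50,
               tolerance = 0.01)
  mesh6 <- build_trachea_mesh(trachea_config(diameter = 6))
  expect_equal(lumen_surface_area(mesh6), pi * 3 * 50 + 6 * 50,
               tolerance = 0.01)
  # area scales linearly with length (same cross-section)
  mesh_long <- build_trachea_mesh(trachea_config(diameter = 6, length = 98))
  expect_equal(lumen_surface_area(mesh_long) / lumen_surface_area(mesh6),
               98 / 50, tolerance = 1e-9)
})

test_that("mid cross-section polygon behaves like the lumen section", {
  cfg <- trachea_config(diameter = 10, n_arc = 64, n_chord = 16)
  mesh <- build_trachea_mesh(cfg)
  a0 <- polygon_area(mid_cross_section_loop(mesh))
  expect_equal(a0, pi * 25 / 2, tolerance = 1e-3)
  # refinement is monotone toward the analytic area
  areas <- vapply(c(8, 16, 32), function(n) {
    m <- build_trachea_mesh(trachea_config(diameter = 10, n_arc = n))
    polygon_area(mid_cross_section_loop(m))
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
  expect_true(all(areas < pi * 25 / 2))

  # rigid translation leaves the area unchanged; radial scaling by s gives s^2
  u <- rep(c(0.5, -0.3, 0.1), nrow(mesh$nodes))
  expect_equal(polygon_area(mid_cross_section_loop(mesh, u)), a0,
               tolerance = 1e-9)
  s <- 0.5
  us <- as.vector(t((s - 1) * cbind(mesh$nodes[, 1], mesh$nodes[, 2], 0)))
  expect_equal(polygon_area(mid_cross_section_loop(mesh, us)), s^2 * a0,
               tolerance = 1e-9)
})

test_that("malacic element selection is centered, typed and symmetric", {
  mesh <- test_mesh(10)
  zc <- (mesh$nodes[mesh$elems[, 1], 3] + mesh$nodes[mesh$elems[, 5], 3]) / 2

  one <- select_malacic_elements(mesh, malacia_spec("anterior", "mucosa", rings = 1))
  expect_true(all(mesh$region[one] == "cartilage"))
  expect_true(all(zc[one] > 24 & zc[one] < 26))  # the middle ring

  seven <- select_malacic_elements(mesh, malacia_spec("anterior", "soft", rings = 7))
  zr <- range(c(mesh$nodes[mesh$elems[seven, 1], 3],
                mesh$nodes[mesh$elems[seven, 5], 3]))
  expect_equal(diff(zr), 20)  # 7-ring span
  expect_setequal(unique(mesh$region[seven]), c("cartilage", "fibrous"))

  post <- select_malacic_elements(mesh,
                                  malacia_spec("posterior", length_mm = 32, a = 1, b = 1))
  expect_true(all(mesh$region[post] == "muscle"))
  # symmetry about the mid-plane
  for (sel in list(one, seven, post))
    expect_equal(sort(round(zc[sel] - 25, 9)), sort(round(25 - zc[sel], 9)))

  expect_length(select_malacic_elements(
    mesh, malacia_spec("posterior", length_mm = 0, a = 1, b = 1)), 0)
  expect_error(select_malacic_elements(
    mesh, malacia_spec("posterior", length_mm = 60, a = 1, b = 1)), "exceeds")
})

test_that("mesh export writes a well-formed VTK text file", {
  mesh <- test_mesh(6)
  tmp <- tempfile(fileext = ".vtk")
  write_mesh_vtk(mesh, tmp, displacements = numeric(3 * nrow(mesh$nodes)),
                 cell_strain = numeric(nrow(mesh$elems)))
  txt <- readLines(tmp)
  expect_true(any(grepl("^POINTS", txt)))
  expect_true(any(grepl("^CELLS", txt)))
  expect_true(any(grepl("region", txt)))
  expect_true(any(grepl("VECTORS displacement", txt)))
})
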