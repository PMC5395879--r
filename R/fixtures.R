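#' Single-element uniaxial benchmark fixture
#'
#' A unit-cube hexahedron with symmetry boundary conditions and a prescribed
#' axial face displacement imposing a homogeneous uniaxial-stress state
#' (lateral faces free). The reference is the incompressible uniaxial
#' closed-form Cauchy stress.
#'
#' @param material An [ogden_material()].
#' @param stretch Target axial stretch.
#' @return A `benchmark_fixture` list with `nodes`, `elems`, boundary data
#'   and `reference_stress` (MPa).
#' @export
make_single_element_fixture <- function(material, stretch) {
  stopifnot(stretch > 0)
  g <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # VTK hexahedron ordering
  ord <- c(1, 2, 4, 3, 5, 6, 8, 7)
  nodes <- g[ord, , drop = FALSE]
  storage.mode(nodes) <- "double"
  elems <- matrix(1:8, 1, 8)
  dx <- function(i) 3 * (i - 1) + 1
  dy <- function(i) 3 * (i - 1) + 2
  dz <- function(i) 3 * (i - 1) + 3
  fx <- which(nodes[, 1] == 0)
  fy <- which(nodes[, 2] == 0)
  z0 <- which(nodes[, 3] == 0)
  z1 <- which(nodes[, 3] == 1)
  fixed <- c(dx(fx), dy(fy), dz(z0), dz(z1))
  fixed_values <- c(rep(0, length(fx) + length(fy) + length(z0)),
                    rep(stretch - 1, length(z1)))
  structure(list(kind = "single_element", nodes = nodes, elems = elems,
                 fixed = fixed, fixed_values = fixed_values,
                 top_nodes = z1, material = material, stretch = stretch,
                 reference_stress = uniaxial_cauchy_stress(material, stretch)),
            class = "benchmark_fixture")
}

#' Solve the single-element fixture
#'
#' Ramps the prescribed stretch in `nsteps` increments and returns the
#' reaction-derived axial Cauchy stress (reaction force over deformed area)
#' alongside the closed-form reference.
#'
#' @param fixture From [make_single_element_fixture()].
#' @param nsteps Ramp steps.
#' @param config A [solver_config()].
#' @return List with `stress` (measured), `reference`, `u`, `history`
#'   (tibble of stretch vs. measured stress).
#' @export
run_single_element <- function(fixture, nsteps = 10,
                               config = solver_config(contact = FALSE)) {
  sys <- fe_system(fixture$nodes, fixture$elems, list(fixture$material),
                   rep(1L, nrow(fixture$elems)), fixed = fixture$fixed,
                   fixed_values = fixture$fixed_values, facets = NULL,
                   contact = FALSE)
  out <- solve_load_control(sys, lam_max = 1,
                            targets = seq_len(nsteps) / nsteps, config)
  if (out$termination != "completed") stop("single-element ramp did not converge")
  measure <- function(u) {
    asm <- sys$assemble(u, 1, want_K = FALSE)
    dzt <- 3 * (fixture$top_nodes - 1) + 3
    reaction <- sum(asm$f_int[dzt])
    xy <- matrix(u, ncol = 3, byrow = TRUE)[fixture$top_nodes, 1:2] +
      fixture$nodes[fixture$top_nodes, 1:2]
    area <- polygon_area(xy[order(atan2(xy[, 2] - mean(xy[, 2]),
                                        xy[, 1] - mean(xy[, 1]))), ])
    reaction / area
  }
  hist <- dplyr::bind_rows(lapply(out$states[-1], function(s)
    tibble::tibble(stretch = 1 + s$lam * (fixture$stretch - 1),
                   stress_mpa = measure(s$u))))
  u <- out$states[[length(out$states)]]$u
  list(stress = hist$stress_mpa[nrow(hist)],
       reference = fixture$reference_stress, u = u, history = hist)
}

#' Shallow two-bar (von Mises) truss snap-through benchmark
#'
#' Two hyperelastic bars from pinned supports at (+/- half_span, 0) to a
#' single free apex at height `rise`, loaded downward at the apex. The bar
#' law is the incompressible uniaxial Ogden nominal stress. The analytic
#' one-dof equilibrium path P(w) is available in closed form, so the limit
#' (snap-through) load can be found by dense scanning, independently of the
#' solver. Non-shallow geometries trigger a warning but the scan oracle
#' stays valid.
#'
#' @param rise Apex height, same units as `half_span`.
#' @param half_span Support half-distance.
#' @param area Bar cross-section area.
#' @param material Bar [ogden_material()].
#' @return A `snapthrough_truss` list with the 1-dof `system` (solver
#'   interface), `path` (closed-form P(w)) and geometry.
#' @export
make_snapthrough_truss <- function(rise = 0.5, half_span = 10, area = 1,
                                   material = ogden_material(1, 2)) {
  if (rise > 0.2 * half_span)
    warning("truss is not shallow; the scan oracle remains valid")
  h <- rise; s <- half_span; A <- area
  L0 <- sqrt(s^2 + h^2)
  p_nom <- function(lam) uniaxial_cauchy_stress(material, lam) / lam
  dp_nom <- function(lam) {
    d <- 0
    for (t in seq_along(material$a)) {
      a <- material$a[t]; b <- material$b[t]
      sig <- a * (lam^b - lam^(-b / 2))
      dsig <- a * (b * lam^(b - 1) + (b / 2) * lam^(-b / 2 - 1))
      d <- d + (dsig * lam - sig) / lam^2
    }
    d
  }
  path <- function(w) {
    L <- sqrt(s^2 + (h - w)^2)
    lam <- L / L0
    -2 * A * p_nom(lam) * (h - w) / L
  }
  f_int <- path
  k_int <- function(w) {
    L <- sqrt(s^2 + (h - w)^2)
    lam <- L / L0
    c <- (h - w) / L
    dlam <- -(h - w) / (L * L0)
    dc <- -s^2 / L^3
    -2 * A * (dp_nom(lam) * dlam * c + p_nom(lam) * dc)
  }
  assemble <- function(u, lam, want_K) {
    w <- u[1]
    r <- f_int(w) - lam
    K <- if (want_K)
      Matrix::sparseMatrix(i = 1, j = 1, x = k_int(w), dims = c(1, 1)) else NULL
    list(ok = is.finite(r), r = r, K = K, q = 1, f_int = f_int(w),
         diag = list())
  }
  system <- list(ndof = 1L, free = 1L, fixed = integer(), fixed_values = numeric(),
                 assemble = assemble, control_dof = 1L, control_sign = 1)
  structure(list(kind = "snapthrough_truss", system = system, path = path,
                 rise = rise, half_span = half_span, area = area,
                 material = material),
            class = "snapthrough_truss")
}

#' Limit load of the truss by dense scanning of the analytic path
#'
#' Brute-force scan of the closed-form equilibrium path P(w) over the
#' pre-inversion range; solver-independent oracle for arc-length
#' validation.
#'
#' @param truss From [make_snapthrough_truss()].
#' @param n Scan resolution.
#' @return List with `limit_load` and the scanned `path` tibble.
#' @export
truss_limit_load_scan <- function(truss, n = 20001) {
  w <- seq(1e-9, truss$rise, length.out = n)
  p <- vapply(w, truss$path, numeric(1))
  i <- which.max(p)
  list(limit_load = p[i], w_at_limit = w[i],
       path = tibble::tibble(w = w, load = p))
}

#' Traverse the truss snap-through with continuation
#'
#' @param truss From [make_snapthrough_truss()].
#' @param lam_max Load at which to stop on the post-buckled branch.
#' @param config A [solver_config()] (arc-length settings are used).
#' @return List with `limit_load` (peak load before the first load
#'   reversal), `states` tibble (w, load) and `termination`.
#' @export
run_truss_continuation <- function(truss, lam_max = NULL,
                                   config = solver_config(
                                     continuation = "arc_length",
                                     arc_ds = 0.01, arc_steps = 2000)) {
  if (is.null(lam_max)) lam_max <- 3 * truss_limit_load_scan(truss, 2001)$limit_load
  out <- solve_continuation(truss$system, lam_max, config)
  df <- dplyr::bind_rows(lapply(out$states, function(s)
    tibble::tibble(w = s$u[1], load = s$lam)))
  # peak before the first reversal
  loads <- df$load
  peak <- if (length(loads) > 2 && any(diff(loads) < 0)) {
    max(loads[seq_len(which(diff(loads) < 0)[1])])
  } else max(loads)
  list(limit_load = peak, states = df, termination = out$termination,
       limit_passed = out$limit_passed)
}

#' Closed circular ring fixture for small-strain validation
#'
#' A full cylinder slice under small external pressure, compared against
#' the plane-strain thick-walled (Lame) solution at matched small-strain
#' moduli (shear modulus \eqn{\sum a b / 2}, bulk modulus = the volumetric
#' penalty stiffness).
#'
#' @param diameter Inner diameter, mm.
#' @param thickness Wall thickness, mm.
#' @param pressure External pressure, cm H2O (keep small).
#' @param material Ring [ogden_material()].
#' @param n_circ,n_thick,length Mesh densities and slice length.
#' @return A `ring_fixture` list including `reference_displacement` (radial,
#'   mm, at the outer surface; negative inward).
#' @export
make_ring_fixture <- function(diameter = 10, thickness = 0.8, pressure = 0.1,
                              material = ogden_material(0.109, 16.63),
                              n_circ = 32, n_thick = 2, length = 1) {
  stopifnot(n_circ %% 4 == 0)
  a <- diameter / 2
  b <- a + thickness
  radii <- a + thickness * (0:n_thick) / n_thick
  th <- 2 * pi * (0:(n_circ - 1)) / n_circ
  ncs <- n_circ * (n_thick + 1)
  cs <- cbind(rep(radii, each = n_circ) * cos(th),
              rep(radii, each = n_circ) * sin(th))
  nodes <- rbind(cbind(cs, 0), cbind(cs, length))
  idx <- function(k, j, p) (p - 1) * ncs + (j - 1) * n_circ + ((k - 1) %% n_circ) + 1
  elems <- list(); facets <- list()
  for (k in seq_len(n_circ)) for (j in seq_len(n_thick)) {
    elems[[length(elems) + 1L]] <- c(idx(k, j, 1), idx(k, j + 1, 1),
                                     idx(k + 1, j + 1, 1), idx(k + 1, j, 1),
                                     idx(k, j, 2), idx(k, j + 1, 2),
                                     idx(k + 1, j + 1, 2), idx(k + 1, j, 2))
  }
  for (k in seq_len(n_circ)) {
    # outer surface facet, oriented so the normal points toward the axis
    facets[[length(facets) + 1L]] <- c(idx(k + 1, n_thick + 1, 1),
                                       idx(k, n_thick + 1, 1),
                                       idx(k, n_thick + 1, 2),
                                       idx(k + 1, n_thick + 1, 2))
  }
  elems <- do.call(rbind, elems)
  facets <- do.call(rbind, facets)
  tolc <- 1e-9
  fixed <- c(3 * (seq_len(nrow(nodes)) - 1) + 3,                 # plane strain
             3 * (which(abs(nodes[, 1]) < tolc) - 1) + 1,
             3 * (which(abs(nodes[, 2]) < tolc) - 1) + 2)
  fixed <- sort(unique(fixed))
  mu <- shear_modulus(material)
  kap <- material$bulk_modulus
  nu <- (3 * kap - 2 * mu) / (2 * (3 * kap + mu))
  E <- 9 * kap * mu / (3 * kap + mu)
  p_mpa <- pressure * CMH2O_MPA
  Ac <- -p_mpa * b^2 / (b^2 - a^2)
  Bc <- Ac * a^2
  u_ref <- (1 + nu) / E * ((1 - 2 * nu) * Ac * b + Bc / b)
  structure(list(kind = "ring", nodes = nodes, elems = elems, facets = facets,
                 fixed = fixed, material = material, pressure = pressure,
                 inner_radius = a, outer_radius = b,
                 reference_displacement = u_ref),
            class = "ring_fixture")
}

#' Solve the ring fixture
#'
#' @param fixture From [make_ring_fixture()].
#' @param config A [solver_config()].
#' @return List with `radial_displacement` (measured, outer surface),
#'   `reference` and the displacement vector.
#' @export
run_ring_fixture <- function(fixture, config = solver_config(contact = FALSE)) {
  sys <- fe_system(fixture$nodes, fixture$elems, list(fixture$material),
                   rep(1L, nrow(fixture$elems)), fixed = fixture$fixed,
                   fixed_values = numeric(length(fixture$fixed)),
                   facets = fixture$facets, follower = TRUE, contact = FALSE)
  out <- solve_load_control(sys, lam_max = fixture$pressure,
                            targets = fixture$pressure, config)
  if (out$termination != "completed") stop("ring fixture did not converge")
  u <- out$states[[length(out$states)]]$u
  um <- matrix(u, ncol = 3, byrow = TRUE)
  r0 <- sqrt(nodes_r2 <- rowSums(fixture$nodes[, 1:2]^2))
  outer <- which(abs(sqrt(nodes_r2) - fixture$outer_radius) < 1e-8)
  er <- fixture$nodes[outer, 1:2] / sqrt(nodes_r2[outer])
  ur <- rowSums(um[outer, 1:2] * er)
  list(radial_displacement = mean(ur),
       reference = fixture$reference_displacement, u = u)
}
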