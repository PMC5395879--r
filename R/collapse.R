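#' Polygon area (shoelace)
#'
#' Absolute, orientation-independent area of an ordered planar polygon. A
#' self-intersecting loop (which can occur for post-contact lumen sections)
#' is split at its first edge crossing and the area of the largest simple
#' sub-loop is returned, with a warning -- the remaining open lumen an
#' outline of the deformed section would capture.
#'
#' @param polygon Two-column matrix of vertex coordinates in loop order
#'   (at least 3 vertices; do not repeat the first vertex).
#' @return Area (mm^2 for mm coordinates).
#' @export
polygon_area <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3 || ncol(polygon) != 2) stop("need an n x 2 polygon, n >= 3")
  cross_pair <- find_self_intersection(polygon)
  if (is.null(cross_pair)) return(abs(shoelace(polygon)))
  warning("self-intersecting polygon: using the largest simple sub-loop")
  largest_simple_area(polygon, depth = 0)
}

shoelace <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

seg_intersect <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-14) return(NULL)
  t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
  s <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
  eps <- 1e-10
  if (t > eps && t < 1 - eps && s > eps && s < 1 - eps)
    return(list(t = t, pt = p1 + t * d1))
  NULL
}

find_self_intersection <- function(p) {
  n <- nrow(p)
  nxt <- c(2:n, 1)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      hit <- seg_intersect(p[i, ], p[nxt[i], ], p[j, ], p[nxt[j], ])
      if (!is.null(hit)) return(list(i = i, j = j, pt = hit$pt))
    }
  }
  NULL
}

largest_simple_area <- function(p, depth) {
  if (depth > 8) return(abs(shoelace(p)))
  hit <- find_self_intersection(p)
  if (is.null(hit)) return(abs(shoelace(p)))
  i <- hit$i; j <- hit$j
  loop1 <- rbind(hit$pt, p[(i + 1):j, , drop = FALSE])
  idx2 <- c(if (j < nrow(p)) (j + 1):nrow(p), 1:i)
  loop2 <- rbind(hit$pt, p[idx2, , drop = FALSE])
  a1 <- if (nrow(loop1) >= 3) largest_simple_area(loop1, depth + 1) else 0
  a2 <- if (nrow(loop2) >= 3) largest_simple_area(loop2, depth + 1) else 0
  max(a1, a2)
}

#' Convert an exhalation pressure to a total airway force
#'
#' `force = pressure x 98.0665 Pa/cmH2O x lumen_area`, using the undeformed
#' luminal surface area so the conversion is a per-model constant (it
#' differs between the 6, 8 and 10 mm diameter models).
#'
#' @param pressure Pressure in cm H2O (vectorized).
#' @param lumen_area Undeformed luminal surface area, mm^2
#'   (see [lumen_surface_area()]).
#' @return Force in N.
#' @export
pressure_to_force <- function(pressure, lumen_area) {
  if (any(pressure < 0) || any(lumen_area < 0)) stop("inputs must be non-negative")
  pressure * CMH2O_MPA * lumen_area
}

#' Lumen area-ratio collapse curve
#'
#' One row per recorded state: pressure, total airway force (pressure times
#' the undeformed luminal area) and the mid-length lumen area divided by the
#' intact undeformed lumen area. The ratio at zero pressure is exactly 1 by
#' calibration.
#'
#' @param result A [run_load_program()] result.
#' @param mesh The mesh (defaults to the one stored in `result`).
#' @return A `collapse_curve` tibble with columns `pressure_cmh2o`,
#'   `force_n`, `area_ratio`, and metadata attributes (`diameter`,
#'   `malacia`, `termination`).
#' @export
area_ratio_curve <- function(result, mesh = result$mesh) {
  stopifnot(inherits(result, "simulation_result") || is.list(result))
  if (length(result$states) < 1) stop("result has no states")
  area0 <- polygon_area(mid_cross_section_loop(mesh, NULL))
  larea <- lumen_surface_area(mesh)
  rows <- lapply(result$states, function(s) {
    a <- suppressWarnings(polygon_area(mid_cross_section_loop(mesh, s$u)))
    tibble::tibble(pressure_cmh2o = s$pressure,
                   force_n = pressure_to_force(max(s$pressure, 0), larea),
                   area_ratio = a / area0)
  })
  out <- dplyr::bind_rows(rows)
  out$area_ratio[1] <- 1  # exact calibration at the reference state
  attr(out, "diameter") <- mesh$config$diameter
  attr(out, "malacia") <- result$malacia
  attr(out, "termination") <- result$termination
  class(out) <- c("collapse_curve", class(out))
  out
}

#' Detect snap-through instability onset
#'
#' At each recorded step `i >= 3`, the expected area ratio is linearly
#' extrapolated through the two previous (force, area-ratio) points; onset
#' is the first step whose actual ratio falls more than `delta` below that
#' prediction. If the run terminated by non-convergent collapse without the
#' extrapolation criterion firing, onset is assigned to the final recorded
#' step (the starred, non-convergent cases).
#'
#' @param curve A [area_ratio_curve()] tibble (or any data frame with
#'   `force_n`, `area_ratio` and optionally `pressure_cmh2o`).
#' @param delta Deviation threshold in area-ratio units (default 0.05).
#' @param termination Termination tag; defaults to the curve attribute.
#' @return An `instability_report`: list with `onset` (flag), `step`,
#'   `pressure_cmh2o`, `force_n`, `deviation`, `assessed`.
#' @export
detect_instability <- function(curve, delta = 0.05, termination = NULL) {
  if (is.null(termination))
    termination <- attr(curve, "termination") %||% "completed"
  n <- nrow(curve)
  rep0 <- structure(list(onset = FALSE, step = NA_integer_,
                         pressure_cmh2o = NA_real_, force_n = NA_real_,
                         deviation = NA_real_, assessed = n >= 3),
                    class = "instability_report")
  if (n < 3) return(rep0)
  f <- curve$force_n; r <- curve$area_ratio
  for (i in 3:n) {
    df <- f[i - 1] - f[i - 2]
    slope <- if (abs(df) > 1e-12) (r[i - 1] - r[i - 2]) / df else 0
    r_hat <- r[i - 1] + slope * (f[i] - f[i - 1])
    dev <- r_hat - r[i]
    if (is.finite(dev) && dev > delta) {
      return(structure(list(onset = TRUE, step = i,
                            pressure_cmh2o = curve$pressure_cmh2o[i],
                            force_n = f[i], deviation = dev, assessed = TRUE),
                       class = "instability_report"))
    }
  }
  if (identical(termination, "non_convergence_collapse")) {
    return(structure(list(onset = TRUE, step = n,
                          pressure_cmh2o = curve$pressure_cmh2o[n],
                          force_n = f[n], deviation = NA_real_,
                          assessed = TRUE),
                     class = "instability_report"))
  }
  rep0
}

#' @export
print.instability_report <- function(x, ...) {
  if (!x$assessed) cat("<instability_report> not assessed (fewer than 3 points)\n")
  else if (!x$onset) cat("<instability_report> no onset\n")
  else cat(sprintf(
    "<instability_report> onset at step %d: %.3g cm H2O, %.3g N (deviation %.3g)\n",
    x$step, x$pressure_cmh2o, x$force_n, x$deviation))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum wall strain at a given total airway force
#'
#' Maximum over elements of the maximum principal Green-Lagrange strain, at
#' the recorded state nearest the requested total force (linear
#' interpolation in force between the bracketing output states). When the
#' force history is non-monotone (arc-length traversal of a limit point),
#' the last bracketing pair is used, i.e. the post-collapse branch.
#'
#' @param result A [run_load_program()] result.
#' @param at_force Requested total airway force, N.
#' @param mesh The mesh (defaults to the one stored in `result`).
#' @return Maximum principal Green-Lagrange strain (dimensionless).
#' @export
max_wall_strain <- function(result, at_force, mesh = result$mesh) {
  larea <- lumen_surface_area(mesh)
  f <- vapply(result$states, function(s)
    pressure_to_force(max(s$pressure, 0), larea), numeric(1))
  if (at_force < -1e-12 || at_force > max(f) + 1e-9)
    stop(sprintf("requested force %.3g N beyond the achieved range (max %.3g N)",
                 at_force, max(f)))
  lib <- if (!is.null(result$config) &&
               identical(result$config$element, "h8i")) result$library else NULL
  ms <- function(i) max(element_strains(mesh, result$states[[i]]$u,
                                        library = lib,
                                        malacia = result$malacia)[, 1])
  hit <- which(abs(f - at_force) < 1e-9)
  if (length(hit)) return(ms(tail(hit, 1)))
  bracket <- NULL
  for (i in seq_len(length(f) - 1))
    if ((f[i] - at_force) * (f[i + 1] - at_force) < 0) bracket <- i
  if (is.null(bracket)) stop("no state brackets the requested force")
  w <- (at_force - f[bracket]) / (f[bracket + 1] - f[bracket])
  (1 - w) * ms(bracket) + w * ms(bracket + 1)
}
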