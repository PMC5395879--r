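#' Plot a collapse curve
#'
#' Lumen area ratio against total airway force, the standard severity plot.
#'
#' @param object A `collapse_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.collapse_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$force_n, y = .data$area_ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Total airway force (N)",
                  y = "Lumen area ratio (deformed / intact)") +
    ggplot2::coord_cartesian(ylim = c(0, 1.05))
}

#' Plot an Ogden fit against its data
#'
#' @param object An `ogden_fit` (from [fit_ogden()]); the fitted curve is
#'   drawn over the data it was fit to.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ogden_fit <- function(object, ...) {
  dat <- object$data
  if (is.null(dat)) stop("fit object carries no data")
  grid <- tibble::tibble(strain = seq(min(dat$strain), max(dat$strain),
                                      length.out = 200))
  grid$stress_mpa <- uniaxial_cauchy_stress(object$material, 1 + grid$strain)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$strain, y = .data$stress_mpa)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, color = "red") +
    ggplot2::labs(x = "Engineering strain", y = "Cauchy stress (MPa)",
                  title = sprintf("%s: a = %.4g MPa, b = %.4g (R² = %.3f)",
                                  object$material$label, object$material$a,
                                  object$material$b, object$r_squared))
}

#' Plot a sweep of collapse curves
#'
#' Area-ratio curves for every converged cell, faceted by diameter and
#' severity and colored by malacic extent.
#'
#' @param object A `sweep_result` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sweep_result <- function(object, ...) {
  rows <- which(!vapply(object$curve, is.null, logical(1)))
  df <- dplyr::bind_rows(lapply(rows, function(i) {
    cv <- object$curve[[i]]
    tibble::tibble(diameter = object$diameter[i],
                   severity = object$severity[i],
                   extent_mm = object$length_mm[i],
                   force_n = cv$force_n, area_ratio = cv$area_ratio)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$force_n, y = .data$area_ratio,
                                   color = factor(.data$extent_mm))) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(severity ~ diameter,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Total airway force (N)", y = "Lumen area ratio",
                  color = "Malacic extent (mm)") +
    ggplot2::coord_cartesian(ylim = c(0, 1.05))
}
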