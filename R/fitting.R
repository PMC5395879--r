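#' Fit a one-term Ogden model to uniaxial stress-strain data
#'
#' Least-squares fit of the incompressible uniaxial Cauchy-stress closed form
#' \eqn{\sigma = a(\lambda^b - \lambda^{-b/2})}, \eqn{\lambda = 1 +
#' \varepsilon}, by unconstrained smooth minimization (BFGS on
#' \eqn{(\log a, b)}) with multistart over log-spaced `b` starting values to
#' avoid local minima. The fit is deterministic given `seed`.
#'
#' @param curve Data frame with columns `strain` (engineering, non-negative,
#'   strictly increasing) and `stress_mpa` (Cauchy stress, MPa), e.g. from
#'   [generate_stress_strain()] or [read_stress_strain()].
#' @param initial_guess Optional `c(a, b)` start; always included among the
#'   multistarts.
#' @param multistart_count Number of starting points (default 8).
#' @param seed Integer seed controlling start-point jitter.
#' @param label Tissue label for the fitted material.
#' @return An object of class `ogden_fit` with elements `material`
#'   ([ogden_material()]), `r_squared`, `residual_norm` (MPa), `converged`.
#'   Supports [tidy()] and [glance()].
#' @examples
#' cart <- ogden_material(0.109, 16.63, label = "cartilage")
#' dat <- generate_stress_strain(cart)
#' fit <- fit_ogden(dat)
#' glance(fit)
#' @export
fit_ogden <- function(curve, initial_guess = NULL, multistart_count = 8,
                      seed = 1L, label = NULL) {
  stopifnot(is.data.frame(curve), all(c("strain", "stress_mpa") %in% names(curve)))
  eps <- as.numeric(curve$strain)
  sig <- as.numeric(curve$stress_mpa)
  if (length(unique(eps)) < 3) stop("need at least 3 distinct strain points")
  if (any(!is.finite(eps)) || any(!is.finite(sig))) stop("non-finite data")
  if (all(sig == 0)) stop("degenerate data: all stresses are zero")
  if (is.null(label)) label <- if (!is.null(curve$tissue)) as.character(curve$tissue[1]) else "fitted"
  lam <- 1 + eps

  obj <- function(par) {
    a <- exp(par[1]); b <- par[2]
    if (!is.finite(a) || abs(b) < 1e-8) return(1e30)
    r <- a * (lam^b - lam^(-b / 2)) - sig
    if (any(!is.finite(r))) return(1e30)
    sum(r^2)
  }

  # starts: log-spaced b, a scaled to match the terminal stress
  bs <- exp(seq(log(0.5), log(25), length.out = multistart_count))
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    bs <- bs * exp(rnorm(multistart_count, 0, 0.05))
  }
  lmax <- max(lam)
  starts <- lapply(bs, function(b) {
    a0 <- abs(sig[which.max(abs(sig))]) / max(lmax^b - lmax^(-b / 2), 1e-8)
    c(log(max(a0, 1e-6)), b)
  })
  if (!is.null(initial_guess))
    starts <- c(list(c(log(initial_guess[1]), initial_guess[2])), starts)

  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      optim(s, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- fit$convergence == 0 && all(is.finite(fit$par))
    any_conv <- any_conv || conv
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed")
  # polish the winner
  pol <- tryCatch(
    optim(best$par, obj, method = "BFGS",
          control = list(maxit = 1000, reltol = 1e-15)),
    error = function(e) best)
  if (pol$value <= best$value) best <- pol

  a_hat <- exp(best$par[1]); b_hat <- best$par[2]
  ss_res <- best$value
  ss_tot <- sum((sig - mean(sig))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(
    list(material = ogden_material(a_hat, b_hat, label = label),
         r_squared = r2, residual_norm = sqrt(ss_res),
         converged = any_conv && all(is.finite(c(a_hat, b_hat))),
         n = length(eps),
         data = tibble::tibble(strain = eps, stress_mpa = sig)),
    class = "ogden_fit")
}

#' @export
print.ogden_fit <- function(x, ...) {
  cat(sprintf("<ogden_fit: %s> a = %.6g MPa, b = %.6g, R^2 = %.4f%s\n",
              x$material$label, x$material$a, x$material$b, x$r_squared,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @rdname fit_ogden
#' @param x An `ogden_fit` object.
#' @param ... Unused.
#' @export
tidy.ogden_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"),
                 estimate = c(x$material$a, x$material$b),
                 unit = c("MPa", ""))
}

#' @rdname fit_ogden
#' @export
glance.ogden_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, residual.norm = x$residual_norm,
                 converged = x$converged, nobs = x$n)
}

#' Generate a synthetic uniaxial stress-strain curve
#'
#' Samples the incompressible uniaxial Ogden closed form on a strain grid,
#' optionally perturbed by additive or multiplicative Gaussian noise. This
#' emulates the published preterm-lamb tracheal tissue curves (which are not
#' deposited) from their fitted coefficients. Identical seeds give identical
#' curves.
#'
#' @param material An [ogden_material()].
#' @param strain Engineering strain grid (default 0 to 0.5 step 0.01, the
#'   plotted experimental range).
#' @param noise `"none"`, `"additive"` (sd in MPa) or `"multiplicative"`
#'   (sd as a fraction of each stress).
#' @param sd Noise magnitude; default 0.
#' @param seed Integer seed for the noise.
#' @return Tibble with columns `tissue`, `strain`, `stress_mpa`.
#' @export
generate_stress_strain <- function(material, strain = seq(0, 0.5, by = 0.01),
                                   noise = c("none", "additive", "multiplicative"),
                                   sd = 0, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(all(strain >= 0), !is.unsorted(strain, strictly = TRUE), sd >= 0)
  sig <- uniaxial_cauchy_stress(material, 1 + strain)
  if (sd > 0 && noise != "none") {
    set.seed(as.integer(seed))
    z <- rnorm(length(sig))
    sig <- if (noise == "additive") sig + sd * z else sig * (1 + sd * z)
  }
  tibble::tibble(tissue = material$label, strain = as.numeric(strain),
                 stress_mpa = sig)
}

#' Read / write delimited stress-strain curves
#'
#' Plain-text format with header `strain,stress_mpa` (and optionally
#' `tissue`).
#'
#' @param path File path.
#' @param tissue Label to attach when the file has no `tissue` column.
#' @return A tibble with columns `tissue`, `strain`, `stress_mpa`.
#' @export
read_stress_strain <- function(path, tissue = "tissue") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("strain", "stress_mpa") %in% names(df)))
  if (is.null(df$tissue)) df$tissue <- tissue
  tibble::as_tibble(df[, c("tissue", "strain", "stress_mpa")])
}

#' @rdname read_stress_strain
#' @param curve Data frame with `strain` and `stress_mpa` columns.
#' @export
write_stress_strain <- function(curve, path) {
  write.csv(curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a tissue library to / from YAML
#'
#' Key-value document with one entry per tissue role holding `a`, `b` and
#' `kappa` (the volumetric penalty stiffness).
#'
#' @param library A [tissue_library()].
#' @param path File path.
#' @export
write_tissue_library <- function(library, path) {
  stopifnot(inherits(library, "tissue_library"))
  doc <- lapply(library, function(m)
    list(a = as.numeric(m$a), b = as.numeric(m$b),
         kappa = as.numeric(m$bulk_modulus)))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_tissue_library
#' @export
read_tissue_library <- function(path) {
  doc <- yaml::read_yaml(path)
  mats <- lapply(names(doc), function(nm)
    ogden_material(unlist(doc[[nm]]$a), unlist(doc[[nm]]$b),
                   doc[[nm]]$kappa, label = nm))
  names(mats) <- names(doc)
  do.call(tissue_library, mats[c("cartilage", "fibrous", "smooth_muscle", "mucosa")])
}
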