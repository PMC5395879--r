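#' Ogden hyperelastic material
#'
#' Constructs an isotropic Ogden material with strain energy
#' \deqn{W = \sum_t \frac{a_t}{b_t}\left(\bar\lambda_1^{b_t} +
#'   \bar\lambda_2^{b_t} + \bar\lambda_3^{b_t} - 3\right) +
#'   \tfrac{1}{2}\kappa (\ln J)^2}
#' where \eqn{\bar\lambda_i = J^{-1/3}\lambda_i} are the unit-volume-scaled
#' (isochoric) principal stretches and \eqn{J = \lambda_1\lambda_2\lambda_3}.
#' A single term is the default, matching the per-tissue coefficient pairs
#' used for tracheal cartilage, fibrous tissue, trachealis smooth muscle and
#' mucosa. The quadratic-log volumetric penalty enforces
#' near-incompressibility; its default stiffness \eqn{\kappa = 1000\sum_t a_t}
#' gives a small-strain Poisson ratio close to 0.4995.
#'
#' @param a Stress-like coefficient(s), MPa. All must be positive.
#' @param b Dimensionless exponent(s), nonzero, same length as `a`.
#' @param bulk_modulus Volumetric penalty stiffness, MPa. Default
#'   `1000 * sum(a)`.
#' @param label Tissue name.
#' @return An object of class `ogden_material`.
#' @examples
#' mucosa <- ogden_material(0.1, 3.4, label = "mucosa")
#' uniaxial_cauchy_stress(mucosa, 1.5)
#' @export
ogden_material <- function(a, b, bulk_modulus = NULL, label = "tissue") {
  stopifnot(length(a) == length(b), length(a) >= 1)
  if (any(!is.finite(a)) || any(a <= 0)) stop("all `a` coefficients must be positive")
  if (any(!is.finite(b)) || any(b == 0)) stop("all `b` exponents must be nonzero")
  if (is.null(bulk_modulus)) bulk_modulus <- 1000 * sum(a)
  if (bulk_modulus <= 0) stop("`bulk_modulus` must be positive")
  structure(
    list(a = as.numeric(a), b = as.numeric(b),
         bulk_modulus = as.numeric(bulk_modulus), label = label),
    class = "ogden_material"
  )
}

#' @export
print.ogden_material <- function(x, ...) {
  cat(sprintf("<ogden_material: %s>\n", x$label))
  for (t in seq_along(x$a))
    cat(sprintf("  term %d: a = %g MPa, b = %g\n", t, x$a[t], x$b[t]))
  cat(sprintf("  bulk modulus: %g MPa\n", x$bulk_modulus))
  invisible(x)
}

#' Small-strain shear modulus of an Ogden material
#'
#' The infinitesimal shear modulus \eqn{\mu = \sum_t a_t b_t / 2}, used when
#' matching the hyperelastic model to linear-elastic reference solutions.
#'
#' @param material An [ogden_material()].
#' @return Shear modulus in MPa.
#' @export
shear_modulus <- function(material) sum(material$a * material$b) / 2

#' Built-in tracheal tissue library
#'
#' One-term Ogden coefficients fit to preterm-lamb tracheal tissue
#' stress-strain data (cartilage, fibrous tissue, smooth muscle) and to
#' engineered oral mucosa (mucosa): cartilage a = 0.109, b = 16.63; fibrous
#' a = 0.01, b = 11.05; smooth muscle a = 0.08, b = 6.29; mucosa a = 0.1,
#' b = 3.4 (a in MPa).
#'
#' @return A `tissue_library`: named list with elements `cartilage`,
#'   `fibrous`, `smooth_muscle`, `mucosa`.
#' @export
default_tissue_library <- function() {
  tissue_library(
    cartilage     = ogden_material(0.109, 16.63, label = "cartilage"),
    fibrous       = ogden_material(0.01, 11.05, label = "fibrous"),
    smooth_muscle = ogden_material(0.08, 6.29, label = "smooth_muscle"),
    mucosa        = ogden_material(0.1, 3.4, label = "mucosa")
  )
}

#' Assemble a tissue library
#'
#' @param cartilage,fibrous,smooth_muscle,mucosa [ogden_material()] objects
#'   for the four tracheal tissue roles.
#' @return A `tissue_library` object.
#' @export
tissue_library <- function(cartilage, fibrous, smooth_muscle, mucosa) {
  lib <- list(cartilage = cartilage, fibrous = fibrous,
              smooth_muscle = smooth_muscle, mucosa = mucosa)
  ok <- vapply(lib, inherits, logical(1), "ogden_material")
  if (!all(ok)) stop("all four tissue roles must be ogden_material objects")
  structure(lib, class = "tissue_library")
}

#' @export
print.tissue_library <- function(x, ...) {
  cat("<tissue_library>\n")
  for (nm in names(x))
    cat(sprintf("  %-13s a = %s, b = %s\n", nm,
                paste(signif(x[[nm]]$a, 4), collapse = ","),
                paste(signif(x[[nm]]$b, 4), collapse = ",")))
  invisible(x)
}

check_stretches <- function(stretches) {
  stretches <- as.numeric(stretches)
  if (length(stretches) != 3 || any(!is.finite(stretches)) || any(stretches <= 0))
    stop("principal stretches must be three positive finite numbers")
  stretches
}

#' Ogden strain-energy density
#'
#' Evaluates the isochoric Ogden energy on the unit-volume-scaled stretches
#' plus the volumetric penalty \eqn{\frac{1}{2}\kappa(\ln J)^2}.
#'
#' @param material An [ogden_material()].
#' @param stretches Principal stretches, length-3 positive vector.
#' @return Energy density in MPa.
#' @examples
#' m <- ogden_material(0.1, 3.4)
#' strain_energy(m, c(1.5, 1.5^-0.5, 1.5^-0.5))
#' @export
strain_energy <- function(material, stretches) {
  stretches <- check_stretches(stretches)
  .ogden_energy_cpp(stretches, material$a, material$b, material$bulk_modulus)
}

#' Uniaxial incompressible Cauchy stress
#'
#' Closed form for uniaxial tension of an incompressible Ogden solid:
#' \deqn{\sigma(\lambda) = \sum_t a_t (\lambda^{b_t} - \lambda^{-b_t/2}).}
#'
#' @param material An [ogden_material()].
#' @param stretch Axial stretch ratio(s), positive. Engineering strain is
#'   `stretch - 1`.
#' @return Cauchy stress in MPa (vectorized over `stretch`).
#' @export
uniaxial_cauchy_stress <- function(material, stretch) {
  stretch <- as.numeric(stretch)
  if (any(!is.finite(stretch)) || any(stretch <= 0))
    stop("stretch must be positive")
  out <- numeric(length(stretch))
  for (t in seq_along(material$a))
    out <- out + material$a[t] *
      (stretch^material$b[t] - stretch^(-material$b[t] / 2))
  out
}

check_defgrad <- function(F) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3, 3)) || any(!is.finite(F)))
    stop("deformation gradient must be a finite 3x3 matrix")
  if (det(F) <= 0) stop("deformation gradient has non-positive determinant (inverted state)")
  F
}

#' Cauchy stress tensor
#'
#' Spectral evaluation of the isochoric Ogden stress on the principal
#' stretches of the deformation gradient, plus the volumetric pressure
#' \eqn{\kappa \ln J / J} on the identity. In the near-incompressible limit
#' the axial component under uniaxial stretch reduces to
#' [uniaxial_cauchy_stress()].
#'
#' @param material An [ogden_material()].
#' @param deformation_gradient 3x3 matrix with positive determinant.
#' @return Symmetric 3x3 Cauchy stress, MPa.
#' @export
cauchy_stress_tensor <- function(material, deformation_gradient) {
  F <- check_defgrad(deformation_gradient)
  .ogden_stress_cpp(F, material$a, material$b, material$bulk_modulus, FALSE)$sigma
}

#' Material tangent dP/dF
#'
#' Consistent linearization of the first Piola-Kirchhoff stress with respect
#' to the deformation gradient, as a 9x9 matrix in column-major ordering of
#' both indices (entry `(i + 3(J-1), k + 3(L-1))` is
#' \eqn{\partial P_{iJ}/\partial F_{kL}}).
#'
#' @inheritParams cauchy_stress_tensor
#' @return List with `P` (3x3 first Piola stress) and `A` (9x9 tangent).
#' @export
material_tangent <- function(material, deformation_gradient) {
  F <- check_defgrad(deformation_gradient)
  out <- .ogden_stress_cpp(F, material$a, material$b, material$bulk_modulus, TRUE)
  list(P = out$P, A = out$A)
}

#' Apply a malacia property reduction to a tissue library
#'
#' Severity `"soft"` replaces the cartilage coefficients with the fibrous
#' tissue coefficients; `"mucosa"` replaces both cartilage and fibrous
#' coefficients with the mucosa coefficients; `"posterior"` replaces the
#' smooth-muscle coefficients with an explicit `(a, b)` pair (the posterior
#' weakening series uses a = 1, b = 7 and a = 1, b = 1). Non-targeted
#' tissues are unchanged.
#'
#' @param library A [tissue_library()].
#' @param severity One of `"soft"`, `"mucosa"`, `"posterior"`.
#' @param a,b Replacement coefficients, required for `"posterior"`.
#' @return A new `tissue_library`.
#' @export
apply_malacia <- function(library, severity, a = NULL, b = NULL) {
  stopifnot(inherits(library, "tissue_library"))
  severity <- match.arg(severity, c("soft", "mucosa", "posterior"))
  out <- library
  if (severity == "soft") {
    out$cartilage <- ogden_material(library$fibrous$a, library$fibrous$b,
                                    library$fibrous$bulk_modulus,
                                    label = "cartilage(soft)")
  } else if (severity == "mucosa") {
    for (role in c("cartilage", "fibrous"))
      out[[role]] <- ogden_material(library$mucosa$a, library$mucosa$b,
                                    library$mucosa$bulk_modulus,
                                    label = paste0(role, "(mucosa)"))
  } else {
    if (is.null(a) || is.null(b))
      stop("posterior severity requires explicit `a` and `b`")
    out$smooth_muscle <- ogden_material(a, b,
                                        label = sprintf("smooth_muscle(a=%g,b=%g)", a, b))
  }
  out
}
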