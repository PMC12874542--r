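# Effective-medium optics for molecular coatings on colloidal beads.
#
# A bead of substrate index n0 in a medium of index nm acquires a thin
# molecular coating of thickness a_c whose material has intrinsic index n1.
# The coating is a mixture of macromolecules (volume fraction phi_c) and
# medium, so its effective index n_c follows Maxwell Garnett mixing. The
# holographically measured diameter increase delta_d relates to a_c through
# the coated-sphere relation delta_d = 2 a_c (n_c - nm) / (n0 - nm).

#' Optical constants for a coated-bead system
#'
#' Bundles the substrate, medium, and coating-material refractive indices
#' with their 1-sigma uncertainties. All indices are dimensionless values
#' at the instrument wavelength; no dispersion model is applied.
#'
#' @param n0 substrate bead refractive index.
#' @param nm fluid medium refractive index.
#' @param n1 intrinsic refractive index of the coating material.
#' @param sigma_n0,sigma_nm,sigma_n1 1-sigma uncertainties (default 0).
#' @return an object of class `optical_constants`.
#' @examples
#' optical_constants(n0 = 1.6019, nm = 1.340, n1 = 1.470)
#' @export
optical_constants <- function(n0, nm, n1,
                              sigma_n0 = 0, sigma_nm = 0, sigma_n1 = 0) {
  for (v in c(n0, nm, n1)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 1 || v >= 3)
      stop("refractive indices must be finite scalars in (1, 3)", call. = FALSE)
  }
  if (n0 == nm)
    stop("n0 must differ from nm: the coated-sphere relation divides by n0 - nm",
         call. = FALSE)
  if (any(c(sigma_n0, sigma_nm, sigma_n1) < 0))
    stop("uncertainties must be non-negative", call. = FALSE)
  structure(
    list(n0 = n0, nm = nm, n1 = n1,
         sigma_n0 = sigma_n0, sigma_nm = sigma_nm, sigma_n1 = sigma_n1),
    class = "optical_constants"
  )
}

#' @export
print.optical_constants <- function(x, ...) {
  cat("Optical constants:\n")
  cat(sprintf("  substrate n0 = %.4f +/- %.4f\n", x$n0, x$sigma_n0))
  cat(sprintf("  medium    nm = %.4f +/- %.4f\n", x$nm, x$sigma_nm))
  cat(sprintf("  coating   n1 = %.4f +/- %.4f\n", x$n1, x$sigma_n1))
  invisible(x)
}

#' Lorentz-Lorenz factor
#'
#' The polarizability-contrast function L(m) = (m^2 - 1) / (m^2 + 2) of a
#' relative refractive index m. It vanishes at index matching (m = 1) and
#' approaches 1 as m grows without bound.
#'
#' @param m relative refractive index (> 0); vectorized.
#' @return the Lorentz-Lorenz factor, in (-0.5, 1).
#' @examples
#' lorentz_lorenz(1.470 / 1.340)
#' @export
lorentz_lorenz <- function(m) {
  if (any(!is.finite(m)) || any(m <= 0))
    stop("relative index m must be positive and finite", call. = FALSE)
  (m^2 - 1) / (m^2 + 2)
}

#' Maxwell Garnett effective index of a polymer-medium mixture
#'
#' Given the volume fraction `phi` of coating material with intrinsic
#' index n1 dispersed in medium of index nm, returns the effective index
#' n_c satisfying L(n_c / nm) = phi * L(n1 / nm), i.e.
#' n_c = nm * sqrt((1 + 2 phi L1) / (1 - phi L1)) with L1 = L(n1 / nm).
#' Strictly increasing in `phi`, with n_c(0) = nm and n_c(1) = n1.
#'
#' @param phi coating volume fraction in [0, 1]; vectorized.
#' @param constants an [optical_constants] object.
#' @return effective refractive index of the mixture.
#' @examples
#' oc <- optical_constants(1.6019, 1.340, 1.470)
#' mg_effective_index(0.0971, oc)
#' @export
mg_effective_index <- function(phi, constants) {
  stopifnot(inherits(constants, "optical_constants"))
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1))
    stop("volume fraction phi must lie in [0, 1]", call. = FALSE)
  L1 <- lorentz_lorenz(constants$n1 / constants$nm)
  constants$nm * sqrt((1 + 2 * phi * L1) / (1 - phi * L1))
}

#' Invert Maxwell Garnett mixing: volume fraction from measured index
#'
#' Exact inverse of [mg_effective_index]:
#' phi = L(n / nm) / L(n1 / nm). Measured indices slightly below nm (as
#' produced by refractometer noise near zero concentration) are clamped
#' to phi = 0 with a warning; indices above n1 are returned as phi > 1
#' with a warning, for the caller to flag as out-of-model.
#'
#' @param n measured mixture refractive index; vectorized.
#' @param constants an [optical_constants] object.
#' @return volume fraction of coating material.
#' @export
mg_volume_fraction <- function(n, constants) {
  stopifnot(inherits(constants, "optical_constants"))
  if (any(!is.finite(n)) || any(n <= 0))
    stop("measured index must be positive and finite", call. = FALSE)
  below <- n < constants$nm
  if (any(below)) {
    warning(sprintf(
      "%d reading(s) below the medium index nm = %.4f clamped to phi = 0",
      sum(below), constants$nm), call. = FALSE)
    n[below] <- constants$nm
  }
  if (any(n > constants$n1))
    warning("measured index above n1: returned phi > 1 is out of model",
            call. = FALSE)
  L1 <- lorentz_lorenz(constants$n1 / constants$nm)
  lorentz_lorenz(n / constants$nm) / L1
}

#' Diameter shift of a coated sphere
#'
#' The apparent diameter increase of a bead carrying a thin coating of
#' thickness `a_c` and effective index `n_c`:
#' delta_d = 2 a_c (n_c - nm) / (n0 - nm). An index-matched coating
#' (n_c = nm) is optically invisible and produces zero shift.
#'
#' @param a_c coating thickness in nm (>= 0).
#' @param n_c effective refractive index of the coating.
#' @param constants an [optical_constants] object.
#' @return apparent diameter change in nm.
#' @export
coated_sphere_shift <- function(a_c, n_c, constants) {
  stopifnot(inherits(constants, "optical_constants"))
  if (any(a_c < 0)) stop("coating thickness a_c must be >= 0", call. = FALSE)
  2 * a_c * (n_c - constants$nm) / (constants$n0 - constants$nm)
}

#' Scaled diameter shift
#'
#' The combination x = (1/4) (n0/nm - 1) delta_d that appears throughout
#' the grafting-density constraint; it carries units of length (nm).
#'
#' @param delta_d (anchor-corrected) diameter shift in nm.
#' @param constants an [optical_constants] object.
#' @return scaled shift x in nm.
#' @export
scaled_shift <- function(delta_d, constants) {
  stopifnot(inherits(constants, "optical_constants"))
  0.25 * (constants$n0 / constants$nm - 1) * delta_d
}

#' Grafting density consistent with a measured diameter shift
#'
#' A single measurement of the diameter shift constrains the grafting
#' density Gamma_c as a function of the assumed coating thickness a_c:
#'
#'   Gamma_c(a_c | delta_d) = x / (vs L(m1)) *
#'       (a_c^2 + x a_c) / ((3/4) a_c^2 + x a_c + x^2)
#'
#' with x the scaled shift and m1 = n1/nm. This closed form is the exact
#' algebraic inversion of the coated-sphere shift through Maxwell Garnett
#' mixing and the volume-fraction relation phi_c = vs Gamma_c / a_c.
#'
#' @param a_c assumed coating thickness in nm (> 0); vectorized.
#' @param delta_d_corrected anchor-corrected diameter shift in nm.
#' @param v_s optical specific volume of one grafted molecule, nm^3.
#' @param constants an [optical_constants] object.
#' @return grafting density in nm^-2.
#' @export
grafting_constraint <- function(a_c, delta_d_corrected, v_s, constants) {
  gamma <- grafting_constraint_raw(a_c, delta_d_corrected, v_s, constants)
  phi <- gamma * v_s / a_c
  if (any(phi > 1 + 1e-12))
    stop("implied coating volume fraction exceeds 1: infeasible coating",
         call. = FALSE)
  gamma
}

# Closed form without the feasibility guard; the joint solver evaluates it
# at bracket endpoints where the implied volume fraction legitimately
# exceeds 1, and validates feasibility only at the solution.
grafting_constraint_raw <- function(a_c, delta_d_corrected, v_s, constants) {
  stopifnot(inherits(constants, "optical_constants"))
  if (any(a_c <= 0)) stop("coating thickness a_c must be > 0", call. = FALSE)
  if (v_s <= 0) stop("specific volume v_s must be > 0", call. = FALSE)
  L1 <- lorentz_lorenz(constants$n1 / constants$nm)
  x <- scaled_shift(delta_d_corrected, constants)
  (x / (v_s * L1)) * (a_c^2 + x * a_c) / (0.75 * a_c^2 + x * a_c + x^2)
}

#' Coating thickness from a diameter shift at an assumed layer index
#'
#' Exact inverse of [coated_sphere_shift]:
#' a_c = (1/2) (n0 - nm) / (n_c - nm) * delta_d. Used to turn an assay's
#' measured shift into a physical layer thickness when the effective index
#' of the bound-analyte layer is supplied.
#'
#' @param delta_d measured diameter shift in nm.
#' @param n_c_assumed assumed effective index of the layer (must differ
#'   from the medium index).
#' @param constants an [optical_constants] object.
#' @return layer thickness in nm.
#' @export
coating_thickness <- function(delta_d, n_c_assumed, constants) {
  stopifnot(inherits(constants, "optical_constants"))
  if (any(n_c_assumed == constants$nm))
    stop("layer index equals the medium index: thickness is indeterminate",
         call. = FALSE)
  0.5 * (constants$n0 - constants$nm) / (n_c_assumed - constants$nm) * delta_d
}
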