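# Self-consistent inference of polymer-brush grafting density from a
# holographically measured bead diameter shift.
#
# Two independent relations constrain (Gamma_c, a_c): the effective-medium
# grafting constraint from the measured shift, and the Gaussian-brush
# scaling law a_c = ((1/6) l^2 v_s Gamma_c)^(1/3). For diblock-anchored
# brushes the embedded anchor block additionally inflates the substrate
# diameter by delta_d0 = 2 Gamma_c (m_ps / rho_ps), which must be
# subtracted from the measured shift before optical inversion — hence the
# outer fixed-point loop.

#' Polymer descriptors for a grafted brush
#'
#' @param mw_coat molecular weight of the brush-forming (coat) block, kDa.
#' @param monomer_mass monomer mass in Da (44 for ethylene oxide).
#' @param increment incremental contour length per monomer, nm.
#' @param l contour length in nm; derived from `mw_coat`, `monomer_mass`
#'   and `increment` when omitted.
#' @param r_g radius of gyration of the free coil, nm.
#' @param m_ps molecular weight of the embedded anchor block, kDa.
#' @param rho_ps mass density of the anchor-block material, g/cm^3.
#' @param v_s optical specific volume of one coat-block molecule, nm^3.
#' @return an object of class `brush_parameters`.
#' @examples
#' brush_parameters(mw_coat = 34, monomer_mass = 44, increment = 0.28,
#'                  r_g = 9.1, m_ps = 3.8, rho_ps = 1.05, v_s = 44.5)
#' @export
brush_parameters <- function(mw_coat, monomer_mass = 44, increment = 0.28,
                             l = NULL, r_g = 9.1, m_ps = 3.8, rho_ps = 1.05,
                             v_s) {
  vals <- c(mw_coat = mw_coat, monomer_mass = monomer_mass,
            increment = increment, r_g = r_g, m_ps = m_ps,
            rho_ps = rho_ps, v_s = v_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all brush parameters must be positive and finite", call. = FALSE)
  l_derived <- contour_length(mw_coat, monomer_mass, increment)
  if (is.null(l)) {
    l <- l_derived
  } else if (abs(l - l_derived) / l_derived > 0.25) {
    warning(sprintf(
      "supplied contour length %.1f nm differs from the derived %.1f nm by > 25%%",
      l, l_derived), call. = FALSE)
  }
  structure(
    list(mw_coat = mw_coat, monomer_mass = monomer_mass,
         increment = increment, l = l, r_g = r_g,
         m_ps = m_ps, rho_ps = rho_ps, v_s = v_s,
         v_anchor = molecular_volume(m_ps, rho_ps)),
    class = "brush_parameters"
  )
}

#' @export
print.brush_parameters <- function(x, ...) {
  cat("Brush parameters:\n")
  cat(sprintf("  coat block  %.1f kDa (monomer %.0f Da, increment %.2f nm)\n",
              x$mw_coat, x$monomer_mass, x$increment))
  cat(sprintf("  contour length l = %.1f nm, Rg = %.1f nm\n", x$l, x$r_g))
  cat(sprintf("  anchor block %.1f kDa at %.2f g/cm^3 (v = %.2f nm^3)\n",
              x$m_ps, x$rho_ps, x$v_anchor))
  cat(sprintf("  specific volume v_s = %.2f nm^3\n", x$v_s))
  invisible(x)
}

#' Contour length of a linear polymer
#'
#' l = increment * (number of monomers) with the monomer count
#' 1000 * mw_coat / monomer_mass.
#'
#' @param mw_coat coat-block molecular weight, kDa.
#' @param monomer_mass monomer mass, Da.
#' @param increment contour length per monomer, nm.
#' @return contour length in nm.
#' @examples
#' contour_length(34, 44, 0.28) # about 216 nm
#' @export
contour_length <- function(mw_coat, monomer_mass, increment) {
  stopifnot(mw_coat >= 0, monomer_mass > 0, increment > 0)
  increment * (1000 * mw_coat / monomer_mass)
}

#' Gaussian-brush thickness at a given grafting density
#'
#' Scaling prediction for the equilibrium thickness of a Gaussian polymer
#' brush: a_c = ((1/6) l^2 v_s Gamma_c)^(1/3), so thickness grows as the
#' cube root of grafting density.
#'
#' @param gamma_c grafting density in nm^-2 (>= 0); vectorized.
#' @param brush a [brush_parameters] object.
#' @return brush thickness in nm.
#' @export
brush_thickness_scaling <- function(gamma_c, brush) {
  stopifnot(inherits(brush, "brush_parameters"))
  if (any(gamma_c < 0)) stop("grafting density must be >= 0", call. = FALSE)
  (brush$l^2 * brush$v_s * gamma_c / 6)^(1 / 3)
}

# Inverse of the scaling law: grafting density implied by a thickness.
scaling_gamma <- function(a_c, brush) {
  6 * a_c^3 / (brush$l^2 * brush$v_s)
}

#' Substrate diameter increase from embedded anchor blocks
#'
#' Each grafted chain buries an anchor block of volume m_ps / rho_ps inside
#' the substrate bead. Volume conservation in a thin shell gives a shell
#' thickness Gamma_c * v_anchor, hence a diameter increase
#' delta_d0 = 2 Gamma_c v_anchor, linear in the grafting density.
#'
#' @param gamma_c grafting density in nm^-2 (>= 0); vectorized.
#' @param brush a [brush_parameters] object.
#' @return anchor-induced diameter increase in nm.
#' @export
anchor_shift <- function(gamma_c, brush) {
  stopifnot(inherits(brush, "brush_parameters"))
  if (any(gamma_c < 0)) stop("grafting density must be >= 0", call. = FALSE)
  2 * gamma_c * brush$v_anchor
}

#' Solve jointly for grafting density and brush thickness
#'
#' Finds the intersection of the effective-medium grafting constraint
#' (conditioned on the measured diameter shift, corrected self-consistently
#' for the anchor-block contribution) with the Gaussian-brush scaling law.
#' The outer loop iterates the anchor correction on Gamma_c; the inner
#' 1-D problem brackets and solves for a_c with [stats::uniroot].
#'
#' @param delta_d_measured measured total diameter shift in nm (> 0).
#' @param constants an [optical_constants] object.
#' @param brush a [brush_parameters] object.
#' @param ac_bracket search interval for the thickness root, nm.
#' @param tol convergence tolerance on a_c for the inner root solve, nm.
#' @param max_iter maximum outer fixed-point iterations.
#' @return an object of class `coating_solution` with elements
#'   `gamma_c`, `a_c`, `phi_c`, `n_c`, `x`, `delta_d0`,
#'   `delta_d_measured`, and convergence diagnostics.
#' @examples
#' oc <- optical_constants(1.6019, 1.340, 1.470)
#' br <- brush_parameters(mw_coat = 34, v_s = 44.5)
#' solve_grafting(3.3, oc, br)
#' @export
solve_grafting <- function(delta_d_measured, constants, brush,
                           ac_bracket = c(0.01, 1000), tol = 1e-12,
                           max_iter = 100) {
  stopifnot(inherits(constants, "optical_constants"),
            inherits(brush, "brush_parameters"))
  if (!is.finite(delta_d_measured) || delta_d_measured <= 0)
    stop("measured diameter shift must be positive", call. = FALSE)

  gamma <- 0
  a_c <- NA_real_
  converged <- FALSE
  iters <- 0L
  for (i in seq_len(max_iter)) {
    iters <- i
    dd <- delta_d_measured - anchor_shift(gamma, brush)
    if (dd <= 0)
      stop("anchor correction exceeds the measured shift: no solution",
           call. = FALSE)
    f <- function(ac) {
      grafting_constraint_raw(ac, dd, brush$v_s, constants) -
        scaling_gamma(ac, brush)
    }
    flo <- f(ac_bracket[1]); fhi <- f(ac_bracket[2])
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
      stop(sprintf(
        "no bracketed thickness root in [%g, %g] nm for shift %.3g nm",
        ac_bracket[1], ac_bracket[2], delta_d_measured), call. = FALSE)
    a_c <- stats::uniroot(f, ac_bracket, tol = tol)$root
    gamma_new <- scaling_gamma(a_c, brush)
    if (abs(gamma_new - gamma) < 1e-12) {
      gamma <- gamma_new
      converged <- TRUE
      break
    }
    gamma <- gamma_new
  }
  if (!converged)
    warning("anchor-correction fixed point did not converge to 1e-12 in ",
            max_iter, " iterations", call. = FALSE)

  delta_d0 <- anchor_shift(gamma, brush)
  dd_corr <- delta_d_measured - delta_d0
  phi_c <- brush$v_s * gamma / a_c
  if (phi_c > 1)
    stop("solution implies coating volume fraction > 1: infeasible",
         call. = FALSE)
  structure(
    list(gamma_c = gamma, a_c = a_c, phi_c = phi_c,
         n_c = mg_effective_index(phi_c, constants),
         x = scaled_shift(dd_corr, constants),
         delta_d0 = delta_d0,
         delta_d_measured = delta_d_measured,
         sigma_gamma_c = NA_real_, sigma_a_c = NA_real_,
         iterations = iters, converged = converged),
    class = "coating_solution"
  )
}

#' @export
print.coating_solution <- function(x, ...) {
  cat("Coating solution (effective-medium + brush scaling):\n")
  fmt <- function(v, s, unit) {
    if (is.finite(s)) sprintf("%.4g +/- %.2g %s", v, s, unit)
    else sprintf("%.4g %s", v, unit)
  }
  cat("  grafting density Gamma_c =",
      fmt(x$gamma_c, x$sigma_gamma_c, "nm^-2"), "\n")
  cat("  coating thickness a_c    =", fmt(x$a_c, x$sigma_a_c, "nm"), "\n")
  cat(sprintf("  volume fraction phi_c    = %.4f\n", x$phi_c))
  cat(sprintf("  effective index n_c      = %.4f\n", x$n_c))
  cat(sprintf("  anchor shift delta_d0    = %.3f nm (of %.3f nm measured)\n",
              x$delta_d0, x$delta_d_measured))
  invisible(x)
}

#' Monte Carlo uncertainty propagation for the grafting solve
#'
#' Resamples the measured shift, the coating and medium indices, and the
#' specific volume from independent normal distributions, re-solves the
#' joint constraint for each draw, and reports sample standard deviations
#' of Gamma_c and a_c. Deterministic given `seed`. Draws for which the
#' solve fails (e.g. infeasible coating) are dropped; the fraction kept is
#' reported.
#'
#' @param delta_d measured shift in nm.
#' @param sigma_delta_d 1-sigma uncertainty of the shift, nm.
#' @param constants an [optical_constants] object (its `sigma_*` fields
#'   drive the index resampling).
#' @param brush a [brush_parameters] object.
#' @param sigma_v_s 1-sigma uncertainty of the specific volume, nm^3.
#' @param n_draws number of Monte Carlo draws (>= 100).
#' @param seed integer RNG seed.
#' @return a `coating_solution` for the central values whose
#'   `sigma_gamma_c` and `sigma_a_c` fields are filled in, with extra
#'   fields `n_draws`, `n_ok`, and `method = "monte-carlo"`.
#' @export
propagate_uncertainty <- function(delta_d, sigma_delta_d, constants, brush,
                                  sigma_v_s = 0, n_draws = 2000, seed = 1) {
  stopifnot(inherits(constants, "optical_constants"),
            inherits(brush, "brush_parameters"))
  if (sigma_delta_d < 0 || sigma_v_s < 0)
    stop("uncertainties must be non-negative", call. = FALSE)
  if (n_draws < 100) stop("n_draws must be at least 100", call. = FALSE)

  central <- solve_grafting(delta_d, constants, brush)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  dd <- stats::rnorm(n_draws, delta_d, sigma_delta_d)
  n1 <- stats::rnorm(n_draws, constants$n1, constants$sigma_n1)
  nm <- stats::rnorm(n_draws, constants$nm, constants$sigma_nm)
  vs <- stats::rnorm(n_draws, brush$v_s, sigma_v_s)

  gam <- ac <- rep(NA_real_, n_draws)
  for (i in seq_len(n_draws)) {
    res <- try({
      oc_i <- optical_constants(constants$n0, nm[i], n1[i])
      br_i <- brush
      br_i$v_s <- vs[i]
      solve_grafting(dd[i], oc_i, br_i)
    }, silent = TRUE)
    if (!inherits(res, "try-error")) {
      gam[i] <- res$gamma_c
      ac[i] <- res$a_c
    }
  }
  ok <- is.finite(gam)
  if (!any(ok))
    stop("uncertainty propagation failed: no feasible Monte Carlo draws",
         call. = FALSE)
  central$sigma_gamma_c <- stats::sd(gam[ok])
  central$sigma_a_c <- stats::sd(ac[ok])
  central$n_draws <- n_draws
  central$n_ok <- sum(ok)
  central$method <- "monte-carlo"
  central
}

#' Brush-regime diagnostics
#'
#' The mean in-plane separation between grafting points is
#' Gamma_c^(-1/2). When this separation is strictly smaller than the
#' coil's radius of gyration the chains crowd and stretch into a brush;
#' otherwise they remain isolated mushrooms. Equality is classified as
#' mushroom (conservative labeling of steric protection).
#'
#' @param gamma_c grafting density in nm^-2 (> 0).
#' @param brush a [brush_parameters] object (supplies `r_g`).
#' @return a list with `mean_separation` (nm) and `regime`
#'   ("brush" or "mushroom").
#' @export
brush_diagnostics <- function(gamma_c, brush) {
  stopifnot(inherits(brush, "brush_parameters"))
  if (!is.finite(gamma_c) || gamma_c <= 0)
    stop("grafting density must be positive", call. = FALSE)
  sep <- gamma_c^(-0.5)
  list(mean_separation = sep,
       regime = if (sep < brush$r_g) "brush" else "mushroom")
}
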