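# Optical specific volume from refractometer dilution series.
#
# For each molecular weight, a serial dilution gives (concentration, index)
# pairs; Maxwell Garnett inversion converts indices to polymer volume
# fractions, and the slope of phi against number density is the
# per-molecule specific volume v_s. Across molecular weights, v_s grows
# linearly; its slope dv_s/dm_w lets v_s be predicted at any chain length.

#' Convert a refractometry series to volume fractions
#'
#' Applies the Maxwell Garnett inversion phi = L(n/nm) / L(n1/nm) to each
#' reading and converts mass concentrations to molecular number densities.
#' Readings with an index above the pure-polymer index n1 are physically
#' impossible and are excluded (flagged `valid = FALSE`); readings slightly
#' below nm clamp to phi = 0 (see [mg_volume_fraction]).
#'
#' @param readings data frame with columns `mw_kda`, `concentration`,
#'   `concentration_unit` ("g/cm3" or "percent_wv"), `n_measured`.
#' @param constants an [optical_constants] object (`nm`, `n1` used).
#' @return the input with added columns `c_mass` (g/cm^3), `c_number`
#'   (molecules/nm^3), `phi`, and `valid`.
#' @export
series_to_phi <- function(readings, constants) {
  stopifnot(inherits(constants, "optical_constants"))
  req <- c("mw_kda", "concentration", "concentration_unit", "n_measured")
  missing_cols <- setdiff(req, names(readings))
  if (length(missing_cols))
    stop("readings lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(readings) == 0) stop("no refractometry readings", call. = FALSE)
  unit <- readings$concentration_unit
  bad_unit <- !unit %in% c("g/cm3", "percent_wv")
  if (any(bad_unit))
    stop("unknown concentration unit: ",
         paste(unique(unit[bad_unit]), collapse = ", "), call. = FALSE)
  c_mass <- ifelse(unit == "percent_wv",
                   percent_wv_to_g_cm3(readings$concentration),
                   readings$concentration)
  readings$c_mass <- c_mass
  readings$c_number <- number_density(c_mass, 1) / readings$mw_kda
  valid <- readings$n_measured <= constants$n1
  if (any(!valid))
    message(sum(!valid), " reading(s) with n above n1 excluded as invalid")
  phi <- rep(NA_real_, nrow(readings))
  phi[valid] <- mg_volume_fraction(readings$n_measured[valid], constants)
  readings$phi <- phi
  readings$valid <- valid
  readings
}

#' Fit the optical specific volume for one molecular weight
#'
#' Ordinary least squares of volume fraction on molecular number density,
#' through the origin (phi must vanish at zero concentration). The slope
#' is v_s in nm^3. A free-intercept refit is run as a diagnostic and a
#' warning raised if its intercept is more than 2 standard errors from 0.
#'
#' @param phi_table output of [series_to_phi] restricted to one molecular
#'   weight (rows with `valid = FALSE` are dropped).
#' @param min_points minimum number of usable points (default 3).
#' @return a list with `v_s`, `se`, `r_squared`, `sigma` (residual sd),
#'   `n_points`, `intercept_diag` (free-intercept estimate and se).
#' @export
fit_specific_volume <- function(phi_table, min_points = 3) {
  stopifnot(is.data.frame(phi_table))
  tb <- phi_table[phi_table$valid & is.finite(phi_table$phi), , drop = FALSE]
  if (nrow(tb) < min_points)
    stop(sprintf("need at least %d usable readings, got %d",
                 min_points, nrow(tb)), call. = FALSE)
  pos <- tb$c_number[tb$c_number > 0]
  if (length(pos) >= 2 && max(pos) / min(pos) < 4)
    warning("concentration series spans less than a 4-fold range",
            call. = FALSE)
  fit <- stats::lm(phi ~ c_number + 0, data = tb)
  slope <- unname(stats::coef(fit)[1])
  if (slope <= 0)
    stop("fitted specific volume is not positive: fit failure", call. = FALSE)
  se <- unname(sqrt(diag(stats::vcov(fit)))[1])
  sm <- summary(fit)
  diag_fit <- stats::lm(phi ~ c_number, data = tb)
  ic <- stats::coef(summary(diag_fit))
  intercept_diag <- c(estimate = unname(ic[1, 1]), se = unname(ic[1, 2]))
  if (abs(intercept_diag["estimate"]) > 2 * intercept_diag["se"])
    warning(sprintf(
      "free-intercept diagnostic: intercept %.2g is > 2 se from 0",
      intercept_diag["estimate"]), call. = FALSE)
  list(v_s = slope, se = se,
       r_squared = sm$r.squared, sigma = sm$sigma,
       n_points = nrow(tb), intercept_diag = intercept_diag)
}

#' Fit the differential specific volume across molecular weights
#'
#' Weighted least squares of v_s on molecular weight, weights 1/se^2.
#' The slope is the differential specific volume dv_s/dm_w in nm^3/kDa.
#'
#' @param vs_by_mw data frame with columns `mw_kda`, `v_s`, and optionally
#'   `se` (when absent or all zero, the fit is unweighted).
#' @return a list with `dvdm`, `se`, `intercept`, `intercept_se`,
#'   `r_squared`, `n_mw`.
#' @export
fit_differential_specific_volume <- function(vs_by_mw) {
  stopifnot(is.data.frame(vs_by_mw),
            all(c("mw_kda", "v_s") %in% names(vs_by_mw)))
  if (nrow(vs_by_mw) < 3)
    stop("need specific volumes for at least 3 molecular weights",
         call. = FALSE)
  w <- NULL
  if ("se" %in% names(vs_by_mw) && all(is.finite(vs_by_mw$se)) &&
      all(vs_by_mw$se > 0)) {
    w <- 1 / vs_by_mw$se^2
  }
  fit <- stats::lm(v_s ~ mw_kda, data = vs_by_mw, weights = w)
  co <- stats::coef(summary(fit))
  if (co["mw_kda", "Estimate"] <= 0)
    stop("fitted differential specific volume is not positive",
         call. = FALSE)
  list(dvdm = unname(co["mw_kda", "Estimate"]),
       se = unname(co["mw_kda", "Std. Error"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       intercept_se = unname(co["(Intercept)", "Std. Error"]),
       r_squared = summary(fit)$r.squared,
       n_mw = nrow(vs_by_mw))
}

#' Specific volume at an arbitrary molecular weight
#'
#' v_s = dv_s/dm_w * m_w: the specific volume of a chain scales linearly
#' with its molecular weight through the differential specific volume.
#'
#' @param mw molecular weight in kDa (> 0); vectorized.
#' @param dvdm differential specific volume in nm^3/kDa.
#' @return specific volume in nm^3.
#' @examples
#' specific_volume_at(34, 1.308) # about 44.5 nm^3
#' @export
specific_volume_at <- function(mw, dvdm) {
  if (any(mw < 0)) stop("molecular weight must be >= 0", call. = FALSE)
  dvdm * mw
}

#' Full refractometry analysis across molecular weights
#'
#' Convenience wrapper: converts readings to volume fractions, fits v_s
#' per molecular weight, then fits the differential specific volume.
#'
#' @param readings raw readings (see [series_to_phi]).
#' @param constants an [optical_constants] object.
#' @return a list with `per_mw` (data frame of mw_kda, v_s, se,
#'   r_squared, n_points) and `dvdm_fit` (see
#'   [fit_differential_specific_volume]).
#' @export
analyze_refractometry <- function(readings, constants) {
  tab <- series_to_phi(readings, constants)
  mws <- sort(unique(tab$mw_kda))
  per <- do.call(rbind, lapply(mws, function(m) {
    f <- fit_specific_volume(tab[tab$mw_kda == m, , drop = FALSE])
    data.frame(mw_kda = m, v_s = f$v_s, se = f$se,
               r_squared = f$r_squared, n_points = f$n_points)
  }))
  list(per_mw = per, dvdm_fit = fit_differential_specific_volume(per))
}
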