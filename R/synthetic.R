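# Forward generator for synthetic per-particle characterization tables and
# refractometry dilution series.
#
# The generator is strictly forward-only: binding shifts are produced by
# the coated-sphere forward model and indices by Maxwell Garnett mixing,
# so the pipeline's inversions are tested against independent ground
# truth. All draws are deterministic given a seed.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of one synthetic bead population
#'
#' @param name population label.
#' @param mean_d mean diameter, um.
#' @param cv_d fractional diameter polydispersity (sd/mean); default 0.02,
#'   the typical polydispersity of monodisperse polystyrene stock.
#' @param mean_n mean refractive index.
#' @param sd_n index spread; default 0.005.
#' @param fraction mixing weight within the kit.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(name, mean_d, cv_d = 0.02, mean_n,
                            sd_n = 0.005, fraction = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (cv_d < 0 || sd_n < 0 || fraction <= 0 || mean_d <= 0 || mean_n <= 1)
    stop("invalid population spec for '", name, "'", call. = FALSE)
  structure(list(name = name, mean_d = mean_d, cv_d = cv_d,
                 mean_n = mean_n, sd_n = sd_n, fraction = fraction),
            class = "population_spec")
}

#' Per-run instrument drift specification
#'
#' Each run receives one shared offset applied to every particle, drawn
#' uniformly within the configured bounds — emulating run-to-run
#' instrumental variation (e.g. microfluidic-cell differences).
#'
#' @param max_offset_d_nm maximum diameter offset magnitude, nm.
#' @param max_offset_n maximum refractive-index offset magnitude.
#' @return an object of class `run_drift_spec`.
#' @export
run_drift_spec <- function(max_offset_d_nm = 5, max_offset_n = 0.003) {
  if (max_offset_d_nm < 0 || max_offset_n < 0)
    stop("drift bounds must be non-negative", call. = FALSE)
  structure(list(max_offset_d_nm = max_offset_d_nm,
                 max_offset_n = max_offset_n),
            class = "run_drift_spec")
}

#' Default three-population assay kit
#'
#' Polystyrene probe beads, silica probe beads, and larger polystyrene
#' reference beads at equal stoichiometry, with 2% diameter
#' polydispersity. The silica index 1.43 is a typical colloidal-silica
#' value chosen for the generator, not a measured property of any
#' particular stock.
#'
#' @return list of three [population_spec] objects.
#' @export
default_kit <- function() {
  list(
    population_spec("ps_probe", mean_d = 0.9920, mean_n = 1.602,
                    fraction = 1 / 3),
    population_spec("silica_probe", mean_d = 1.0436, mean_n = 1.430,
                    fraction = 1 / 3),
    population_spec("reference", mean_d = 1.3476, mean_n = 1.602,
                    fraction = 1 / 3)
  )
}

#' Default gates matching the default kit
#'
#' Axis-aligned rectangles around the three clusters of [default_kit],
#' wide enough (> 4 sd in every direction) that assignment is essentially
#' error-free, and non-overlapping as rectangles. The probe gates leave
#' headroom above the stock diameter for binding-induced growth.
#'
#' @return list of [population_gate] objects.
#' @export
default_gates <- function() {
  list(
    population_gate("ps_probe", d_min = 0.85, d_max = 1.18,
                    n_min = 1.55, n_max = 1.65),
    population_gate("silica_probe", d_min = 0.90, d_max = 1.25,
                    n_min = 1.38, n_max = 1.48),
    population_gate("reference", d_min = 1.20, d_max = 1.50,
                    n_min = 1.55, n_max = 1.65)
  )
}

#' Generate one synthetic characterization run
#'
#' Draws particles for each population (normal diameter with
#' sd = cv_d * mean_d, normal index), applies one shared drift offset to
#' the whole run, and attaches per-particle measurement-uncertainty
#' columns. Deterministic given `seed`.
#'
#' @param kit list of [population_spec] objects; fractions must sum to 1.
#' @param drift a [run_drift_spec]; NULL for no drift.
#' @param n_particles total particles in the run.
#' @param seed integer RNG seed.
#' @param run_id run label.
#' @param condition condition label (e.g. "pre", "IgG").
#' @param shifts_nm optional named vector of population mean-diameter
#'   increases in nm (binding shifts), applied before the run offset.
#' @param sigma_d_um,sigma_n reported per-particle uncertainties.
#' @return a list with `records` (particle table with columns run_id,
#'   condition, d_um, n, sigma_d_um, sigma_n, true_population) and
#'   `offsets` (the run's drift draw, nm and index units).
#' @export
generate_run <- function(kit, drift = run_drift_spec(), n_particles,
                         seed, run_id = "run1", condition = "pre",
                         shifts_nm = NULL, sigma_d_um = 0.003,
                         sigma_n = 0.001) {
  stopifnot(length(kit) >= 1,
            all(vapply(kit, inherits, TRUE, "population_spec")),
            n_particles >= 1)
  fr <- vapply(kit, `[[`, 1, "fraction")
  if (abs(sum(fr) - 1) > 1e-8)
    stop("population fractions must sum to 1", call. = FALSE)
  nms <- vapply(kit, `[[`, "", "name")
  if (!is.null(shifts_nm)) {
    unknown <- setdiff(names(shifts_nm), nms)
    if (length(unknown))
      stop("binding shift names not in kit: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    counts <- drop(stats::rmultinom(1, n_particles, fr))
    d <- n <- numeric(0)
    pop <- character(0)
    for (i in seq_along(kit)) {
      s <- kit[[i]]
      if (counts[i] == 0) next
      mu_d <- s$mean_d
      if (!is.null(shifts_nm) && s$name %in% names(shifts_nm))
        mu_d <- mu_d + shifts_nm[[s$name]] / 1000
      d <- c(d, stats::rnorm(counts[i], mu_d, s$cv_d * s$mean_d))
      n <- c(n, stats::rnorm(counts[i], s$mean_n, s$sd_n))
      pop <- c(pop, rep(s$name, counts[i]))
    }
    off_d <- off_n <- 0
    if (!is.null(drift)) {
      stopifnot(inherits(drift, "run_drift_spec"))
      off_d <- stats::runif(1, -drift$max_offset_d_nm, drift$max_offset_d_nm)
      off_n <- stats::runif(1, -drift$max_offset_n, drift$max_offset_n)
    }
    records <- data.frame(
      run_id = run_id, condition = condition,
      d_um = d + off_d / 1000, n = n + off_n,
      sigma_d_um = sigma_d_um, sigma_n = sigma_n,
      true_population = pop)
    list(records = records,
         offsets = c(offset_d_nm = off_d, offset_n = off_n))
  })
}

#' Binding specification for the synthetic forward model
#'
#' Describes the analyte layer deposited on one probe population, either
#' directly as a (thickness, layer index) pair or as a grafted-coat state
#' (grafting density, specific volume, thickness) whose effective index
#' follows from Maxwell Garnett mixing. The diameter shift is always
#' produced by the coated-sphere forward model.
#'
#' @param target name of the probe population receiving the layer.
#' @param constants [optical_constants] for that bead type (its `n0`
#'   sets the substrate; `n1` is the layer material index).
#' @param a_c layer thickness, nm.
#' @param n_c effective layer index; when NULL it is derived from
#'   `gamma_c` and `v_s` via phi = v_s * gamma_c / a_c and MG mixing.
#' @param gamma_c,v_s grafted-coat state used when `n_c` is NULL.
#' @return an object of class `binding_spec` with the forward-modeled
#'   `delta_d_nm`.
#' @export
binding_spec <- function(target, constants, a_c, n_c = NULL,
                         gamma_c = NULL, v_s = NULL) {
  stopifnot(inherits(constants, "optical_constants"), a_c > 0)
  if (is.null(n_c)) {
    if (is.null(gamma_c) || is.null(v_s))
      stop("supply either n_c or both gamma_c and v_s", call. = FALSE)
    phi <- v_s * gamma_c / a_c
    if (phi < 0 || phi > 1)
      stop("implied layer volume fraction outside [0, 1]", call. = FALSE)
    n_c <- mg_effective_index(phi, constants)
  }
  dd <- coated_sphere_shift(a_c, n_c, constants)
  if (dd < 0)
    stop("binding spec produces a negative diameter shift", call. = FALSE)
  structure(list(target = target, constants = constants, a_c = a_c,
                 n_c = n_c, delta_d_nm = dd),
            class = "binding_spec")
}

#' Generate a complete synthetic pre/post assay experiment
#'
#' Produces pre-incubation and post-incubation particle tables across
#' replicate runs, with binding shifts applied to the targeted probe
#' populations via the coated-sphere forward model, independent drift
#' offsets per run, and a manifest recording every ground truth for
#' later assertions.
#'
#' @param kit list of [population_spec] objects.
#' @param drift a [run_drift_spec] shared by all runs.
#' @param binding list of [binding_spec] objects (targets must exist in
#'   the kit; the reference population must not be targeted).
#' @param n_particles particles per run.
#' @param n_runs_pre,n_runs_post number of replicate runs per phase.
#' @param seed integer RNG seed.
#' @return a list with `pre` and `post` particle tables, and `manifest`
#'   (population truths, per-run offsets, injected shifts, seed).
#' @export
generate_assay_experiment <- function(kit, drift = run_drift_spec(),
                                      binding = list(), n_particles = 3000,
                                      n_runs_pre = 3, n_runs_post = 3,
                                      seed = 1) {
  nms <- vapply(kit, `[[`, "", "name")
  shifts <- NULL
  if (length(binding)) {
    stopifnot(all(vapply(binding, inherits, TRUE, "binding_spec")))
    tg <- vapply(binding, `[[`, "", "target")
    unknown <- setdiff(tg, nms)
    if (length(unknown))
      stop("binding targets not in kit: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    shifts <- vapply(binding, `[[`, 1, "delta_d_nm")
    names(shifts) <- tg
  }
  pre <- post <- NULL
  offsets <- list()
  for (r in seq_len(n_runs_pre)) {
    g <- generate_run(kit, drift, n_particles, seed = seed + r,
                      run_id = sprintf("pre_%d", r), condition = "pre")
    pre <- rbind(pre, g$records)
    offsets[[sprintf("pre_%d", r)]] <- g$offsets
  }
  for (r in seq_len(n_runs_post)) {
    g <- generate_run(kit, drift, n_particles,
                      seed = seed + 1000L + r,
                      run_id = sprintf("post_%d", r), condition = "post",
                      shifts_nm = shifts)
    post <- rbind(post, g$records)
    offsets[[sprintf("post_%d", r)]] <- g$offsets
  }
  manifest <- list(
    populations = data.frame(
      name = nms,
      mean_d = vapply(kit, `[[`, 1, "mean_d"),
      cv_d = vapply(kit, `[[`, 1, "cv_d"),
      mean_n = vapply(kit, `[[`, 1, "mean_n"),
      sd_n = vapply(kit, `[[`, 1, "sd_n")),
    shifts_nm = if (is.null(shifts)) numeric(0) else shifts,
    offsets = offsets,
    n_particles = n_particles, seed = seed)
  list(pre = pre, post = post, manifest = manifest)
}

#' Generate a synthetic refractometer dilution series
#'
#' For each molecular weight, starts at a stock concentration and
#' serially dilutes by factors of two; indices are produced by the
#' Maxwell Garnett forward model from phi = c_number * v_s(mw) with
#' v_s(mw) = dvdm_truth * mw, plus optional Gaussian index noise.
#'
#' @param dvdm_truth ground-truth differential specific volume, nm^3/kDa.
#' @param mws molecular weights, kDa.
#' @param constants an [optical_constants] object (`nm`, `n1`).
#' @param start_percent_wv stock concentration in % w/v (default 40).
#' @param dilution_steps number of points per series (>= 3), each half
#'   the previous concentration.
#' @param noise_sd_n sd of additive index noise (0 for noiseless).
#' @param seed integer RNG seed (used only when noise_sd_n > 0).
#' @return a readings data frame (columns mw_kda, concentration,
#'   concentration_unit, n_measured) suitable for [series_to_phi].
#' @export
generate_refractometry <- function(dvdm_truth, mws = c(1.5, 4, 6, 8, 20),
                                   constants, start_percent_wv = 40,
                                   dilution_steps = 7, noise_sd_n = 0,
                                   seed = 1) {
  stopifnot(inherits(constants, "optical_constants"),
            dvdm_truth > 0, dilution_steps >= 3)
  out <- NULL
  for (mw in mws) {
    c_mass <- percent_wv_to_g_cm3(start_percent_wv) / 2^(0:(dilution_steps - 1))
    phi <- number_density(c_mass, mw) * specific_volume_at(mw, dvdm_truth)
    if (any(phi >= 1))
      stop("stock concentration implies volume fraction >= 1", call. = FALSE)
    out <- rbind(out, data.frame(
      mw_kda = mw, concentration = c_mass,
      concentration_unit = "g/cm3",
      n_measured = mg_effective_index(phi, constants)))
  }
  if (noise_sd_n > 0) {
    out$n_measured <- with_seed(seed,
      out$n_measured + stats::rnorm(nrow(out), 0, noise_sd_n))
  }
  out
}
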