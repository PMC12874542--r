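# Multi-population holographic binding assay workflow.
#
# Per-particle characterization tables (one row per particle, with
# diameter in um and refractive index) are gated into bead populations by
# rectangular regions of the diameter-index plane, checked for run-to-run
# consistency with two-sample Kolmogorov-Smirnov tests, pooled, and
# differenced against a pre-incubation baseline to yield the diameter
# shift for each bead type. Runs are optionally drift-corrected by the
# deviation of an inert reference-bead population from its ground truth.

UNGATED <- "<ungated>"

#' Rectangular population gate in the diameter-index plane
#'
#' @param name population label.
#' @param d_min,d_max diameter bounds in um (closed lower, open upper).
#' @param n_min,n_max refractive-index bounds (closed lower, open upper).
#' @return an object of class `population_gate`.
#' @export
population_gate <- function(name, d_min, d_max, n_min, n_max) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!(d_min < d_max) || !(n_min < n_max))
    stop("gate bounds must satisfy d_min < d_max and n_min < n_max",
         call. = FALSE)
  structure(list(name = name, d_min = d_min, d_max = d_max,
                 n_min = n_min, n_max = n_max),
            class = "population_gate")
}

# Two axis-aligned rectangles overlap iff their intervals overlap in both
# dimensions (boundaries shared between a closed upper and open lower edge
# do not count).
gates_overlap <- function(g1, g2) {
  d_olap <- g1$d_min < g2$d_max && g2$d_min < g1$d_max
  n_olap <- g1$n_min < g2$n_max && g2$n_min < g1$n_max
  d_olap && n_olap
}

check_gates <- function(gates) {
  stopifnot(length(gates) >= 1L,
            all(vapply(gates, inherits, TRUE, "population_gate")))
  nms <- vapply(gates, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate gate names: ", paste(nms[duplicated(nms)], collapse = ", "),
         call. = FALSE)
  if (length(gates) > 1) {
    for (i in seq_len(length(gates) - 1)) {
      for (j in (i + 1):length(gates)) {
        if (gates_overlap(gates[[i]], gates[[j]]))
          stop(sprintf("gates '%s' and '%s' overlap", nms[i], nms[j]),
               call. = FALSE)
      }
    }
  }
  invisible(nms)
}

#' Assign particles to gated populations
#'
#' Each particle lands in the unique gate containing its (diameter, index)
#' point — membership uses closed lower bounds and open upper bounds — or
#' in the ungated remainder. Gates must be pairwise non-overlapping, so
#' the assignment is a partition.
#'
#' @param records particle table with columns `d_um` and `n`.
#' @param gates list of [population_gate] objects.
#' @return `records` with an added `population` column (ungated rows are
#'   labeled `"<ungated>"`).
#' @export
gate_particles <- function(records, gates) {
  stopifnot(is.data.frame(records),
            all(c("d_um", "n") %in% names(records)))
  check_gates(gates)
  pop <- rep(UNGATED, nrow(records))
  for (g in gates) {
    inside <- records$d_um >= g$d_min & records$d_um < g$d_max &
      records$n >= g$n_min & records$n < g$n_max
    pop[inside] <- g$name
  }
  records$population <- pop
  records
}

#' Kolmogorov-Smirnov consistency check across replicate runs
#'
#' Runs two-sample KS tests on every pair of replicates. A replicate is
#' flagged inconsistent when it rejects against a strict majority of its
#' co-replicates at level `alpha`; flagged replicates are dropped from the
#' retained set. With fewer than two replicates the verdict is trivially
#' consistent (with a warning).
#'
#' @param samples named list of numeric vectors (per-run particle
#'   diameters for one population), each with at least 20 particles.
#' @param alpha significance level for each pairwise test.
#' @return a list with `pairs` (data frame: run_a, run_b, statistic,
#'   p_value, reject), `retained` (character vector of run names), and
#'   `consistent` (TRUE when no run was dropped).
#' @export
ks_consistency <- function(samples, alpha = 0.01) {
  stopifnot(is.list(samples))
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("replicate samples must be named by run", call. = FALSE)
  if (length(samples) < 2) {
    warning("fewer than 2 replicates: consistency is trivial", call. = FALSE)
    return(list(pairs = data.frame(run_a = character(), run_b = character(),
                                   statistic = numeric(), p_value = numeric(),
                                   reject = logical()),
                retained = names(samples), consistent = TRUE))
  }
  small <- vapply(samples, length, 1L) < 20
  if (any(small))
    warning("replicate(s) with fewer than 20 particles: ",
            paste(names(samples)[small], collapse = ", "), call. = FALSE)
  nms <- names(samples)
  idx <- utils::combn(length(nms), 2)
  pairs <- data.frame(run_a = nms[idx[1, ]], run_b = nms[idx[2, ]],
                      statistic = NA_real_, p_value = NA_real_,
                      reject = NA)
  for (k in seq_len(ncol(idx))) {
    kt <- suppressWarnings(
      stats::ks.test(samples[[idx[1, k]]], samples[[idx[2, k]]]))
    pairs$statistic[k] <- unname(kt$statistic)
    pairs$p_value[k] <- kt$p.value
    pairs$reject[k] <- kt$p.value < alpha
  }
  n_rejects <- vapply(nms, function(r) {
    sum(pairs$reject[pairs$run_a == r | pairs$run_b == r])
  }, 1L)
  failed <- nms[n_rejects > (length(nms) - 1) / 2]
  retained <- setdiff(nms, failed)
  if (length(retained) == 0) {
    warning("all replicates mutually inconsistent; retaining all for pooling",
            call. = FALSE)
    retained <- nms
  }
  list(pairs = pairs, retained = retained,
       consistent = length(retained) == length(nms))
}

#' Pool retained replicates into a population summary
#'
#' Particle-level concatenation of the retained replicates, yielding the
#' population mean diameter and index with the standard error of the mean.
#' When per-run correction uncertainties are supplied (from the
#' reference-bead drift correction), they are propagated into the pooled
#' standard error in quadrature with run-size weights.
#'
#' @param replicates named list of particle tables (columns `d_um`, `n`),
#'   one per retained run.
#' @param name population label for the summary.
#' @param extra_se_um optional named vector of per-run correction standard
#'   errors (um) added to the pooled diameter sem in quadrature.
#' @return one-row data frame: name, count, mean_d, sd_d, sem_d, mean_n,
#'   sem_n (diameters in um).
#' @export
pool_population <- function(replicates, name = "population",
                            extra_se_um = NULL) {
  stopifnot(is.list(replicates), length(replicates) >= 1)
  ok <- vapply(replicates, function(r)
    is.data.frame(r) && all(c("d_um", "n") %in% names(r)) && nrow(r) > 0,
    TRUE)
  if (!all(ok)) stop("each replicate must be a non-empty particle table",
                     call. = FALSE)
  d <- unlist(lapply(replicates, `[[`, "d_um"), use.names = FALSE)
  n <- unlist(lapply(replicates, `[[`, "n"), use.names = FALSE)
  N <- length(d)
  sem_d <- stats::sd(d) / sqrt(N)
  if (!is.null(extra_se_um) && length(replicates) > 0) {
    sizes <- vapply(replicates, nrow, 1L)
    w <- sizes / N
    se_r <- extra_se_um[names(replicates)]
    se_r[is.na(se_r)] <- 0
    sem_d <- sqrt(sem_d^2 + sum((w * se_r)^2))
  }
  data.frame(name = name, count = N,
             mean_d = mean(d), sd_d = stats::sd(d), sem_d = sem_d,
             mean_n = mean(n), sem_n = stats::sd(n) / sqrt(N))
}

#' Diameter shift between pre- and post-incubation summaries
#'
#' delta_dp = (mean_d_post - mean_d_pre) * 1000, in nm, with the standard
#' error combining both summaries in quadrature. The two summaries must
#' describe the same population.
#'
#' @param pre,post one-row population summaries (from [pool_population]).
#' @return a list with `delta_dp` and `se`, both in nm.
#' @export
diameter_shift <- function(pre, post) {
  stopifnot(is.data.frame(pre), is.data.frame(post),
            nrow(pre) == 1, nrow(post) == 1)
  if (!identical(pre$name, post$name))
    stop(sprintf("population mismatch: pre '%s' vs post '%s'",
                 pre$name, post$name), call. = FALSE)
  list(delta_dp = (post$mean_d - pre$mean_d) * 1000,
       se = sqrt(pre$sem_d^2 + post$sem_d^2) * 1000)
}

#' Reference-bead drift correction of per-run summaries
#'
#' For each run, the deviation delta_ref of the reference population's
#' mean diameter from a nominal ground truth is subtracted from every
#' population's mean diameter in that run, canceling run-to-run
#' instrumental offsets shared by all beads in the run. The reference
#' population maps exactly onto the ground truth after correction. Runs
#' lacking a reference population cannot be corrected and are dropped
#' with a message.
#'
#' @param summaries data frame of per-run population summaries with
#'   columns `run_id`, `name`, `mean_d`, `sem_d` (um).
#' @param ground_truth_d nominal reference-bead mean diameter, um.
#' @param reference name of the reference population.
#' @return a list with `summaries` (corrected; non-reference rows carry
#'   the reference sem folded into `sem_d`) and `corrections` (data
#'   frame: run_id, delta_ref_nm, se_ref_nm, ground_truth_d).
#' @export
reference_correction <- function(summaries, ground_truth_d,
                                 reference = "reference") {
  stopifnot(is.data.frame(summaries),
            all(c("run_id", "name", "mean_d", "sem_d") %in% names(summaries)))
  runs <- unique(summaries$run_id)
  has_ref <- vapply(runs, function(r)
    any(summaries$run_id == r & summaries$name == reference), TRUE)
  if (any(!has_ref)) {
    message("run(s) without reference population dropped: ",
            paste(runs[!has_ref], collapse = ", "))
    summaries <- summaries[summaries$run_id %in% runs[has_ref], , drop = FALSE]
    runs <- runs[has_ref]
  }
  if (length(runs) == 0)
    stop("no run contains the reference population '", reference, "'",
         call. = FALSE)
  corrections <- data.frame(run_id = runs, delta_ref_nm = NA_real_,
                            se_ref_nm = NA_real_,
                            ground_truth_d = ground_truth_d)
  for (i in seq_along(runs)) {
    ref_row <- summaries[summaries$run_id == runs[i] &
                           summaries$name == reference, , drop = FALSE]
    delta_um <- ref_row$mean_d - ground_truth_d
    corrections$delta_ref_nm[i] <- delta_um * 1000
    corrections$se_ref_nm[i] <- ref_row$sem_d * 1000
    in_run <- summaries$run_id == runs[i]
    summaries$mean_d[in_run] <- summaries$mean_d[in_run] - delta_um
    not_ref <- in_run & summaries$name != reference
    summaries$sem_d[not_ref] <-
      sqrt(summaries$sem_d[not_ref]^2 + ref_row$sem_d^2)
  }
  list(summaries = summaries, corrections = corrections)
}

#' Classify an assay response
#'
#' A shift is called positive when it exceeds `k` standard errors, negative
#' when its magnitude is within `k` standard errors, and indeterminate when
#' it is more than `k` standard errors *below* zero — apparent shrinkage is
#' unphysical for binding and is flagged for quality control.
#'
#' @param delta_dp diameter shift in nm; vectorized.
#' @param se standard error of the shift (> 0); vectorized.
#' @param k call threshold in units of se (default 3).
#' @return character vector: "positive", "negative", or "indeterminate".
#' @export
analyte_call <- function(delta_dp, se, k = 3) {
  if (any(se <= 0)) stop("standard error must be positive", call. = FALSE)
  ifelse(delta_dp > k * se, "positive",
         ifelse(delta_dp < -k * se, "indeterminate", "negative"))
}

#' Analyte layer thickness from an assay shift
#'
#' Delegates to [coating_thickness] with a configured effective index for
#' the bound-analyte layer; the standard error propagates linearly.
#'
#' @param delta_dp diameter shift in nm.
#' @param se standard error of the shift, nm.
#' @param constants an [optical_constants] object for the bead type.
#' @param n_c_layer effective index of the analyte layer, or NULL when
#'   unconfigured (thickness is then reported unavailable).
#' @return a list with `a_c` and `se` in nm (both NA when `n_c_layer` is
#'   NULL).
#' @export
analyte_thickness <- function(delta_dp, se, constants, n_c_layer = NULL) {
  if (is.null(n_c_layer))
    return(list(a_c = NA_real_, se = NA_real_))
  a <- coating_thickness(delta_dp, n_c_layer, constants)
  scale <- abs(0.5 * (constants$n0 - constants$nm) /
                 (n_c_layer - constants$nm))
  list(a_c = a, se = scale * se)
}

# Per-run, per-population summaries of a gated particle table.
summarize_runs <- function(gated) {
  stopifnot(all(c("run_id", "population", "d_um", "n") %in% names(gated)))
  gated <- gated[gated$population != UNGATED, , drop = FALSE]
  parts <- split(gated, list(gated$run_id, gated$population), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(p) {
    s <- pool_population(list(p), name = p$population[1])
    cbind(data.frame(run_id = p$run_id[1]), s)
  }))
  rownames(out) <- NULL
  out
}

#' Run a full pre/post binding assay
#'
#' End-to-end workflow: gate both particle tables, optionally apply the
#' reference-bead drift correction to each run, check replicate
#' consistency per population with Kolmogorov-Smirnov tests, pool the
#' retained replicates, and compute each population's diameter shift and
#' binding call. When optical constants and an analyte-layer index are
#' configured, the shift is also converted to a layer thickness.
#'
#' @param pre,post particle tables (columns `run_id`, `d_um`, `n`).
#' @param gates list of [population_gate] objects.
#' @param reference name of the reference population, or NULL to skip
#'   drift correction.
#' @param ground_truth_d reference ground-truth mean diameter (um);
#'   required when `reference` is given.
#' @param alpha significance level for the KS consistency tests.
#' @param threshold_k call threshold for [analyte_call].
#' @param constants optional named list of [optical_constants], keyed by
#'   population name, for thickness estimates.
#' @param n_c_layer optional effective index of the analyte layer.
#' @param ks_center whether to mean-center each replicate before the KS
#'   consistency test. Defaults to TRUE when reference correction is
#'   active: run-to-run mean offsets are then explicitly modeled and
#'   removed by the reference standard (with their residual propagated
#'   into the pooled standard error), so the consistency check should
#'   assess replicability of the distribution's shape rather than
#'   re-detect sub-nanometer residual mean jitter. Without a reference,
#'   raw diameters are compared, so uncorrected drift can fail the check.
#' @return an object of class `assay_result`: list with `results` (one
#'   row per population: delta_dp_nm, se_nm, call, a_c_nm, a_c_se_nm),
#'   `pre_summaries`, `post_summaries`, `corrections`, `ks`, and the
#'   gating counts.
#' @export
run_assay <- function(pre, post, gates, reference = NULL,
                      ground_truth_d = NULL, alpha = 0.01, threshold_k = 3,
                      constants = NULL, n_c_layer = NULL,
                      ks_center = !is.null(reference)) {
  pre_g <- gate_particles(pre, gates)
  post_g <- gate_particles(post, gates)
  counts <- list(
    pre = table(pre_g$population), post = table(post_g$population))

  corrections <- NULL
  extra <- list(pre = NULL, post = NULL)
  if (!is.null(reference)) {
    if (is.null(ground_truth_d))
      stop("ground_truth_d is required for reference correction",
           call. = FALSE)
    for (phase in c("pre", "post")) {
      g <- if (phase == "pre") pre_g else post_g
      sums <- summarize_runs(g)
      rc <- reference_correction(sums, ground_truth_d, reference)
      keep <- g$run_id %in% rc$corrections$run_id
      g <- g[keep, , drop = FALSE]
      shift_um <- rc$corrections$delta_ref_nm[
        match(g$run_id, rc$corrections$run_id)] / 1000
      g$d_um <- g$d_um - shift_um
      se_um <- rc$corrections$se_ref_nm / 1000
      names(se_um) <- rc$corrections$run_id
      extra[[phase]] <- se_um
      rc$corrections$phase <- phase
      corrections <- rbind(corrections, rc$corrections)
      if (phase == "pre") pre_g <- g else post_g <- g
    }
  }

  pops <- setdiff(intersect(unique(pre_g$population),
                            unique(post_g$population)), UNGATED)
  ks_log <- list()
  rows <- list()
  summaries <- list(pre = NULL, post = NULL)
  for (p in pops) {
    pooled <- list()
    for (phase in c("pre", "post")) {
      g <- if (phase == "pre") pre_g else post_g
      gp <- g[g$population == p, , drop = FALSE]
      reps <- split(gp, gp$run_id)
      ks_samples <- lapply(reps, `[[`, "d_um")
      if (ks_center) ks_samples <- lapply(ks_samples, function(d) d - mean(d))
      ks <- ks_consistency(ks_samples, alpha = alpha)
      ks_log[[paste(p, phase, sep = ".")]] <- ks
      reps <- reps[ks$retained]
      # the reference itself is pinned to ground truth; its correction
      # noise must not be double counted
      xse <- if (!is.null(reference) && p != reference) extra[[phase]] else NULL
      pooled[[phase]] <- pool_population(reps, name = p, extra_se_um = xse)
      summaries[[phase]] <- rbind(summaries[[phase]], pooled[[phase]])
    }
    sh <- diameter_shift(pooled$pre, pooled$post)
    th <- analyte_thickness(sh$delta_dp, sh$se,
                            constants = constants[[p]],
                            n_c_layer = if (is.null(constants[[p]])) NULL
                                        else n_c_layer)
    rows[[p]] <- data.frame(
      population = p,
      d0_um = pooled$pre$mean_d, delta_dp_nm = sh$delta_dp, se_nm = sh$se,
      call = analyte_call(sh$delta_dp, sh$se, k = threshold_k),
      a_c_nm = th$a_c, a_c_se_nm = th$se)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results,
                 pre_summaries = summaries$pre,
                 post_summaries = summaries$post,
                 corrections = corrections, ks = ks_log,
                 counts = counts,
                 alpha = alpha, threshold_k = threshold_k),
            class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  cat("Holographic binding assay result",
      sprintf("(call threshold %g se, KS alpha %g):\n", x$threshold_k, x$alpha))
  df <- x$results
  df$delta_dp <- sprintf("%.1f +/- %.1f nm", df$delta_dp_nm, df$se_nm)
  print(df[, c("population", "d0_um", "delta_dp", "call")], row.names = FALSE)
  if (!is.null(x$corrections))
    cat(sprintf("Reference drift correction applied to %d run(s).\n",
                nrow(x$corrections)))
  invisible(x)
}
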