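# Small helper: per-run, per-population summaries of a gated table.
run_summaries <- function(gated) {
  gated <- gated[gated$population != "<ungated>", , drop = FALSE]
  parts <- split(gated, list(gated$run_id, gated$population), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(p) {
    data.frame(run_id = p$run_id[1], name = p$population[1],
               mean_d = mean(p$d_um),
               sem_d = sd(p$d_um) / sqrt(nrow(p)))
  }))
  rownames(out) <- NULL
  out
}

test_that("gating partitions particles into non-overlapping boxes", {
  gates <- list(
    population_gate("a", 0.9, 1.1, 1.55, 1.65),
    population_gate("b", 1.2, 1.5, 1.55, 1.65))
  rec <- data.frame(d_um = c(1.0, 1.3, 1.9, 0.95),
                    n = c(1.60, 1.60, 1.60, 1.40))
  g <- gate_particles(rec, gates)
  expect_identical(g$population, c("a", "b", "<ungated>", "<ungated>"))
  # boundaries: closed lower, open upper
  edge <- gate_particles(data.frame(d_um = c(0.9, 1.1), n = c(1.6, 1.6)),
                         gates)
  expect_identical(edge$population, c("a", "<ungated>"))
  # counts conserved under partition
  expect_equal(sum(table(g$population)), nrow(rec))
  expect_error(
    check <- gate_particles(rec, list(
      population_gate("a", 0.9, 1.1, 1.55, 1.65),
      population_gate("b", 1.0, 1.5, 1.60, 1.70))), "overlap")
})

test_that("well-separated synthetic clusters gate almost perfectly", {
  g <- generate_run(default_kit(), run_drift_spec(), n_particles = 6000,
                    seed = 101)
  gated <- gate_particles(g$records, default_gates())
  correct <- mean(gated$population == gated$true_population)
  expect_gte(correct, 0.99)
})

test_that("KS consistency passes identical replicates and fails disjoint
           ones", {
  x <- rnorm(200, 1.0, 0.02)
  same <- ks_consistency(list(r1 = x, r2 = x), alpha = 0.01)
  expect_equal(same$pairs$statistic, 0)
  expect_true(same$consistent)

  disj <- ks_consistency(list(r1 = runif(100, 0, 1), r2 = runif(100, 2, 3),
                              r3 = runif(100, 0, 1)), alpha = 0.01)
  expect_true(any(disj$pairs$statistic == 1))
  expect_false("r2" %in% disj$retained)
  expect_true(all(c("r1", "r3") %in% disj$retained))

  expect_warning(one <- ks_consistency(list(r1 = x)), "trivial")
  expect_true(one$consistent)
})

test_that("null replicates from one distribution are retained", {
  set.seed(5150)
  reps <- lapply(1:3, function(i) rnorm(1000, 1.3476, 0.027))
  names(reps) <- paste0("r", 1:3)
  expect_true(ks_consistency(reps, alpha = 0.01)$consistent)
})

test_that("pooling concatenates particles and shrinks the sem", {
  set.seed(77)
  r1 <- data.frame(d_um = rnorm(400, 1.0, 0.02), n = rnorm(400, 1.6, 0.005))
  r2 <- data.frame(d_um = rnorm(400, 1.0, 0.02), n = rnorm(400, 1.6, 0.005))
  single <- pool_population(list(r1), name = "p")
  expect_equal(single$mean_d, mean(r1$d_um))
  expect_equal(single$sem_d, sd(r1$d_um) / sqrt(400))
  both <- pool_population(list(a = r1, b = r2), name = "p")
  expect_equal(both$count, 800)
  expect_equal(both$mean_d, mean(c(r1$d_um, r2$d_um)))
  expect_lt(both$sem_d, single$sem_d)
  expect_lt(both$sem_d, pool_population(list(r2), name = "p")$sem_d)
  expect_error(pool_population(list()), "length")
})

test_that("diameter shift reports nm with quadrature errors", {
  pre <- data.frame(name = "ps_probe", mean_d = 0.9920, sem_d = 0.0006)
  post <- data.frame(name = "ps_probe", mean_d = 1.0080, sem_d = 0.0008)
  sh <- diameter_shift(pre, post)
  expect_equal(sh$delta_dp, 16.0)
  expect_equal(sh$se, 1.0)
  same <- diameter_shift(pre, pre)
  expect_equal(same$delta_dp, 0)
  expect_equal(same$se, sqrt(2) * 0.6, tolerance = 1e-12)
  other <- data.frame(name = "silica_probe", mean_d = 1.05, sem_d = 0.001)
  expect_error(diameter_shift(pre, other), "mismatch")
})

test_that("reference correction subtracts each run's deviation and pins
           the reference to ground truth", {
  sums <- data.frame(
    run_id = c("A", "A", "B", "B"),
    name = c("probe", "reference", "probe", "reference"),
    mean_d = c(0.9950, 1.3526, 0.9910, 1.3476),
    sem_d = rep(5e-4, 4))
  rc <- reference_correction(sums, ground_truth_d = 1.3476,
                             reference = "reference")
  expect_equal(rc$corrections$delta_ref_nm[rc$corrections$run_id == "A"],
               5.0, tolerance = 1e-9)
  expect_equal(rc$corrections$delta_ref_nm[rc$corrections$run_id == "B"],
               0.0, tolerance = 1e-9)
  ref_rows <- rc$summaries[rc$summaries$name == "reference", ]
  expect_equal(ref_rows$mean_d, c(1.3476, 1.3476))
  probe_A <- rc$summaries[rc$summaries$run_id == "A" &
                            rc$summaries$name == "probe", ]
  expect_equal(probe_A$mean_d, 0.9900)
  # run B was already on truth: its probe is untouched
  probe_B <- rc$summaries[rc$summaries$run_id == "B" &
                            rc$summaries$name == "probe", ]
  expect_equal(probe_B$mean_d, 0.9910)
  # correction noise propagates into non-reference sems
  expect_equal(probe_A$sem_d, sqrt(2) * 5e-4, tolerance = 1e-12)

  # a run without the reference population is uncorrectable
  expect_message(
    dropped <- reference_correction(
      rbind(sums, data.frame(run_id = "C", name = "probe",
                             mean_d = 1.0, sem_d = 5e-4)),
      1.3476, reference = "reference"),
    "dropped")
  expect_false("C" %in% dropped$summaries$run_id)
})

test_that("reference correction reduces between-run spread of probe means
           under instrument drift", {
  exp_data <- generate_assay_experiment(
    default_kit(), run_drift_spec(5, 0.003), binding = list(),
    n_particles = 3000, n_runs_pre = 6, n_runs_post = 0, seed = 321)
  gated <- gate_particles(exp_data$pre, default_gates())
  sums <- run_summaries(gated)
  rc <- reference_correction(sums, ground_truth_d = 1.3476,
                             reference = "reference")
  for (p in c("ps_probe", "silica_probe")) {
    v_raw <- var(sums$mean_d[sums$name == p])
    v_cor <- var(rc$summaries$mean_d[rc$summaries$name == p])
    expect_lt(v_cor, v_raw)
  }
})

test_that("binding calls follow the k-sigma rule and are monotone", {
  expect_identical(analyte_call(16, 1), "positive")
  expect_identical(analyte_call(0, 1), "negative")
  expect_identical(analyte_call(-2, 1), "negative")
  expect_identical(analyte_call(8, 2, k = 3), "positive")
  expect_identical(analyte_call(-5, 1), "indeterminate")
  calls <- analyte_call(seq(-10, 10, by = 1), rep(1, 21))
  lv <- c(indeterminate = 0, negative = 1, positive = 2)
  expect_true(all(diff(lv[calls]) >= 0))
  expect_error(analyte_call(1, 0), "positive")
})

test_that("analyte thickness delegates to the coated-sphere inverse", {
  oc <- ps_water_peo()
  th <- analyte_thickness(16, 1, oc, n_c_layer = 1.50)
  expect_equal(th$a_c, coating_thickness(16, 1.50, oc))
  expect_equal(analyte_thickness(32, 1, oc, 1.50)$a_c, 2 * th$a_c)
  expect_equal(analyte_thickness(0, 1, oc, 1.50)$a_c, 0)
  expect_equal(th$se, th$a_c / 16, tolerance = 1e-12)
  none <- analyte_thickness(16, 1, oc, n_c_layer = NULL)
  expect_true(is.na(none$a_c))
})

test_that("the end-to-end assay recovers injected shifts and calls
           binding correctly", {
  oc_ps <- optical_constants(1.6019, 1.340, 1.54)
  oc_si <- optical_constants(1.430, 1.340, 1.54)
  binding <- list(
    binding_spec("ps_probe", oc_ps, a_c = 13, n_c = 1.50),
    binding_spec("silica_probe", oc_si, a_c = 15, n_c = 1.50))
  exp_data <- generate_assay_experiment(
    default_kit(), run_drift_spec(5, 0.003), binding,
    n_particles = 3000, n_runs_pre = 3, n_runs_post = 3, seed = 2024)
  res <- run_assay(exp_data$pre, exp_data$post, default_gates(),
                   reference = "reference", ground_truth_d = 1.3476,
                   constants = list(ps_probe = oc_ps, silica_probe = oc_si),
                   n_c_layer = 1.50)
  expect_s3_class(res, "assay_result")
  tab <- res$results
  truth <- exp_data$manifest$shifts_nm
  for (p in names(truth)) {
    row <- tab[tab$population == p, ]
    expect_identical(row$call, "positive")
    expect_lt(abs(row$delta_dp_nm - truth[[p]]), 3 * row$se_nm)
    # recovered layer thickness near the generating truth
    expect_equal(row$a_c_nm, if (p == "ps_probe") 13 else 15,
                 tolerance = 0.25)
  }
  ref_row <- tab[tab$population == "reference", ]
  expect_identical(ref_row$call, "negative")
  expect_lt(abs(ref_row$delta_dp_nm), 3 * ref_row$se_nm)
})
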