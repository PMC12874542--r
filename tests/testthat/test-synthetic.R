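test_that("generation is deterministic given a seed", {
  a <- generate_run(default_kit(), run_drift_spec(), 500, seed = 3)
  b <- generate_run(default_kit(), run_drift_spec(), 500, seed = 3)
  c <- generate_run(default_kit(), run_drift_spec(), 500, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a$records$d_um, c$records$d_um))
})

test_that("zero-width populations without drift are exactly at their means", {
  kit <- list(population_spec("only", mean_d = 1.0, cv_d = 0,
                              mean_n = 1.6, sd_n = 0, fraction = 1))
  g <- generate_run(kit, drift = NULL, n_particles = 50, seed = 1)
  expect_true(all(g$records$d_um == 1.0))
  expect_true(all(g$records$n == 1.6))
  expect_equal(unname(g$offsets), c(0, 0))
})

test_that("generated marginals match the configured specs", {
  g <- generate_run(default_kit(), drift = NULL, n_particles = 10000,
                    seed = 99)
  rec <- g$records
  for (s in default_kit()) {
    r <- rec[rec$true_population == s$name, ]
    n <- nrow(r)
    sd_d <- s$cv_d * s$mean_d
    # mean within 4 standard errors, sd within 4 of its sampling error
    expect_lt(abs(mean(r$d_um) - s$mean_d), 4 * sd_d / sqrt(n))
    expect_lt(abs(sd(r$d_um) - sd_d), 4 * sd_d / sqrt(2 * n))
    expect_lt(abs(mean(r$n) - s$mean_n), 4 * s$sd_n / sqrt(n))
    # 2% diameter polydispersity by construction
    expect_equal(sd(r$d_um) / mean(r$d_um), 0.02, tolerance = 0.1)
  }
})

test_that("population fractions and run offsets obey their bounds", {
  g <- generate_run(default_kit(), run_drift_spec(5, 0.003), 9000, seed = 12)
  counts <- table(g$records$true_population)
  expect_true(all(abs(counts / 9000 - 1 / 3) < 0.05))
  expect_lte(abs(g$offsets["offset_d_nm"]), 5)
  expect_lte(abs(g$offsets["offset_n"]), 0.003)
  bad_kit <- list(population_spec("a", 1, 0.02, 1.6, 0.005, fraction = 0.6))
  expect_error(generate_run(bad_kit, NULL, 10, seed = 1), "sum to 1")
})

test_that("binding specs forward-model the coated-sphere shift", {
  oc <- optical_constants(1.6019, 1.340, 1.54)
  b <- binding_spec("ps_probe", oc, a_c = 13, n_c = 1.50)
  expect_equal(b$delta_d_nm, 2 * 13 * (1.50 - 1.340) / (1.6019 - 1.340),
               tolerance = 1e-12)
  # index-matched layer is optically invisible
  invisible_layer <- binding_spec("ps_probe", oc, a_c = 13, n_c = 1.340)
  expect_equal(invisible_layer$delta_d_nm, 0)
  # grafted-coat parameterization goes through MG mixing
  g <- binding_spec("ps_probe", oc, a_c = 20, gamma_c = 0.05, v_s = 40)
  expect_equal(g$n_c, mg_effective_index(0.05 * 40 / 20, oc))
  expect_error(binding_spec("p", oc, a_c = 10, gamma_c = 0.5, v_s = 40),
               "volume fraction")
})

test_that("experiment manifests record the injected ground truth", {
  oc <- optical_constants(1.6019, 1.340, 1.54)
  binding <- list(binding_spec("ps_probe", oc, a_c = 13, n_c = 1.50))
  expect_error(
    generate_assay_experiment(default_kit(), binding = list(
      binding_spec("nonexistent", oc, a_c = 13, n_c = 1.50))),
    "not in kit")
  exp_data <- generate_assay_experiment(
    default_kit(), drift = NULL, binding = binding,
    n_particles = 1e5, n_runs_pre = 1, n_runs_post = 1, seed = 6)
  pre_m <- mean(exp_data$pre$d_um[exp_data$pre$true_population == "ps_probe"])
  post_m <- mean(exp_data$post$d_um[
    exp_data$post$true_population == "ps_probe"])
  # law of large numbers: empirical shift approaches the manifest truth
  se_diff_nm <- 0.02 * sqrt(2 / (1e5 / 3)) * 1000
  expect_lt(abs((post_m - pre_m) * 1000 -
                  exp_data$manifest$shifts_nm[["ps_probe"]]),
            4 * se_diff_nm)
  # untargeted populations are unshifted in expectation
  pre_r <- mean(exp_data$pre$d_um[exp_data$pre$true_population == "reference"])
  post_r <- mean(exp_data$post$d_um[
    exp_data$post$true_population == "reference"])
  expect_lt(abs(post_r - pre_r) * 1000, 4 * 0.027 * sqrt(2 / (1e5 / 3)) * 1000)
})

test_that("refractometry generator is forward-only and seeded", {
  oc <- optical_constants(n0 = 1.45, nm = 1.3325, n1 = 1.466)
  t1 <- generate_refractometry(1.308, mws = c(4, 8), constants = oc,
                               noise_sd_n = 2e-4, seed = 5)
  t2 <- generate_refractometry(1.308, mws = c(4, 8), constants = oc,
                               noise_sd_n = 2e-4, seed = 5)
  expect_identical(t1, t2)
  noiseless <- generate_refractometry(1.308, mws = c(4, 8), constants = oc)
  # serial 2x dilution from the stock concentration
  cc <- noiseless$concentration[noiseless$mw_kda == 4]
  expect_equal(cc[1], 0.40)
  expect_equal(cc[-length(cc)] / cc[-1], rep(2, length(cc) - 1))
  expect_error(generate_refractometry(1.308, mws = 4, constants = oc,
                                      dilution_steps = 2), "dilution_steps")
})
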