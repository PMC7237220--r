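test_that("agents are deterministic given the seed", {
  cfg <- agent_config(n_trials = 40, seed = 123)
  a1 <- gen_agent_performance(cfg)
  a2 <- gen_agent_performance(cfg)
  expect_identical(a1$performance, a2$performance)
  expect_identical(a1$scores, a2$scores)
  a3 <- gen_agent_performance(agent_config(n_trials = 40, seed = 124))
  expect_false(identical(a1$scores, a3$scores))
})

test_that("a no-update agent performs identically forever", {
  cfg <- agent_config(beta0 = 0, beta1 = 0, beta2 = 0, zeta = 1e-20,
                      shape_jitter = FALSE, n_trials = 30, seed = 1)
  ap <- gen_agent_performance(cfg)
  expect_lt(diff(range(ap$cv)), 1e-9)
  expect_lt(diff(range(ap$scores)), 1e-6)
})

test_that("an agent at the rewarded variability level scores near 100", {
  # the alternating shape with CV matching the target norm is the
  # maximal-reward performance; verify against the scoring oracle
  m <- 0.6
  a <- 0.4                                   # the printed example's spread
  patt <- m + rep_len(c(-1, 1), 7) * a       # [0.2, 1, ...]
  cv_star <- sqrt(mean((patt - mean(patt))^2)) / mean(patt)
  cfg <- agent_config(beta0 = 0, beta1 = 0, beta2 = 0, zeta = 1e-18,
                      cv_start = cv_star, shape_jitter = FALSE,
                      n_trials = 20, seed = 2)
  ap <- gen_agent_performance(cfg, target_norm = 1.9596)
  expect_true(all(ap$scores > 99.99))
  expect_equal(ap$scores[1],
               compute_score(trial_performance(patt), 1.9596),
               tolerance = 1e-6)
})

test_that("infeasible requested CVs are clipped and flagged", {
  cfg <- agent_config(beta0 = 0.2, beta1 = 0, beta2 = 0, zeta = 1e-6,
                      n_trials = 25, seed = 3)
  ap <- gen_agent_performance(cfg)
  expect_true(any(ap$clipped))
  expect_true(all(ap$performance$iki_ms > 0))
})

test_that("burst signals carry exact ground truth", {
  cfg <- burst_signal_config(burst_rate_per_s = 0, seed = 1)
  quiet <- gen_burst_signal(cfg)
  expect_identical(nrow(quiet$annotations), 0L)
  expect_equal(length(quiet$signal), cfg$fs * cfg$duration_s)
  cfg2 <- burst_signal_config(duration_s = 60, seed = 2)
  s1 <- gen_burst_signal(cfg2)
  s2 <- gen_burst_signal(cfg2)
  expect_identical(s1$signal, s2$signal)
  expect_identical(s1$annotations, s2$annotations)
  # annotations are non-overlapping after merging
  ann <- s1$annotations
  if (nrow(ann) > 1) {
    ends <- ann$onset_s + ann$duration_ms / 1000
    expect_true(all(ann$onset_s[-1] >= ends[-nrow(ann)]))
  }
})

test_that("sampled burst durations follow the requested power law", {
  set.seed(4)
  d <- rtrunc_powerlaw(5000, 1.5)
  expect_true(all(d >= 50 & d <= 2000))
  fit <- duration_distribution(d)
  expect_gt(fit$tau, 1.4)
  expect_lt(fit$tau, 1.6)
})

test_that("R-peak trains have the requested rate and variability", {
  r0 <- gen_rpeaks(60, 0, 60, seed = 1)
  expect_equal(length(r0), 60)              # 60 bpm for 60 s
  expect_equal(hrv_metrics(r0)$cv_ibi, 0)
  expect_equal(hrv_metrics(r0)$mean_hr, 60)
  r <- gen_rpeaks(70, 0.05, 500, seed = 2)  # ~580 beats
  expect_gt(length(r), 500)
  cv <- hrv_metrics(r)$cv_ibi
  expect_lt(abs(cv - 0.05) / 0.05, 0.05)    # within 5% of requested
  expect_identical(r, gen_rpeaks(70, 0.05, 500, seed = 2))
  expect_warning(gen_rpeaks(60, 0.8, 30, seed = 3), "resampled")
})

test_that("group datasets validate, reproduce and inject differences", {
  expect_error(gen_group_dataset(list(a = list()), 4), "2 groups")
  expect_error(gen_group_dataset(list(a = list(), b = list()), 1),
               "2 subjects")
  cfgs <- list(control = list(n_trials = 25),
               anx = list(n_trials = 25, tau_true = 1.3))
  d1 <- gen_group_dataset(cfgs, 2, seed = 9, n_burst_samples = 300)
  d2 <- gen_group_dataset(cfgs, 2, seed = 9, n_burst_samples = 300)
  expect_identical(d1, d2)
  expect_identical(nrow(d1$subjects), 4L)
  expect_true(all(c("subject", "group", "trial", "position", "iki_ms",
                    "kvel", "score") %in% names(d1$performance)))
  # the injected tau difference shows in the ground-truth durations
  tau_hat <- vapply(d1$ground_truth, function(g)
    duration_distribution(g$burst_durations_ms)$tau, numeric(1))
  grp <- d1$subjects$group
  expect_lt(mean(tau_hat[grp == "anx"]), mean(tau_hat[grp == "control"]))
})

test_that("an injected tau shift is detected; a null shift mostly is not", {
  # scaled-down power/calibration study: 8 replicates each, 6 subjects per
  # group, permutation on the per-subject fitted exponents
  p_alt <- vapply(1:8, function(r) {
    cfgs <- list(g1 = list(n_trials = 2, tau_true = 1.7),
                 g2 = list(n_trials = 2, tau_true = 1.4))
    ds <- gen_group_dataset(cfgs, 6, seed = 100 + r,
                            n_burst_samples = 2000)
    tau <- vapply(ds$ground_truth, function(g)
      duration_distribution(g$burst_durations_ms)$tau, numeric(1))
    grp <- ds$subjects$group
    permutation_test(tau[grp == "g1"], tau[grp == "g2"],
                     n_perm = 1000, seed = r)$p
  }, numeric(1))
  expect_gte(mean(p_alt < 0.05), 0.75)
  p_null <- vapply(1:8, function(r) {
    cfgs <- list(g1 = list(n_trials = 2, tau_true = 1.6),
                 g2 = list(n_trials = 2, tau_true = 1.6))
    ds <- gen_group_dataset(cfgs, 6, seed = 200 + r,
                            n_burst_samples = 2000)
    tau <- vapply(ds$ground_truth, function(g)
      duration_distribution(g$burst_durations_ms)$tau, numeric(1))
    grp <- ds$subjects$group
    permutation_test(tau[grp == "g1"], tau[grp == "g2"],
                     n_perm = 1000, seed = r)$p
  }, numeric(1))
  expect_lte(sum(p_null < 0.05), 2)
})
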