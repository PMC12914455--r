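test_that("deterministic cycle matrices produce strictly alternating paths", {
  P <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  cfg <- caregiver_sim_config(state_labels = c("A", "T"),
                              transition_matrix = P, n_transitions = 50,
                              seed = 3)
  path <- attr(simulate_caregiver_sequence(cfg), "state_path")
  expect_true(all(path[-1] != path[-length(path)]))
  expect_lte(length(unique(path)), 2)
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- caregiver_sim_config(duration_s = 120, seed = 17)
  expect_identical(simulate_caregiver_sequence(cfg),
                   simulate_caregiver_sequence(cfg))
  ccfg <- cardiac_sim_config(duration_s = 60, seed = 17)
  expect_identical(simulate_ibi(ccfg), simulate_ibi(ccfg))
  ecfg <- cohort_sim_config(n = 30, seed = 17)
  expect_identical(simulate_cohort(ecfg), simulate_cohort(ecfg))
  e1 <- simulate_eeg(NULL, n_channels = 2, task_duration_s = 5, seed = 17)
  e2 <- simulate_eeg(NULL, n_channels = 2, task_duration_s = 5, seed = 17)
  expect_identical(e1, e2)
})

test_that("empirical transition frequencies converge (uniform 4 states)", {
  cfg <- caregiver_sim_config(state_labels = c("A", "V", "T", "AV"),
                              n_transitions = 100000, seed = 5)
  path <- attr(simulate_caregiver_sequence(cfg), "state_path")
  tm <- estimate_transition_model(path)
  off <- tm$conditional_probs[row(tm$conditional_probs) !=
                                col(tm$conditional_probs)]
  expect_lt(sqrt(mean((off - 1 / 3)^2)), 0.01)
  expect_lt(max(abs(off - 1 / 3)), 0.02)
})

test_that("invalid transition matrices are rejected", {
  expect_error(caregiver_sim_config(
    state_labels = c("A", "V"),
    transition_matrix = matrix(c(0, 0.5, 1, 0), 2, byrow = TRUE)),
    "row-stochastic")
  expect_error(caregiver_sim_config(
    state_labels = c("A", "V"),
    transition_matrix = matrix(c(0.5, 0.5, 1, 0), 2, byrow = TRUE)),
    "zero diagonal")
})

test_that("event logs round-trip to the generating state path", {
  for (s in 1:5) {
    cfg <- caregiver_sim_config(duration_s = 200, seed = s)
    lg <- simulate_caregiver_sequence(cfg)
    sq <- events_to_state_sequence(lg)
    expect_identical(sq$states, attr(lg, "state_path"))
    expect_equal(sq$change_times_s, attr(lg, "change_times_s"),
                 tolerance = 1e-9)
  }
})

test_that("entropy-matched matrices hit their target entropy rate", {
  for (h in c(0, 0.3, 0.79, 1.65, 2.2)) {
    P <- entropy_matched_matrix(h, 8)
    expect_equal(rowSums(P), rep(1, 8), tolerance = 1e-9)
    expect_equal(markov_entropy_rate(P)$value_bits, h, tolerance = 1e-6)
  }
  expect_error(entropy_matched_matrix(3.1, 8), "target_bits")
})

test_that("zero-variability cardiac config gives a constant series", {
  s <- simulate_ibi(cardiac_sim_config(rmssd_target_ms = 0,
                                       duration_s = 60, seed = 1))
  expect_equal(rmssd(s), 0, tolerance = 1e-9)
  expect_equal(stats::sd(s$ibi_ms), 0, tolerance = 1e-9)
})

test_that("planted epochs elevate the in-epoch mean IBI", {
  cfg <- cardiac_sim_config(
    baseline_ibi_ms = 500, rmssd_target_ms = 2,
    decel_epochs = data.frame(onset_s = 100, offset_s = 150,
                              delta_ibi_ms = 30),
    duration_s = 300, seed = 2)
  s <- simulate_ibi(cfg)
  t <- s$beat_times_s[seq_along(s$ibi_ms)]
  inside <- mean(s$ibi_ms[t >= 101 & t < 149])
  outside <- mean(s$ibi_ms[t < 99 | t > 151])
  expect_equal(inside, 530, tolerance = 2)
  expect_equal(inside - outside, 30, tolerance = 3)
})

test_that("sample RMSSD tracks the configured target", {
  r <- sapply(1:50, function(s)
    rmssd(simulate_ibi(cardiac_sim_config(rmssd_target_ms = 11.23,
                                          duration_s = 300, seed = s))))
  expect_lt(abs(mean(r) / 11.23 - 1), 0.15)
})

test_that("cardiac config rejects invalid setups", {
  expect_error(cardiac_sim_config(baseline_ibi_ms = 100), "250")
  expect_error(cardiac_sim_config(rmssd_target_ms = -1))
  expect_error(cardiac_sim_config(
    decel_epochs = data.frame(onset_s = c(0, 5), offset_s = c(10, 15),
                              delta_ibi_ms = 10), duration_s = 60),
    "overlap")
  expect_error(simulate_ibi(cardiac_sim_config(duration_s = 2, seed = 1)),
               "fewer than 10 beats")
})

test_that("null cohort model is uncorrelated; planted slopes recover", {
  null_cfg <- cohort_sim_config(
    n = 10000, beta_entropy_theta = 0, beta_entropy_decel = 0,
    beta_entropy_hrv = 0, beta_hrv_decel = 0,
    covariate_effects = list(age_months = 0, sex = 0,
                             gestational_age_weeks = 0),
    missing_rate_range = c(0, 0), seed = 31)
  d0 <- simulate_cohort(null_cfg)
  cm <- stats::cor(d0[, c("entropy_bits", "rmssd_ms", "sa_duration_s",
                          "deceleration_ms", "theta_change")])
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.03)
  # planted standardized slope recovered by OLS at large n
  cfg <- cohort_sim_config(n = 10000, beta_entropy_hrv = -0.25,
                           missing_rate_range = c(0, 0), seed = 32,
                           covariate_effects = list(
                             age_months = 0, sex = 0,
                             gestational_age_weeks = 0))
  d <- simulate_cohort(cfg)
  b <- stats::coef(stats::lm(scale(rmssd_ms) ~ scale(entropy_bits),
                             data = d))[2]
  expect_equal(unname(b), -0.25, tolerance = 0.02)
})

test_that("MCAR masking is within binomial tolerance and flags recorded", {
  d <- simulate_cohort(cohort_sim_config(n = 104, seed = 33))
  sv <- c("entropy_bits", "rmssd_ms", "mean_hr_bpm", "sa_duration_s",
          "deceleration_ms", "theta_change")
  fr <- colMeans(is.na(d[, sv]))
  expect_true(all(fr >= 0.08 & fr <= 0.26))
  expect_true(all(!is.na(d$age_months)))
  expect_length(attr(d, "missing_rates"), 6)
})

test_that("impossible planted structures are rejected", {
  expect_error(cohort_sim_config(beta_entropy_hrv = -1.2), "betas")
  expect_error(simulate_cohort(cohort_sim_config(
    beta_entropy_hrv = 0.9,
    covariate_effects = list(age_months = 0.3, sex = 0.3,
                             gestational_age_weeks = 0.3), seed = 1)),
    "residual variance")
  expect_error(cohort_sim_config(n = 2), "n must be")
  expect_error(cohort_sim_config(missing_rate_range = c(0.5, 0.2)))
})
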