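sin_seg <- function(f, sr = 250, nch = 1, amp = 1) {
  t(replicate(nch, amp * sin(2 * pi * f * (0:(sr - 1)) / sr)))
}

test_that("windowed power spectrum: Parseval, zero signal, 5 Hz peak", {
  sr <- 250
  seg <- sin_seg(5, sr)
  P <- segment_power_spectrum(seg, sr)
  f <- as.numeric(colnames(P))
  # energy concentrates in the 4-6 Hz main lobe, peak at the 5 Hz bin
  expect_gt(sum(P[f >= 4 & f <= 6]) / sum(P), 0.95)
  expect_equal(f[which.max(P)], 5)
  # Parseval: total one-sided power equals windowed time-domain energy
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(sr - 1)) / (sr - 1))
  expect_equal(sum(P), sum((seg[1, ] * w)^2), tolerance = 1e-6)
  expect_true(all(segment_power_spectrum(matrix(0, 1, sr), sr) == 0))
  expect_error(segment_power_spectrum(matrix(0, 1, 100), 250),
               "1 second")
})

test_that("relative powers of disjoint bands partition the total", {
  set.seed(8)
  sr <- 250
  segs <- array(rnorm(2 * sr * 6), c(2, sr, 6))
  st <- eeg_segment_set(segs, sr, rep("attention", 6))
  bands <- list(c(1, 9), c(10, 24), c(25, 50))
  tot <- Reduce(`+`, lapply(bands, function(b)
    relative_band_power(st, b, total_band = c(1, 50))))
  expect_equal(tot, rep(1, 6), tolerance = 1e-9)
})

test_that("relative theta is scale invariant and frontal-only", {
  set.seed(9)
  sr <- 250
  segs <- array(rnorm(4 * sr * 24), c(4, sr, 24))
  labs <- rep(c("attention", "inattention"), 12)
  st <- eeg_segment_set(segs, sr, labs, frontal_channels = 1:4)
  r1 <- relative_theta(st, min_segments = 20)
  st2 <- eeg_segment_set(segs * 37.5, sr, labs, frontal_channels = 1:4)
  expect_equal(relative_theta(st2, min_segments = 20)$theta_change,
               r1$theta_change, tolerance = 1e-12)
  # adding non-frontal channels with arbitrary content changes nothing
  segs3 <- array(0, c(6, sr, 24))
  segs3[1:4, , ] <- segs
  segs3[5:6, , ] <- array(100 * sin(2 * pi * 5 * (0:(sr - 1)) / sr),
                          c(2, sr, 24))
  st3 <- eeg_segment_set(segs3, sr, labs, frontal_channels = 1:4)
  expect_equal(relative_theta(st3, min_segments = 20)$rel_theta_attention,
               r1$rel_theta_attention, tolerance = 1e-12)
  # swapping condition labels flips the sign of the change score
  st4 <- eeg_segment_set(segs, sr,
                         ifelse(labs == "attention", "inattention",
                                "attention"),
                         frontal_channels = 1:4)
  expect_equal(relative_theta(st4, min_segments = 20)$theta_change,
               -r1$theta_change, tolerance = 1e-12)
})

test_that("pure 5 Hz content saturates the theta band in both conditions", {
  sr <- 250
  segs <- array(rep(sin_seg(5, sr), 22), c(1, sr, 22))
  st <- eeg_segment_set(segs, sr, rep(c("attention", "inattention"), 11))
  r <- relative_theta(st, min_segments = 20)
  expect_gt(r$rel_theta_attention, 0.95)
  expect_gt(r$rel_theta_inattention, 0.95)
  expect_equal(r$theta_change, 0, tolerance = 1e-9)
  expect_equal(r$theta_change,
               r$rel_theta_attention - r$rel_theta_inattention,
               tolerance = 1e-12)
})

test_that("white noise gives relative theta near the bandwidth ratio", {
  set.seed(10)
  sr <- 250
  vals <- replicate(10, {
    segs <- array(rnorm(2 * sr * 30), c(2, sr, 30))
    st <- eeg_segment_set(segs, sr, rep(c("attention", "inattention"), 15))
    r <- relative_theta(st, min_segments = 20)
    c(r$rel_theta_attention, r$theta_change)
  })
  # theta occupies 3 of the 50 unit bins of the 1-50 Hz total band
  expect_lt(abs(mean(vals[1, ]) - 3 / 50), 0.01)
  expect_lt(abs(mean(vals[2, ])), 0.01)
})

test_that("amplitude outlier rejection excludes exactly the planted segment", {
  set.seed(11)
  sr <- 250
  segs <- array(rnorm(2 * sr * 50), c(2, sr, 50))
  segs[, , 17] <- segs[, , 17] * 100
  st <- eeg_segment_set(segs, sr, rep("inattention", 50))
  out <- reject_amplitude_outliers(st, z = 3)
  expect_equal(out$n_rejected, 1L)
  expect_equal(n_segments(out), 49L)
  # identical segments: nothing rejected
  same <- eeg_segment_set(array(rep(segs[, , 1], 10), c(2, sr, 10)),
                          sr, rep("attention", 10))
  expect_equal(reject_amplitude_outliers(same)$n_rejected, 0L)
  # calibrated synthetic noise: rejection stays rare
  st2 <- simulate_eeg(NULL, sr_hz = 250, n_channels = 4,
                      task_duration_s = 100, seed = 5)
  rej <- reject_amplitude_outliers(st2)$n_rejected
  expect_lt(rej / 100, 0.05)
})

test_that("minimum-segment gate is exact at the boundary", {
  sr <- 250
  mk <- function(k) eeg_segment_set(array(rnorm(sr * k), c(1, sr, k)),
                                    sr, rep("attention", k))
  expect_false(enforce_minimum_segments(mk(19)))
  expect_true(enforce_minimum_segments(mk(20)))
  r <- relative_theta(mk(19), min_segments = 20)
  expect_false(r$usable)
  expect_true(is.na(r$theta_change))
})

test_that("a condition with zero segments propagates missing values", {
  sr <- 250
  set.seed(12)
  st <- eeg_segment_set(array(rnorm(sr * 25), c(1, sr, 25)), sr,
                        rep("inattention", 25))
  r <- relative_theta(st, min_segments = 20)
  expect_true(is.na(r$rel_theta_attention))
  expect_true(is.na(r$theta_change))
  expect_false(is.na(r$rel_theta_inattention))
})

test_that("simulated EEG has exact segment shape and planted theta gain", {
  ph <- make_phases(c(0, 20), c(10, 30), 0, 40)
  st <- simulate_eeg(ph, sr_hz = 250, n_channels = 3, theta_gain = 4,
                     seed = 1)
  expect_equal(dim(st$segments)[2], 250)
  expect_equal(n_segments(st), 40L)
  expect_equal(sum(st$condition_labels == "attention"), 20L)
  # gain 4 drives a positive change score in almost all seeds
  chg <- sapply(1:12, function(s) {
    st <- simulate_eeg(make_phases(0, 15, 0, 30), sr_hz = 250,
                       n_channels = 4, theta_gain = 4, seed = s)
    relative_theta(st, min_segments = 20)$theta_change
  })
  expect_gte(mean(chg > 0), 0.95)
  # gain 1: no planted effect, change centered at zero
  chg1 <- sapply(1:12, function(s) {
    st <- simulate_eeg(make_phases(0, 15, 0, 30), sr_hz = 250,
                       n_channels = 4, theta_gain = 1, seed = 100 + s)
    relative_theta(st, min_segments = 20)$theta_change
  })
  expect_lt(abs(mean(chg1)), 0.01)
})

test_that("EEG array round-trips through CSV plus sidecar", {
  set.seed(13)
  m <- matrix(rnorm(3 * 500), 3)
  p <- withr::local_tempfile(fileext = ".csv")
  write_eeg_array(m, 250, p)
  back <- read_eeg_array(p)
  expect_equal(back$sr_hz, 250)
  expect_equal(back$data, m, tolerance = 1e-12)
  expect_equal(back$channel_names, c("E1", "E2", "E3"))
})

test_that("continuous records segment to labeled 1-s windows", {
  ph <- make_phases(2, 6, 0, 10)
  set.seed(14)
  dat <- matrix(rnorm(2 * 250 * 10), 2)
  st <- segment_eeg(dat, 250, ph)
  expect_equal(n_segments(st), 10L)
  expect_equal(st$condition_labels,
               ifelse(seq(0, 9) + 0.5 >= 2 & seq(0, 9) + 0.5 < 6,
                      "attention", "inattention"))
})
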