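full_look <- function(dur = 12, onset = 0)
  looking_record(data.frame(onset_s = onset, offset_s = onset + dur),
                 task_onset_s = onset, task_duration_s = dur)

test_that("hand-traced onset/offset: 5x500 then 8x530 then 6x470", {
  ib <- ibi_series(ibi_ms = c(rep(500, 8), rep(530, 8), rep(470, 8)))
  ph <- detect_sustained_attention(ib, full_look(12))
  sa <- ph[ph$kind == "sustained_attention", ]
  expect_equal(nrow(sa), 1)
  # opens at the first 530 beat (beat 9, t = 4.0 s)
  expect_equal(sa$onset_s, 4.0)
  expect_equal(sa$trigger_beat_index, 9)
  expect_equal(sa$baseline_median_ms, 500)
  # closes at the first 470 beat of the closing 5-run
  expect_equal(sa$offset_s, 4.0 + 8 * 0.53)
  expect_true(replay_sa_onsets(ib, ph))
})

test_that("looking is required at onset (conjunction rule)", {
  ib <- ibi_series(ibi_ms = c(rep(500, 8), rep(530, 8), rep(470, 8)))
  # looking everywhere except around the 530-run onset at t = 4.0
  lk <- looking_record(data.frame(onset_s = c(0, 9), offset_s = c(3.5, 12)),
                       task_onset_s = 0, task_duration_s = 12)
  ph <- detect_sustained_attention(ib, lk)
  expect_equal(sum(ph$kind == "sustained_attention"), 0)
  # absent looking entirely: zero SA phases, still valid
  ph2 <- detect_sustained_attention(
    ib, looking_record(NULL, 0, 12))
  expect_equal(sum(ph2$kind == "sustained_attention"), 0)
})

test_that("flat and purely accelerating series yield no SA", {
  flat <- ibi_series(ibi_ms = rep(500, 30))
  ph <- detect_sustained_attention(flat, full_look(15))
  expect_equal(sum(ph$kind == "sustained_attention"), 0)
  # strictly decreasing IBIs (pure acceleration): nothing exceeds a median
  acc <- ibi_series(ibi_ms = seq(600, 420, by = -6))
  ph2 <- detect_sustained_attention(acc, full_look(15))
  expect_equal(sum(ph2$kind == "sustained_attention"), 0)
})

test_that("detector needs at least 10 task beats", {
  ib <- ibi_series(ibi_ms = rep(500, 5))
  expect_error(detect_sustained_attention(ib, full_look(3)),
               "at least 10 beats")
})

test_that("phases tile the task window and durations add up", {
  expect_equal(total_sa_duration(make_phases(numeric(0), numeric(0))), 0)
  ph <- make_phases(c(2, 12), c(10, 18), 0, 30)
  expect_equal(total_sa_duration(ph), 8 + 6)
  for (s in 1:20) {
    fx <- random_sa_fixture(s)
    ph <- detect_sustained_attention(fx$ibi, fx$looking)
    # brute-force total duration
    sa <- ph[ph$kind == "sustained_attention", ]
    brute <- if (nrow(sa)) sum(sa$offset_s - sa$onset_s) else 0
    expect_equal(total_sa_duration(ph), brute)
    # partition: kinds alternate with no overlap and cover the window
    ph <- ph[order(ph$onset_s), ]
    expect_equal(ph$onset_s[1], attr(ph, "task_onset_s"))
    expect_equal(ph$offset_s[nrow(ph)], attr(ph, "task_end_s"))
    if (nrow(ph) > 1)
      expect_equal(ph$onset_s[-1], ph$offset_s[-nrow(ph)])
    # replay invariant on every emitted phase
    expect_true(replay_sa_onsets(fx$ibi, ph))
  }
})

test_that("deceleration is SA mean IBI minus pre-stimulus mean", {
  # 5 s pre-stimulus at 500 ms, then a detectable 530 ms plateau
  ib <- ibi_series(ibi_ms = c(rep(500, 10), rep(500, 8), rep(530, 12),
                              rep(470, 8)))
  lk <- full_look(17, onset = 5)
  ph <- detect_sustained_attention(ib, lk)
  sa <- ph[ph$kind == "sustained_attention", ]
  expect_equal(nrow(sa), 1)
  dec <- heart_rate_deceleration(ib, ph, prestim_window_s = 5)
  it <- ib$beat_times_s[seq_along(ib$ibi_ms)]
  in_sa <- it >= sa$onset_s & it < sa$offset_s
  pre <- it >= 0 & it < 5
  expect_equal(dec, mean(ib$ibi_ms[in_sa]) - mean(ib$ibi_ms[pre]))
  expect_gt(dec, 0)
  # no SA phase: missing value, not zero
  flat <- ibi_series(ibi_ms = rep(500, 40))
  ph0 <- detect_sustained_attention(flat, full_look(14, onset = 5))
  expect_true(is.na(heart_rate_deceleration(flat, ph0)))
  # no pre-stimulus beats: error
  ib2 <- ibi_series(beat_times_s = seq(6, 20, by = 0.5))
  lk2 <- full_look(14, onset = 6)
  ph2 <- detect_sustained_attention(ib2, lk2)
  expect_error(heart_rate_deceleration(ib2, ph2), "pre-stimulus")
})

test_that("planted decelerations are recovered from the summary", {
  fx <- random_sa_fixture(11)
  ph <- detect_sustained_attention(fx$ibi, fx$looking)
  sm <- attention_summary(fx$ibi, ph)
  expect_equal(sm$total_sa_duration_s, total_sa_duration(ph))
  expect_equal(sm$n_sa_phases, sum(ph$kind == "sustained_attention"))
})

test_that("scaling planted decelerations up does not shrink SA time", {
  wins <- 0
  for (s in 1:10) {
    sa_small <- sa_big <- NA
    for (d in c(1, 2)) {
      delta <- c(8, 30)[d]
      epochs <- data.frame(onset_s = c(30, 120), offset_s = c(70, 160),
                           delta_ibi_ms = delta)
      cfg <- cardiac_sim_config(baseline_ibi_ms = 400, rmssd_target_ms = 6,
                                decel_epochs = epochs, duration_s = 200,
                                seed = s)
      ibi <- simulate_ibi(cfg)
      lk <- looking_record(data.frame(onset_s = 5, offset_s = 195),
                           task_onset_s = 5, task_duration_s = 190)
      sa_d <- total_sa_duration(detect_sustained_attention(ibi, lk))
      if (d == 1) sa_small <- sa_d else sa_big <- sa_d
    }
    if (sa_big >= sa_small) wins <- wins + 1
  }
  expect_gte(wins, 6)  # majority criterion over seeds
})
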