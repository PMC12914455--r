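# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data.

# simple interval event log
make_log <- function(..., duration = NULL) {
  ev <- do.call(rbind, lapply(list(...), function(e)
    data.frame(modality = e[[1]], onset_s = as.numeric(e[[2]]),
               offset_s = as.numeric(e[[3]]))))
  sensory_event_log(ev, duration)
}

# attention_phases data.frame with task-window attributes, for tests that
# need phases without running the detector
make_phases <- function(sa_onsets, sa_offsets, task_onset = 0,
                        task_end = 30) {
  sa <- if (length(sa_onsets)) {
    data.frame(kind = "sustained_attention", onset_s = sa_onsets,
               offset_s = sa_offsets, trigger_beat_index = NA_integer_,
               baseline_median_ms = NA_real_)
  } else {
    data.frame(kind = character(0), onset_s = numeric(0),
               offset_s = numeric(0), trigger_beat_index = integer(0),
               baseline_median_ms = numeric(0))
  }
  attr(sa, "task_onset_s") <- task_onset
  attr(sa, "task_end_s") <- task_end
  class(sa) <- c("attention_phases", "data.frame")
  sa
}

# random dyad-style IBI fixture with planted deceleration steps, used for
# detector replay audits
random_sa_fixture <- function(seed) {
  set.seed(seed)
  n_ep <- sample(1:3, 1)
  starts <- sort(sample(c(10, 60, 110, 160), n_ep))
  epochs <- data.frame(onset_s = starts, offset_s = starts + 30,
                       delta_ibi_ms = runif(n_ep, 10, 40))
  cfg <- cardiac_sim_config(baseline_ibi_ms = 400,
                            rmssd_target_ms = runif(1, 2, 12),
                            decel_epochs = epochs, duration_s = 250,
                            seed = seed)
  ibi <- simulate_ibi(cfg)
  look <- looking_record(data.frame(onset_s = 5, offset_s = 245),
                         task_onset_s = 5, task_duration_s = 240)
  list(ibi = ibi, looking = look, epochs = epochs)
}
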