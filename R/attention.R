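# Heart-rate-defined sustained-attention segmentation and attention indices.
#
# Sustained attention (SA) opens when the infant is looking at the stimulus
# AND five consecutive IBIs each exceed the median of the five baseline IBIs
# preceding the run; it closes when five consecutive IBIs each fall below
# the median of the five IBIs immediately preceding the closing run.
# Baselines are reset after each termination. All non-SA task time is
# labeled inattention.

#' Construct a looking record
#'
#' Manually coded intervals of screen-directed gaze during the attention
#' task.
#'
#' @param intervals data.frame with columns `onset_s`, `offset_s`
#'   (non-overlapping, sorted, within the task window); may have zero rows.
#' @param task_onset_s task (stimulus) start time in seconds.
#' @param task_duration_s stimulus length in seconds (default 281).
#' @return object of class `looking_record`.
#' @export
looking_record <- function(intervals, task_onset_s = 0,
                           task_duration_s = 281) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    intervals <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  }
  stopifnot(all(c("onset_s", "offset_s") %in% names(intervals)),
            task_duration_s > 0)
  intervals <- intervals[order(intervals$onset_s), , drop = FALSE]
  if (nrow(intervals)) {
    if (any(intervals$offset_s <= intervals$onset_s))
      stop("looking intervals need onset_s < offset_s")
    if (any(intervals$onset_s < task_onset_s - 1e-9) ||
        any(intervals$offset_s > task_onset_s + task_duration_s + 1e-9))
      stop("looking intervals must lie within the task window")
    if (nrow(intervals) > 1 &&
        any(intervals$onset_s[-1] < intervals$offset_s[-nrow(intervals)]))
      stop("looking intervals must not overlap")
  }
  rownames(intervals) <- NULL
  structure(list(intervals = intervals,
                 task_onset_s = task_onset_s,
                 task_duration_s = task_duration_s),
            class = "looking_record")
}

#' Read looking intervals from CSV
#'
#' Expects columns `onset_s`, `offset_s`.
#'
#' @param path CSV path.
#' @inheritParams looking_record
#' @return a [looking_record()].
#' @export
read_looking <- function(path, task_onset_s = 0, task_duration_s = 281) {
  looking_record(utils::read.csv(path), task_onset_s, task_duration_s)
}

.in_intervals <- function(t, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(t)))
  vapply(t, function(tt)
    any(intervals$onset_s - 1e-9 <= tt & tt < intervals$offset_s - 1e-12),
    logical(1))
}

#' Detect heart-rate-defined sustained-attention phases
#'
#' Scans task-window IBIs in order. Outside SA a rolling baseline of the
#' `baseline_len` most recent IBIs is maintained; when a run of `run_len`
#' consecutive IBIs each *strictly* exceeds the baseline median and the
#' first beat of the run falls inside a looking interval, an SA phase opens
#' at that beat's time. Within SA, a run of `run_len` consecutive IBIs each
#' strictly below the median of the `baseline_len` IBIs immediately
#' preceding the run closes the phase at the first beat of the closing run.
#' After closure the baseline is re-seeded from post-closure beats (the
#' next onset needs `baseline_len` fresh IBIs). Ties break toward not
#' changing state. A phase still open at the last evaluable beat extends to
#' the end of the task window. All remaining task time is labeled
#' inattention.
#'
#' @param ibi an [ibi_series()]; needs at least 10 beats inside the task
#'   window.
#' @param looking a [looking_record()]; an empty record yields zero SA
#'   phases.
#' @param run_len length of the qualifying run (default 5).
#' @param baseline_len length of the baseline window (default 5).
#' @param require_looking_throughout if `TRUE`, an SA phase is also closed
#'   at the first in-phase beat at which the infant is no longer looking;
#'   by default looking is required only at onset and termination is
#'   governed by the heart-rate criterion.
#' @return data.frame of class `attention_phases` with columns `kind`
#'   (`"sustained_attention"`/`"inattention"`), `onset_s`, `offset_s`,
#'   `trigger_beat_index` (index into the IBI sequence of the opening run's
#'   first beat; `NA` for inattention) and `baseline_median_ms`; attributes
#'   `task_onset_s`, `task_end_s`.
#' @export
detect_sustained_attention <- function(ibi, looking, run_len = 5,
                                       baseline_len = 5,
                                       require_looking_throughout = FALSE) {
  stopifnot(inherits(ibi, "ibi_series"), inherits(looking, "looking_record"))
  t0 <- looking$task_onset_s
  t1 <- t0 + looking$task_duration_s
  nall <- length(ibi$ibi_ms)
  # IBI k (timestamped at its starting beat) is in the window when both its
  # beats are
  inwin <- which(ibi$beat_times_s[seq_len(nall)] >= t0 - 1e-9 &
                 ibi$beat_times_s[seq_len(nall) + 1] <= t1 + 1e-9)
  if (length(inwin) + 1 < 10)
    stop("need at least 10 beats inside the task window")
  x <- ibi$ibi_ms[inwin]
  tt <- ibi$beat_times_s[inwin]
  M <- length(x)
  look_at <- .in_intervals(tt, looking$intervals)
  phases <- list()
  k <- baseline_len + 1
  while (k <= M - run_len + 1) {
    base <- x[(k - baseline_len):(k - 1)]
    bmed <- stats::median(base)
    if (all(x[k:(k + run_len - 1)] > bmed) && look_at[k]) {
      open_idx <- k
      open_t <- tt[k]
      close_idx <- NA_integer_
      close_t <- t1
      j <- k + run_len
      while (j <= M - run_len + 1) {
        if (require_looking_throughout && !look_at[j]) {
          close_idx <- j; close_t <- tt[j]; break
        }
        cmed <- stats::median(x[(j - baseline_len):(j - 1)])
        if (all(x[j:(j + run_len - 1)] < cmed)) {
          close_idx <- j; close_t <- tt[j]; break
        }
        j <- j + 1
      }
      phases[[length(phases) + 1]] <- data.frame(
        kind = "sustained_attention",
        onset_s = open_t, offset_s = close_t,
        trigger_beat_index = inwin[open_idx],
        baseline_median_ms = bmed)
      if (is.na(close_idx)) break
      # re-seed the baseline from the beats following phase offset
      k <- close_idx + baseline_len
    } else {
      k <- k + 1
    }
  }
  sa <- if (length(phases)) do.call(rbind, phases) else
    data.frame(kind = character(0), onset_s = numeric(0),
               offset_s = numeric(0), trigger_beat_index = integer(0),
               baseline_median_ms = numeric(0))
  # tile the task window: the complement of SA is inattention
  gaps <- list()
  cur <- t0
  if (nrow(sa)) {
    for (i in seq_len(nrow(sa))) {
      if (sa$onset_s[i] > cur + 1e-9)
        gaps[[length(gaps) + 1]] <- c(cur, sa$onset_s[i])
      cur <- sa$offset_s[i]
    }
  }
  if (cur < t1 - 1e-9) gaps[[length(gaps) + 1]] <- c(cur, t1)
  inatt <- if (length(gaps)) {
    g <- do.call(rbind, gaps)
    data.frame(kind = "inattention", onset_s = g[, 1], offset_s = g[, 2],
               trigger_beat_index = NA_integer_,
               baseline_median_ms = NA_real_)
  } else sa[0, ]
  out <- rbind(sa, inatt)
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "task_onset_s") <- t0
  attr(out, "task_end_s") <- t1
  class(out) <- c("attention_phases", "data.frame")
  out
}

#' Total sustained-attention duration
#'
#' Sum of phase lengths over phases of kind `"sustained_attention"`, in
#' seconds — the behavioral index of sustained attention.
#'
#' @param phases an `attention_phases` data.frame
#'   (from [detect_sustained_attention()]).
#' @return total duration in seconds.
#' @export
total_sa_duration <- function(phases) {
  sa <- phases[phases$kind == "sustained_attention", , drop = FALSE]
  if (!nrow(sa)) return(0)
  sum(sa$offset_s - sa$onset_s)
}

#' Heart-rate deceleration during sustained attention
#'
#' Mean IBI over all beats inside SA phases minus mean IBI over the
#' `prestim_window_s` seconds immediately preceding task onset. Positive
#' values indicate a slower heart (greater deceleration) during attention.
#' With no SA phases the score is a missing value (`NA`), propagated to the
#' statistical stage rather than coerced to zero.
#'
#' @param ibi an [ibi_series()] covering the pre-stimulus window and task.
#' @param phases an `attention_phases` data.frame.
#' @param prestim_window_s pre-stimulus baseline length in seconds
#'   (default 5).
#' @return mean deceleration in ms (`NA_real_` if no SA phase).
#' @export
heart_rate_deceleration <- function(ibi, phases, prestim_window_s = 5) {
  stopifnot(inherits(ibi, "ibi_series"))
  t0 <- attr(phases, "task_onset_s")
  n <- length(ibi$ibi_ms)
  it <- ibi$beat_times_s[seq_len(n)]
  pre <- ibi$ibi_ms[it >= t0 - prestim_window_s - 1e-9 & it < t0 - 1e-9]
  if (!length(pre)) stop("no beats in the pre-stimulus window")
  sa <- phases[phases$kind == "sustained_attention", , drop = FALSE]
  if (!nrow(sa)) return(NA_real_)
  in_sa <- .in_intervals(it, sa)
  if (!any(in_sa)) return(NA_real_)
  mean(ibi$ibi_ms[in_sa]) - mean(pre)
}

#' Summary of attention indices for one infant
#'
#' @inheritParams heart_rate_deceleration
#' @return object of class `attention_summary`: list with
#'   `total_sa_duration_s`, `mean_deceleration_ms`, `n_sa_phases`,
#'   `prestim_baseline_ibi_ms`.
#' @export
attention_summary <- function(ibi, phases, prestim_window_s = 5) {
  t0 <- attr(phases, "task_onset_s")
  n <- length(ibi$ibi_ms)
  it <- ibi$beat_times_s[seq_len(n)]
  pre <- ibi$ibi_ms[it >= t0 - prestim_window_s - 1e-9 & it < t0 - 1e-9]
  structure(list(
    total_sa_duration_s = total_sa_duration(phases),
    mean_deceleration_ms = heart_rate_deceleration(ibi, phases,
                                                   prestim_window_s),
    n_sa_phases = sum(phases$kind == "sustained_attention"),
    prestim_baseline_ibi_ms = if (length(pre)) mean(pre) else NA_real_),
    class = "attention_summary")
}

#' @export
print.attention_summary <- function(x, ...) {
  cat(sprintf(
    "<attention_summary> %d SA phase(s), %.1f s total; deceleration %s ms\n",
    x$n_sa_phases, x$total_sa_duration_s,
    if (is.na(x$mean_deceleration_ms)) "NA"
    else sprintf("%+.1f", x$mean_deceleration_ms)))
  invisible(x)
}

#' Replay the onset rule for emitted SA phases
#'
#' Re-evaluates, for every sustained-attention phase, the recorded
#' `trigger_beat_index` and `baseline_median_ms` against the IBI series:
#' the onset run must strictly exceed the recorded baseline median. Used as
#' a structural audit of the detector's output.
#'
#' @inheritParams heart_rate_deceleration
#' @param run_len,baseline_len as in [detect_sustained_attention()].
#' @return logical: `TRUE` when every phase replays.
#' @export
replay_sa_onsets <- function(ibi, phases, run_len = 5, baseline_len = 5) {
  sa <- phases[phases$kind == "sustained_attention", , drop = FALSE]
  if (!nrow(sa)) return(TRUE)
  for (i in seq_len(nrow(sa))) {
    k <- sa$trigger_beat_index[i]
    base <- ibi$ibi_ms[(k - baseline_len):(k - 1)]
    if (abs(stats::median(base) - sa$baseline_median_ms[i]) > 1e-9)
      return(FALSE)
    if (!all(ibi$ibi_ms[k:(k + run_len - 1)] > sa$baseline_median_ms[i]))
      return(FALSE)
  }
  TRUE
}
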