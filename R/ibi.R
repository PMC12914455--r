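# Inter-beat-interval series and time-domain baseline HRV metrics.

#' Construct an inter-beat-interval series
#'
#' Holds R-peak times and the derived inter-beat intervals (IBIs), the
#' latency between the R waves of successive heartbeats in milliseconds.
#' IBI `k` spans beats `k` and `k + 1`; throughout the package it is
#' timestamped at its *starting* beat. Values outside the physiologic
#' bounds are flagged, not dropped.
#'
#' @param beat_times_s strictly increasing R-peak times in seconds. Exactly
#'   one of `beat_times_s` / `ibi_ms` must be given.
#' @param ibi_ms successive IBIs in ms (beat times reconstructed from
#'   `start_time_s` by cumulative summation).
#' @param start_time_s time of the first beat when building from `ibi_ms`.
#' @param bounds_ms physiologic IBI bounds used for quality flags
#'   (default 250--1000 ms).
#' @return object of class `ibi_series` with fields `beat_times_s`,
#'   `ibi_ms`, `quality_flags` (per-IBI character: `"ok"`,
#'   `"out_of_bounds"`, `"interpolated"`), `bounds_ms`.
#' @export
ibi_series <- function(beat_times_s = NULL, ibi_ms = NULL, start_time_s = 0,
                       bounds_ms = c(250, 1000)) {
  if (is.null(beat_times_s) == is.null(ibi_ms))
    stop("give exactly one of `beat_times_s` or `ibi_ms`")
  if (is.null(beat_times_s)) {
    if (any(ibi_ms <= 0)) stop("IBIs must be positive")
    beat_times_s <- start_time_s + c(0, cumsum(ibi_ms) / 1000)
  } else {
    if (length(beat_times_s) < 2) stop("need at least 2 beats")
    if (any(diff(beat_times_s) <= 0))
      stop("beat times must be strictly increasing")
    ibi_ms <- diff(beat_times_s) * 1000
  }
  flags <- ifelse(ibi_ms < bounds_ms[1] | ibi_ms > bounds_ms[2],
                  "out_of_bounds", "ok")
  structure(list(beat_times_s = as.numeric(beat_times_s),
                 ibi_ms = as.numeric(ibi_ms),
                 quality_flags = flags,
                 bounds_ms = bounds_ms),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf(
    "<ibi_series> %d beats over %.1f s; mean IBI %.1f ms; %d flagged\n",
    length(x$beat_times_s),
    diff(range(x$beat_times_s)),
    mean(x$ibi_ms),
    sum(x$quality_flags != "ok")))
  invisible(x)
}

#' Read an IBI series from disk
#'
#' Accepts either a CSV with an `ibi_ms` column (optionally `t_s`), or a
#' plain text file of R-peak times, one per line, in seconds.
#'
#' @param path file path.
#' @param bounds_ms passed to [ibi_series()].
#' @return an [ibi_series()].
#' @export
read_ibi <- function(path, bounds_ms = c(250, 1000)) {
  head1 <- readLines(path, n = 1)
  if (grepl("ibi_ms", head1, fixed = TRUE)) {
    df <- utils::read.csv(path)
    if ("t_s" %in% names(df))
      return(ibi_series(ibi_ms = df$ibi_ms, start_time_s = df$t_s[1],
                        bounds_ms = bounds_ms))
    return(ibi_series(ibi_ms = df$ibi_ms, bounds_ms = bounds_ms))
  }
  ibi_series(beat_times_s = scan(path, quiet = TRUE), bounds_ms = bounds_ms)
}

#' Write an IBI series as CSV
#'
#' Columns `beat_index`, `ibi_ms`, `t_s` (time of the IBI's starting beat).
#'
#' @param series an [ibi_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ibi <- function(series, path) {
  stopifnot(inherits(series, "ibi_series"))
  n <- length(series$ibi_ms)
  utils::write.csv(
    data.frame(beat_index = seq_len(n), ibi_ms = series$ibi_ms,
               t_s = series$beat_times_s[seq_len(n)]),
    path, row.names = FALSE)
  invisible(path)
}

#' Flag and repair rule-based IBI artifacts
#'
#' Flags IBIs outside the physiologic bounds and successive jumps larger
#' than `max_jump_ms`, then (optionally) replaces flagged values by linear
#' interpolation from neighboring clean IBIs, marking them
#' `"interpolated"`. A rule-based stand-in for manual beat editing.
#'
#' @param series an [ibi_series()].
#' @param max_jump_ms flag IBIs whose difference from the previous IBI
#'   exceeds this (default 200 ms).
#' @param repair replace flagged IBIs by interpolation (default `TRUE`).
#' @return an [ibi_series()] with updated flags (and values if repaired).
#' @export
clean_ibi <- function(series, max_jump_ms = 200, repair = TRUE) {
  stopifnot(inherits(series, "ibi_series"))
  x <- series$ibi_ms
  bad <- x < series$bounds_ms[1] | x > series$bounds_ms[2]
  jump <- c(FALSE, abs(diff(x)) > max_jump_ms) & !bad
  flag <- bad | jump
  if (repair && any(flag) && any(!flag)) {
    idx <- seq_along(x)
    x[flag] <- stats::approx(idx[!flag], x[!flag], xout = idx[flag],
                             rule = 2)$y
  }
  out <- series
  out$ibi_ms <- x
  out$quality_flags <- ifelse(flag,
                              if (repair) "interpolated" else "out_of_bounds",
                              "ok")
  # beat times are kept as recorded; values are what the repair changes
  out
}

#' Interpolate an IBI tachogram onto a uniform sampling grid
#'
#' Linear interpolation of the IBI-versus-time tachogram (IBI `k` at the
#' time of its starting beat) onto a uniform grid spanning the recording,
#' with endpoints held at the nearest beat's value. The grid signal is kept
#' for spectral extensions; successive-difference statistics such as RMSSD
#' are computed on the beat-domain series (see [rmssd()]).
#'
#' @param series an [ibi_series()].
#' @param grid_hz grid sampling rate in Hz (default 100).
#' @return data.frame with columns `time_s`, `ibi_ms`.
#' @export
interpolate_to_grid <- function(series, grid_hz = 100) {
  stopifnot(inherits(series, "ibi_series"), grid_hz > 0)
  n <- length(series$ibi_ms)
  if (n < 1) stop("need at least 2 beats to interpolate")
  knots_t <- series$beat_times_s[seq_len(n)]
  grid <- seq(series$beat_times_s[1],
              series$beat_times_s[n + 1], by = 1 / grid_hz)
  if (n == 1) {
    return(data.frame(time_s = grid, ibi_ms = rep(series$ibi_ms, length(grid))))
  }
  y <- stats::approx(knots_t, series$ibi_ms, xout = grid, rule = 2)$y
  data.frame(time_s = grid, ibi_ms = y)
}

#' Root mean square of successive differences (RMSSD)
#'
#' \deqn{\mathrm{RMSSD} = \sqrt{\frac{1}{n-1}\sum_{k=1}^{n-1}
#'   (\mathrm{IBI}_{k+1} - \mathrm{IBI}_k)^2}}
#' in milliseconds, computed on the beat-domain IBI sequence. The primary
#' time-domain index of vagally mediated heart-rate variability: shift
#' invariant and scale equivariant.
#'
#' @param x an [ibi_series()] or numeric vector of IBIs in ms.
#' @return RMSSD in ms.
#' @export
rmssd <- function(x) {
  ibi <- if (inherits(x, "ibi_series")) x$ibi_ms else as.numeric(x)
  if (length(ibi) < 2)
    stop("RMSSD needs at least 3 beats (2 IBIs)")
  sqrt(mean(diff(ibi)^2))
}

#' Mean heart rate from an IBI series
#'
#' `60000 / mean(ibi_ms)`, in beats per minute. Entered as a covariate in
#' every model involving RMSSD, given the known dependence of HRV on heart
#' rate.
#'
#' @inheritParams rmssd
#' @return mean heart rate in bpm.
#' @export
mean_heart_rate <- function(x) {
  ibi <- if (inherits(x, "ibi_series")) x$ibi_ms else as.numeric(x)
  if (length(ibi) < 1) stop("need at least 2 beats")
  60000 / mean(ibi)
}

#' Winsorize values at percentile caps
#'
#' Values below the `lower_pct` percentile are set to it and values above
#' the `upper_pct` percentile are set to it; order and length are
#' preserved, `NA`s pass through. The percentile estimator is linear
#' interpolation between closest order statistics
#' ([stats::quantile()] type 7), fixed for reproducibility. Applied at the
#' cohort level (across infants' RMSSD values), and idempotent.
#'
#' @param values numeric vector (at least 2 finite values).
#' @param lower_pct,upper_pct percentile caps (default 5 and 95).
#' @return winsorized vector.
#' @export
winsorize <- function(values, lower_pct = 5, upper_pct = 95) {
  if (sum(is.finite(values)) < 2)
    stop("winsorize needs at least 2 finite values")
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100))
    stop("need 0 <= lower_pct < upper_pct <= 100")
  qs <- stats::quantile(values, c(lower_pct, upper_pct) / 100,
                        na.rm = TRUE, names = FALSE, type = 7)
  pmin(pmax(values, qs[1]), qs[2])
}

#' Baseline HRV summary for one recording
#'
#' Computes RMSSD and mean heart rate on the (optionally artifact-cleaned)
#' beat-domain series, reports usable duration and applies a minimum
#' usable-duration gate. The winsorized RMSSD is a cohort-level quantity
#' (see [winsorize()]) and is left `NA` here.
#'
#' @param series an [ibi_series()].
#' @param min_duration_s minimum usable recording length in seconds
#'   (default 60); shorter recordings are flagged unusable.
#' @param clean apply [clean_ibi()] first (default `FALSE`).
#' @return object of class `baseline_hrv`: list with `rmssd_ms`,
#'   `mean_hr_bpm`, `usable_duration_s`, `usable`, `winsorized_rmssd_ms`
#'   (`NA` until set at cohort level).
#' @export
baseline_hrv <- function(series, min_duration_s = 60, clean = FALSE) {
  stopifnot(inherits(series, "ibi_series"))
  if (clean) series <- clean_ibi(series)
  dur <- diff(range(series$beat_times_s))
  structure(list(rmssd_ms = rmssd(series),
                 mean_hr_bpm = mean_heart_rate(series),
                 usable_duration_s = dur,
                 usable = dur >= min_duration_s,
                 winsorized_rmssd_ms = NA_real_),
            class = "baseline_hrv")
}

#' @export
print.baseline_hrv <- function(x, ...) {
  cat(sprintf(
    "<baseline_hrv> RMSSD %.2f ms, mean HR %.1f bpm, %.0f s%s\n",
    x$rmssd_ms, x$mean_hr_bpm, x$usable_duration_s,
    if (x$usable) "" else " (below usable-duration floor)"))
  invisible(x)
}
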