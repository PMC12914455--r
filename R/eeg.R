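# Relative frontal theta power from 1-second EEG segments.
#
# Power decomposition: Hanning-windowed FFT per 1-s segment per channel,
# giving 1 Hz resolution bins. Relative theta = summed 4-6 Hz power over
# summed 1-50 Hz power (inclusive bin convention), per segment per frontal
# channel, averaged; the attention-minus-inattention change score is the
# neural index of sustained attention quality.

#' Default frontal electrode numbers (64-channel geodesic montage)
#'
#' @return integer vector of frontal electrode numbers.
#' @export
frontal_electrodes <- function() {
  c(2L, 3L, 5L, 6L, 9L, 10L, 11L, 12L, 13L, 14L, 57L, 59L, 60L)
}

#' Construct a set of labeled 1-second EEG segments
#'
#' @param segments channels x samples x segments numeric array (or a list
#'   of equally shaped channels x samples matrices). Each segment must hold
#'   exactly `sr_hz` samples (1 second).
#' @param sr_hz sampling rate in Hz.
#' @param condition_labels per-segment condition, `"attention"` or
#'   `"inattention"`.
#' @param channel_names optional channel names (default `E1`, `E2`, ...).
#' @param frontal_channels indices (rows) of frontal channels; defaults to
#'   [frontal_electrodes()] when the array has at least 60 channels,
#'   otherwise all channels.
#' @return object of class `eeg_segment_set`.
#' @export
eeg_segment_set <- function(segments, sr_hz, condition_labels,
                            channel_names = NULL,
                            frontal_channels = NULL) {
  if (is.list(segments)) {
    d <- dim(segments[[1]])
    segments <- array(unlist(segments), dim = c(d, length(segments)))
  }
  stopifnot(length(dim(segments)) == 3)
  nch <- dim(segments)[1]; nsamp <- dim(segments)[2]; nseg <- dim(segments)[3]
  if (nsamp != round(sr_hz))
    stop("each 1-s segment must hold exactly sr_hz samples")
  if (length(condition_labels) != nseg)
    stop("need one condition label per segment")
  if (!all(condition_labels %in% c("attention", "inattention")))
    stop("condition labels must be 'attention' or 'inattention'")
  if (is.null(channel_names)) channel_names <- paste0("E", seq_len(nch))
  if (is.null(frontal_channels)) {
    frontal_channels <- if (nch >= 60) frontal_electrodes() else seq_len(nch)
  }
  if (any(frontal_channels < 1 | frontal_channels > nch))
    stop("frontal channel indices outside the channel set")
  structure(list(segments = segments, sr_hz = sr_hz,
                 condition_labels = condition_labels,
                 channel_names = channel_names,
                 frontal_channels = as.integer(frontal_channels),
                 n_rejected = 0L),
            class = "eeg_segment_set")
}

#' @export
print.eeg_segment_set <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf(
    "<eeg_segment_set> %d segments (%d att / %d inatt), %d ch @ %g Hz, %d rejected\n",
    d[3], sum(x$condition_labels == "attention"),
    sum(x$condition_labels == "inattention"), d[1], x$sr_hz, x$n_rejected))
  invisible(x)
}

#' Number of segments in a set
#' @param set an [eeg_segment_set()].
#' @return integer count.
#' @export
n_segments <- function(set) dim(set$segments)[3]

#' Hanning-windowed power spectrum of one 1-second segment
#'
#' Applies a Hann window per channel and returns one-sided squared-magnitude
#' FFT power at 1 Hz resolution. Power is normalized so that the sum over
#' all bins equals the windowed time-domain energy (Parseval):
#' \eqn{P_0 = |X_0|^2/n}, \eqn{P_k = (|X_k|^2 + |X_{n-k}|^2)/n} for
#' \eqn{0 < k < n/2}, \eqn{P_{n/2} = |X_{n/2}|^2/n}.
#'
#' @param segment channels x samples matrix (or a numeric vector for one
#'   channel); the number of samples must equal `sr_hz`.
#' @param sr_hz sampling rate in Hz.
#' @return channels x bins matrix of power; column names are frequencies
#'   `0 .. sr_hz/2` in Hz.
#' @export
segment_power_spectrum <- function(segment, sr_hz) {
  if (is.null(dim(segment))) segment <- matrix(segment, nrow = 1)
  n <- ncol(segment)
  if (n != round(sr_hz))
    stop("segment length must equal sr_hz samples (1 second)")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xw <- sweep(segment, 2, w, `*`)
  X <- t(apply(xw, 1, stats::fft))
  if (nrow(X) != nrow(segment)) X <- t(X)  # single-row apply transposes
  half <- floor(n / 2)
  P <- matrix(0, nrow(segment), half + 1)
  P[, 1] <- Mod(X[, 1])^2 / n
  if (half > 1) {
    ks <- 2:half
    P[, ks] <- (Mod(X[, ks])^2 + Mod(X[, n + 2 - ks])^2) / n
  }
  if (n %% 2 == 0) P[, half + 1] <- Mod(X[, half + 1])^2 / n
  colnames(P) <- as.character(0:half)
  rownames(P) <- rownames(segment)
  P
}

.band_cols <- function(P, band) {
  f <- as.numeric(colnames(P))
  which(f >= band[1] - 1e-9 & f <= band[2] + 1e-9)
}

#' Reject amplitude-outlier segments
#'
#' Each segment is summarized by its maximum absolute value across frontal
#' channels; segments whose summary lies more than `z` standard deviations
#' from the median summary are excluded. Counts of rejected segments are
#' accumulated on the returned set.
#'
#' @param set an [eeg_segment_set()] with at least 2 segments.
#' @param z rejection threshold in SD units (default 3).
#' @return the set with outlier segments removed; `set$n_rejected` is
#'   incremented accordingly.
#' @export
reject_amplitude_outliers <- function(set, z = 3) {
  stopifnot(inherits(set, "eeg_segment_set"))
  nseg <- n_segments(set)
  if (nseg < 2) stop("need at least 2 segments")
  fr <- set$frontal_channels
  amp <- vapply(seq_len(nseg),
                function(i) max(abs(set$segments[fr, , i])), numeric(1))
  s <- stats::sd(amp)
  keep <- if (s == 0) rep(TRUE, nseg) else
    abs(amp - stats::median(amp)) <= z * s
  out <- set
  out$segments <- set$segments[, , keep, drop = FALSE]
  out$condition_labels <- set$condition_labels[keep]
  out$n_rejected <- set$n_rejected + sum(!keep)
  out
}

#' Minimum usable-segment gate
#'
#' @param set an [eeg_segment_set()].
#' @param min_n minimum number of retained segments (default 20).
#' @return logical: `TRUE` when the set is usable.
#' @export
enforce_minimum_segments <- function(set, min_n = 20) {
  n_segments(set) >= min_n
}

#' Relative band power of one segment set (internal helper)
#'
#' Per segment and frontal channel, band power divided by total-band power;
#' averaged across frontal channels to give a per-segment value.
#'
#' @param set an [eeg_segment_set()].
#' @param band numeric length-2 band in Hz (inclusive bin convention).
#' @param total_band denominator band (default 1--50 Hz).
#' @return numeric vector, one relative power per segment.
#' @export
relative_band_power <- function(set, band, total_band = c(1, 50)) {
  stopifnot(inherits(set, "eeg_segment_set"))
  fr <- set$frontal_channels
  vapply(seq_len(n_segments(set)), function(i) {
    P <- segment_power_spectrum(set$segments[fr, , i, drop = FALSE],
                                set$sr_hz)
    bi <- .band_cols(P, band); ti <- .band_cols(P, total_band)
    num <- rowSums(P[, bi, drop = FALSE])
    den <- rowSums(P[, ti, drop = FALSE])
    mean(ifelse(den > 0, num / den, 0))
  }, numeric(1))
}

#' Relative frontal theta power and attention change score
#'
#' Computes, per condition, relative theta power (theta-band power over
#' total-band power, per segment per frontal channel, averaged across
#' channels then across segments) and the change score
#' `attention - inattention`. Log10-transformed mean band powers are
#' retained as auxiliary outputs. Sets failing the minimum-segment rule
#' yield missing values; a condition with zero segments yields a missing
#' value for that condition and for the change score.
#'
#' @param set an [eeg_segment_set()] (after any segment rejection).
#' @param theta_band theta band in Hz, inclusive bins (default `c(4, 6)`).
#' @param total_band denominator band (default `c(1, 50)`).
#' @param min_segments usable-data floor on total retained segments
#'   (default 20).
#' @param method `"per_segment"` (default: ratio per segment, then
#'   averaged) or `"average_spectra"` (ratio of segment-averaged band
#'   powers).
#' @return object of class `spectral_summary`: list with
#'   `rel_theta_attention`, `rel_theta_inattention`, `theta_change`,
#'   `n_segments_attention`, `n_segments_inattention`, `n_rejected`,
#'   `usable`, `log10_theta_power` (per condition).
#' @export
relative_theta <- function(set, theta_band = c(4, 6), total_band = c(1, 50),
                           min_segments = 20,
                           method = c("per_segment", "average_spectra")) {
  method <- match.arg(method)
  stopifnot(inherits(set, "eeg_segment_set"))
  usable <- enforce_minimum_segments(set, min_segments)
  labs <- set$condition_labels
  n_att <- sum(labs == "attention"); n_in <- sum(labs == "inattention")
  res <- list(rel_theta_attention = NA_real_,
              rel_theta_inattention = NA_real_,
              theta_change = NA_real_,
              n_segments_attention = n_att,
              n_segments_inattention = n_in,
              n_rejected = set$n_rejected,
              usable = usable,
              log10_theta_power = c(attention = NA_real_,
                                    inattention = NA_real_))
  class(res) <- "spectral_summary"
  if (!usable) return(res)
  fr <- set$frontal_channels
  cond_value <- function(cond) {
    idx <- which(labs == cond)
    if (!length(idx)) return(list(rel = NA_real_, logp = NA_real_))
    th <- numeric(0); tot <- numeric(0); ratios <- numeric(0)
    th_sum <- 0; tot_sum <- 0
    for (i in idx) {
      P <- segment_power_spectrum(set$segments[fr, , i, drop = FALSE],
                                  set$sr_hz)
      bi <- .band_cols(P, theta_band); ti <- .band_cols(P, total_band)
      num <- rowSums(P[, bi, drop = FALSE])
      den <- rowSums(P[, ti, drop = FALSE])
      ratios <- c(ratios, mean(ifelse(den > 0, num / den, 0)))
      th_sum <- th_sum + mean(num); tot_sum <- tot_sum + mean(den)
    }
    rel <- if (method == "per_segment") mean(ratios)
           else if (tot_sum > 0) th_sum / tot_sum else NA_real_
    list(rel = rel,
         logp = if (th_sum > 0) log10(th_sum / length(idx)) else NA_real_)
  }
  att <- cond_value("attention"); inatt <- cond_value("inattention")
  res$rel_theta_attention <- att$rel
  res$rel_theta_inattention <- inatt$rel
  res$theta_change <- att$rel - inatt$rel
  res$log10_theta_power <- c(attention = att$logp, inattention = inatt$logp)
  res
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf(
    "<spectral_summary> rel theta att %.4f / inatt %.4f, change %+.4f (%d/%d segs, %d rejected)%s\n",
    x$rel_theta_attention, x$rel_theta_inattention, x$theta_change,
    x$n_segments_attention, x$n_segments_inattention, x$n_rejected,
    if (x$usable) "" else " [unusable: below minimum segments]"))
  invisible(x)
}

#' Read an EEG array with a JSON-style sidecar
#'
#' Reads a channels x samples numeric matrix from CSV (one row per channel,
#' no header) plus a sidecar file holding `sr_hz` and `channel_names`
#' (JSON parsed with a minimal reader; written by [write_eeg_array()]).
#'
#' @param data_path CSV of the channel x sample matrix.
#' @param sidecar_path JSON sidecar path (default: `data_path` with
#'   `.json` extension).
#' @return list with `data` (matrix), `sr_hz`, `channel_names`.
#' @export
read_eeg_array <- function(data_path,
                           sidecar_path = sub("\\.[^.]+$", ".json",
                                              data_path)) {
  data <- as.matrix(utils::read.csv(data_path, header = FALSE))
  dimnames(data) <- NULL
  txt <- paste(readLines(sidecar_path, warn = FALSE), collapse = "")
  sr <- as.numeric(sub('.*"sr_hz"\\s*:\\s*([0-9.]+).*', "\\1", txt))
  ch <- regmatches(txt, gregexpr('"E[0-9]+"', txt))[[1]]
  ch <- gsub('"', "", ch)
  list(data = data, sr_hz = sr,
       channel_names = if (length(ch)) ch else paste0("E", seq_len(nrow(data))))
}

#' Write an EEG array with a JSON sidecar
#'
#' @param data channels x samples matrix.
#' @param sr_hz sampling rate.
#' @param data_path output CSV path.
#' @param channel_names channel names (default `E1`, ...).
#' @return `data_path`, invisibly.
#' @export
write_eeg_array <- function(data, sr_hz, data_path,
                            channel_names = paste0("E", seq_len(nrow(data)))) {
  utils::write.table(data, data_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- sub("\\.[^.]+$", ".json", data_path)
  writeLines(sprintf('{"sr_hz": %g, "channel_names": [%s]}', sr_hz,
                     paste(sprintf('"%s"', channel_names), collapse = ", ")),
             sidecar)
  invisible(data_path)
}

#' Cut a continuous EEG record into labeled 1-second segments
#'
#' Segments a channels x samples matrix into consecutive 1-s windows
#' starting at `task_onset_s`, labeling each window `"attention"` when its
#' midpoint falls inside a sustained-attention phase and `"inattention"`
#' otherwise.
#'
#' @param data channels x samples matrix; sample 1 is at `record_start_s`.
#' @param sr_hz sampling rate in Hz.
#' @param phases an `attention_phases` data.frame.
#' @param record_start_s time of the first sample (default 0).
#' @param frontal_channels passed to [eeg_segment_set()].
#' @return an [eeg_segment_set()].
#' @export
segment_eeg <- function(data, sr_hz, phases, record_start_s = 0,
                        frontal_channels = NULL) {
  t0 <- attr(phases, "task_onset_s")
  t1 <- attr(phases, "task_end_s")
  n <- round(sr_hz)
  starts <- seq(t0, t1 - 1 + 1e-9, by = 1)
  sa <- phases[phases$kind == "sustained_attention", , drop = FALSE]
  segs <- list(); labs <- character(0)
  for (s in starts) {
    i0 <- round((s - record_start_s) * sr_hz) + 1
    if (i0 < 1 || i0 + n - 1 > ncol(data)) next
    segs[[length(segs) + 1]] <- data[, i0:(i0 + n - 1), drop = FALSE]
    labs <- c(labs, if (any(sa$onset_s <= s + 0.5 & s + 0.5 < sa$offset_s))
      "attention" else "inattention")
  }
  if (!length(segs)) stop("no complete 1-s segments inside the task window")
  eeg_segment_set(segs, sr_hz, labs, frontal_channels = frontal_channels)
}
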