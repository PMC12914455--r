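# Coded caregiver sensory events and composite signal states.
#
# A session is coded as on/off intervals of three signal modalities
# (auditory, visual, tactile). At any instant the caregiver's "composite
# state" is the subset of modalities currently active, one of 8 states
# including the empty "none" state. Transitions between composite states
# form the sequence whose entropy rate indexes (un)predictability.

SENSORY_MODALITIES <- c("auditory", "visual", "tactile")
.MOD_ABBREV <- c(auditory = "A", visual = "V", tactile = "T")

#' All composite sensory state labels
#'
#' Canonical labels for the subsets of \{auditory, visual, tactile\}:
#' `"none"`, `"A"`, `"V"`, `"T"`, `"AV"`, `"AT"`, `"VT"`, `"AVT"`.
#' Modalities are abbreviated by initial and concatenated in fixed A, V, T
#' order, so labels are unambiguous.
#'
#' @param include_empty include the empty "none" state (default `TRUE`).
#' @return character vector of state labels.
#' @export
composite_state_labels <- function(include_empty = TRUE) {
  ab <- unname(.MOD_ABBREV)
  subsets <- character(0)
  for (k in 1:3) {
    cmb <- utils::combn(ab, k)
    subsets <- c(subsets, apply(cmb, 2, paste, collapse = ""))
  }
  if (include_empty) c("none", subsets) else subsets
}

.state_label <- function(mods) {
  if (length(mods) == 0) return("none")
  ab <- .MOD_ABBREV[sort(match(mods, SENSORY_MODALITIES))]
  paste(unname(ab), collapse = "")
}

#' Construct a caregiver sensory event log
#'
#' Holds timed on/off intervals of caregiver auditory, visual and tactile
#' signals, as exported from micro-coding software. Intervals of the same
#' modality must not overlap (the coding scheme codes each modality as a
#' single on/off channel); overlapping intervals of different modalities are
#' what create composite states.
#'
#' @param events data.frame with columns `modality`
#'   (`"auditory"`/`"visual"`/`"tactile"`), `onset_s`, `offset_s`.
#' @param session_duration_s total coded session length in seconds; defaults
#'   to the latest offset.
#' @return object of class `sensory_event_log`.
#' @export
sensory_event_log <- function(events, session_duration_s = NULL) {
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(modality = character(0), onset_s = numeric(0),
                         offset_s = numeric(0))
  }
  req <- c("modality", "onset_s", "offset_s")
  if (!all(req %in% names(events)))
    stop("`events` must have columns modality, onset_s, offset_s")
  events$modality <- as.character(events$modality)
  bad <- setdiff(unique(events$modality), SENSORY_MODALITIES)
  if (length(bad))
    stop("unknown modality: ", paste(bad, collapse = ", "))
  if (is.null(session_duration_s))
    session_duration_s <- if (nrow(events)) max(events$offset_s) else 0
  if (nrow(events)) {
    if (any(events$onset_s < 0) || any(events$offset_s <= events$onset_s))
      stop("each event needs 0 <= onset_s < offset_s")
    if (any(events$offset_s > session_duration_s + 1e-9))
      stop("events extend past session_duration_s")
    # same-modality overlap check, naming the offending pair
    for (m in unique(events$modality)) {
      ev <- events[events$modality == m, , drop = FALSE]
      ev <- ev[order(ev$onset_s), , drop = FALSE]
      if (nrow(ev) > 1) {
        ov <- which(ev$onset_s[-1] < ev$offset_s[-nrow(ev)] - 1e-12)
        if (length(ov)) {
          i <- ov[1]
          stop(sprintf(
            "overlapping %s events: [%g, %g] and [%g, %g]",
            m, ev$onset_s[i], ev$offset_s[i], ev$onset_s[i + 1],
            ev$offset_s[i + 1]))
        }
      }
    }
  }
  events <- events[order(events$onset_s, events$modality), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events,
                 session_duration_s = as.numeric(session_duration_s)),
            class = "sensory_event_log")
}

#' @export
print.sensory_event_log <- function(x, ...) {
  cat(sprintf("<sensory_event_log> %d events over %.1f s\n",
              nrow(x$events), x$session_duration_s))
  if (nrow(x$events)) {
    tab <- table(x$events$modality)
    cat("  events by modality:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a caregiver sensory event log from CSV
#'
#' Two layouts are supported: a BORIS-style point-event export with columns
#' `time_s`, `modality`, `event` (`"start"`/`"stop"`, paired in time order
#' within modality), and a plain interval layout with columns `modality`,
#' `onset_s`, `offset_s`.
#'
#' @param path CSV file path.
#' @param session_duration_s optional session length (defaults to last
#'   offset).
#' @param format `"auto"` (default; inferred from columns), `"boris"` or
#'   `"intervals"`.
#' @return a [sensory_event_log()].
#' @export
read_event_log <- function(path, session_duration_s = NULL,
                           format = c("auto", "boris", "intervals")) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "auto") {
    format <- if (all(c("time_s", "event") %in% names(df))) "boris"
              else "intervals"
  }
  if (format == "intervals") {
    return(sensory_event_log(df[, c("modality", "onset_s", "offset_s")],
                             session_duration_s))
  }
  if (!all(c("time_s", "modality", "event") %in% names(df)))
    stop("BORIS-style log needs columns time_s, modality, event")
  out <- list()
  for (m in unique(df$modality)) {
    sub <- df[df$modality == m, , drop = FALSE]
    sub <- sub[order(sub$time_s), , drop = FALSE]
    ev <- tolower(sub$event)
    if (!all(ev %in% c("start", "stop")))
      stop("event column must be start/stop")
    if (length(ev) %% 2 != 0 || !all(ev == rep(c("start", "stop"),
                                               length(ev) / 2)))
      stop(sprintf("unpaired start/stop events for modality %s", m))
    idx <- seq(1, length(ev), by = 2)
    out[[m]] <- data.frame(modality = m,
                           onset_s = sub$time_s[idx],
                           offset_s = sub$time_s[idx + 1])
  }
  sensory_event_log(do.call(rbind, out), session_duration_s)
}

#' Write an event log as BORIS-style CSV
#'
#' @param log a [sensory_event_log()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "sensory_event_log"))
  ev <- log$events
  df <- data.frame(
    time_s = c(rbind(ev$onset_s, ev$offset_s)),
    modality = rep(ev$modality, each = 2),
    event = rep(c("start", "stop"), nrow(ev)))
  df <- df[order(df$time_s, df$modality), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert an event log to a composite-state transition sequence
#'
#' At every instant the active composite state is the set of modalities whose
#' coded intervals cover it. The output records the state entered at each
#' change point, with consecutive identical states collapsed so the sequence
#' has no self-transitions by construction. The segment before the first
#' event (and after the last offset) is the "none" state; inclusion of a
#' positive-length leading "none" segment is controlled by
#' `include_leading`.
#'
#' @param log a [sensory_event_log()].
#' @param include_leading include the (positive-length) leading no-signal
#'   segment as a state (default `TRUE`).
#' @return object of class `signal_state_sequence` with fields `states`,
#'   `change_times_s` and `session_duration_s`.
#' @export
events_to_state_sequence <- function(log, include_leading = TRUE) {
  stopifnot(inherits(log, "sensory_event_log"))
  ev <- log$events
  dur <- log$session_duration_s
  if (nrow(ev) == 0) {
    return(structure(list(states = "none", change_times_s = 0,
                          session_duration_s = dur),
                     class = "signal_state_sequence"))
  }
  start_t <- if (include_leading) 0 else min(ev$onset_s)
  bp <- sort(unique(c(start_t, ev$onset_s, ev$offset_s)))
  bp <- bp[bp >= start_t & bp < dur]
  seg_end <- c(bp[-1], dur)
  keep <- seg_end - bp > 1e-12
  bp <- bp[keep]; seg_end <- seg_end[keep]
  mid <- (bp + seg_end) / 2
  # active-set labels at segment midpoints, vectorized per modality: with
  # non-overlapping same-modality intervals, a midpoint is covered iff
  # #onsets <= t exceeds #offsets <= t
  parts <- vapply(SENSORY_MODALITIES, function(m) {
    sel <- ev$modality == m
    if (!any(sel)) return(rep("", length(mid)))
    on <- sort(ev$onset_s[sel]); off <- sort(ev$offset_s[sel])
    act <- findInterval(mid, on) > findInterval(mid, off)
    ifelse(act, unname(.MOD_ABBREV[m]), "")
  }, character(length(mid)))
  if (is.null(dim(parts))) parts <- matrix(parts, nrow = 1)
  states <- paste0(parts[, 1], parts[, 2], parts[, 3])
  states[states == ""] <- "none"
  # collapse consecutive duplicates
  keep <- c(TRUE, states[-1] != states[-length(states)])
  structure(list(states = states[keep], change_times_s = bp[keep],
                 session_duration_s = dur),
            class = "signal_state_sequence")
}

#' @export
print.signal_state_sequence <- function(x, ...) {
  cat(sprintf("<signal_state_sequence> %d states, %d transitions, %.1f s\n",
              length(x$states), max(0L, length(x$states) - 1L),
              x$session_duration_s))
  n <- min(10, length(x$states))
  cat("  ", paste(x$states[seq_len(n)], collapse = " -> "),
      if (length(x$states) > n) " ..." else "", "\n", sep = "")
  invisible(x)
}
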