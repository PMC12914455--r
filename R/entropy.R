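# Transition models and entropy-rate scoring of caregiver signal sequences,
# plus interrater reliability for the underlying coding.

#' Estimate a first-order transition model from a state sequence
#'
#' Counts i -> j transitions between consecutive composite states and
#' row-normalizes the counts into conditional probabilities P(j | i). The
#' marginal frequencies `pi` are the empirical frequencies of *source*
#' states (row sums over total transitions), the plug-in weighting used for
#' finite sessions, not the chain's stationary distribution. Rows with zero
#' outgoing counts are flagged absent (`NA` probabilities), never imputed.
#' No smoothing is applied unless `pseudocount > 0` is requested.
#'
#' @param seq a `signal_state_sequence` (from [events_to_state_sequence()])
#'   or a plain character vector of states.
#' @param state_set optional state universe; defaults to the states observed
#'   in `seq` (sorted). States never observed do not affect the entropy rate.
#' @param pseudocount optional additive smoothing count for off-diagonal
#'   cells (default 0, the plug-in estimator).
#' @return object of class `transition_model` with fields `state_set`,
#'   `count_matrix`, `conditional_probs`, `marginal_freqs`, `n_transitions`.
#' @export
estimate_transition_model <- function(seq, state_set = NULL,
                                      pseudocount = 0) {
  states <- if (inherits(seq, "signal_state_sequence")) seq$states
            else as.character(seq)
  if (length(states) < 2)
    stop("need at least 2 states to estimate a transition model")
  if (any(states[-1] == states[-length(states)]))
    stop("self-transitions are not allowed; collapse repeated states first")
  if (is.null(state_set)) state_set <- sort(unique(states))
  if (!all(states %in% state_set))
    stop("sequence contains states outside `state_set`")
  k <- length(state_set)
  counts <- matrix(0L, k, k, dimnames = list(state_set, state_set))
  from <- factor(states[-length(states)], levels = state_set)
  to <- factor(states[-1], levels = state_set)
  tab <- table(from, to)
  counts[] <- as.integer(tab)
  if (pseudocount > 0) {
    cm <- counts + pseudocount
    diag(cm) <- 0
  } else cm <- counts
  rs <- rowSums(cm)
  probs <- cm / ifelse(rs > 0, rs, 1)
  probs[rs == 0, ] <- NA_real_
  n_trans <- sum(counts)
  structure(list(state_set = state_set,
                 count_matrix = counts,
                 conditional_probs = probs,
                 marginal_freqs = rowSums(counts) / n_trans,
                 n_transitions = n_trans,
                 n_states_observed = length(unique(states))),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> %d states, %d transitions\n",
              length(x$state_set), x$n_transitions))
  print(round(x$conditional_probs, 3))
  invisible(x)
}

#' Entropy rate of a transition model
#'
#' The plug-in conditional Shannon entropy, in bits per transition:
#' \deqn{H = -\sum_i \pi_i \sum_j P(j|i) \log_2 P(j|i),}
#' with \eqn{0 \log 0 := 0} and rows without outgoing transitions
#' contributing 0. Zero for deterministic sequences; at most
#' \eqn{\log_2} of the number of observed states. Higher values mean the
#' next caregiver signal state is less predictable from the current one.
#'
#' @param model a `transition_model` (or a state sequence, which is first
#'   passed through [estimate_transition_model()]).
#' @return object of class `entropy_rate`: list with `value_bits`,
#'   `n_transitions`, `n_states_observed`.
#' @export
entropy_rate <- function(model) {
  if (!inherits(model, "transition_model"))
    model <- estimate_transition_model(model)
  P <- model$conditional_probs
  pi_i <- model$marginal_freqs
  row_h <- apply(P, 1, function(p) {
    if (all(is.na(p))) return(0)
    p <- p[p > 0 & !is.na(p)]
    if (!length(p)) 0 else -sum(p * log2(p))
  })
  structure(list(value_bits = sum(pi_i * row_h),
                 n_transitions = model$n_transitions,
                 n_states_observed = model$n_states_observed),
            class = "entropy_rate")
}

#' @export
print.entropy_rate <- function(x, ...) {
  cat(sprintf("Entropy rate: %.4f bits (%d transitions, %d states)\n",
              x$value_bits, x$n_transitions, x$n_states_observed))
  invisible(x)
}

#' Closed-form entropy rate of a Markov chain
#'
#' Exact entropy rate of a row-stochastic transition matrix, weighting each
#' row's conditional entropy by the chain's stationary distribution (left
#' eigenvector of `P` for eigenvalue 1). Used as the analytic reference the
#' plug-in estimator converges to on long realizations.
#'
#' @param P row-stochastic transition matrix.
#' @return list with `value_bits` and `stationary`.
#' @export
markov_entropy_rate <- function(P) {
  P <- as.matrix(P)
  if (any(abs(rowSums(P) - 1) > 1e-8))
    stop("P must be row-stochastic")
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  pi_s <- Re(e$vectors[, i])
  pi_s <- pi_s / sum(pi_s)
  if (any(pi_s < -1e-8)) stop("no non-negative stationary distribution found")
  pi_s <- pmax(pi_s, 0); pi_s <- pi_s / sum(pi_s)
  row_h <- apply(P, 1, function(p) {
    p <- p[p > 0]
    if (!length(p)) 0 else -sum(p * log2(p))
  })
  list(value_bits = sum(pi_s * row_h), stationary = pi_s)
}

#' Entropy rate from an event log
#'
#' Convenience wrapper: event log -> state sequence -> transition model ->
#' entropy rate.
#'
#' @inheritParams events_to_state_sequence
#' @return an `entropy_rate` object.
#' @export
event_log_entropy <- function(log, include_leading = TRUE) {
  entropy_rate(estimate_transition_model(
    events_to_state_sequence(log, include_leading = include_leading)))
}

#' Interrater reliability of two coded event logs
#'
#' Discretizes the session into bins of `bin_s` seconds and compares, per
#' modality, the binary presence/absence pattern coded by the two raters.
#' Raw agreement is the percentage of matching bins; Cohen's kappa is
#' \eqn{(p_o - p_e)/(1 - p_e)} with chance agreement \eqn{p_e} computed from
#' each rater's marginal bin rates. Both statistics are averaged across
#' modalities that occur in at least one log; a modality absent from both
#' logs carries no information about the coders and is excluded. Kappa is 1
#' when observed agreement is exactly 1 (including the degenerate case
#' \eqn{p_e = 1}).
#'
#' @param log_a,log_b two [sensory_event_log()]s of the same session.
#' @param bin_s bin width in seconds (default 1).
#' @return list with `raw_agreement_pct`, `cohens_kappa`, and a
#'   `per_modality` data.frame.
#' @export
interrater_reliability <- function(log_a, log_b, bin_s = 1) {
  stopifnot(inherits(log_a, "sensory_event_log"),
            inherits(log_b, "sensory_event_log"), bin_s > 0)
  dur <- log_a$session_duration_s
  if (abs(dur - log_b$session_duration_s) > 1e-9)
    stop("session durations differ between the two logs")
  starts <- (seq_len(max(1, floor(dur / bin_s + 1e-9))) - 1) * bin_s
  presence <- function(log, m) {
    ev <- log$events[log$events$modality == m, , drop = FALSE]
    if (!nrow(ev)) return(rep(FALSE, length(starts)))
    vapply(starts, function(t0) {
      any(ev$onset_s < min(t0 + bin_s, dur) - 1e-12 & ev$offset_s > t0 + 1e-12)
    }, logical(1))
  }
  rows <- list()
  for (m in SENSORY_MODALITIES) {
    a <- presence(log_a, m); b <- presence(log_b, m)
    if (!any(a) && !any(b)) next  # uninformative modality
    po <- mean(a == b)
    pa1 <- mean(a); pb1 <- mean(b)
    pe <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
    kap <- if (po >= 1 - 1e-12) 1 else (po - pe) / (1 - pe)
    rows[[m]] <- data.frame(modality = m, raw_agreement_pct = 100 * po,
                            kappa = kap)
  }
  if (!length(rows))
    stop("no modality occurs in either log; reliability undefined")
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  list(raw_agreement_pct = mean(per$raw_agreement_pct),
       cohens_kappa = mean(per$kappa),
       per_modality = per)
}
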