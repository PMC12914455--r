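# Synthetic dyad generators: Markov caregiver signal sequences with tunable
# entropy rate, IBI series with controllable RMSSD and planted
# decelerations, EEG with condition-modulated theta power, and cohorts with
# planted standardized effects under MCAR missingness. These emulate the
# study conditions the measurement chain assumes, so every downstream stage
# is testable without participant data.

#' Caregiver simulation configuration
#'
#' A continuous-time Markov model of composite sensory states: states dwell
#' for exponential times (mean `mean_dwell_s`) and jump according to a
#' row-stochastic transition matrix with zero diagonal (an event *is* a
#' state change). Timing only affects how many transitions fit into the
#' session; the entropy rate depends on transition order alone.
#'
#' @param state_labels composite state labels (default all 8 subsets of
#'   auditory/visual/tactile, including "none").
#' @param transition_matrix row-stochastic matrix with zero diagonal
#'   (default uniform over the other states).
#' @param mean_dwell_s mean dwell time per state in seconds (default 2).
#' @param duration_s session length in seconds (default 300, a 5-minute
#'   play interaction).
#' @param n_transitions optional: generate exactly this many transitions
#'   instead of filling `duration_s`.
#' @param seed integer seed.
#' @return object of class `caregiver_sim_config`.
#' @export
caregiver_sim_config <- function(state_labels = composite_state_labels(),
                                 transition_matrix = NULL,
                                 mean_dwell_s = 2, duration_s = 300,
                                 n_transitions = NULL, seed = 1) {
  k <- length(state_labels)
  if (k < 2) stop("need at least 2 states")
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (k - 1), k, k)
    diag(transition_matrix) <- 0
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == k))
    stop("transition_matrix must be ", k, " x ", k)
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-8))
    stop("transition_matrix must be row-stochastic")
  if (any(abs(diag(transition_matrix)) > 1e-12))
    stop("transition_matrix must have a zero diagonal (event = state change)")
  if (mean_dwell_s <= 0 || duration_s <= 0)
    stop("mean_dwell_s and duration_s must be positive")
  structure(list(state_labels = state_labels,
                 transition_matrix = transition_matrix,
                 mean_dwell_s = mean_dwell_s, duration_s = duration_s,
                 n_transitions = n_transitions, seed = seed),
            class = "caregiver_sim_config")
}

#' Transition matrix with a prescribed entropy rate
#'
#' One-parameter family interpolating between a deterministic cycle
#' (entropy 0) and the uniform off-diagonal matrix (entropy
#' \eqn{\log_2(k - 1)}): each row puts probability
#' \eqn{(1-\theta) + \theta/(k-1)} on the cyclic successor and
#' \eqn{\theta/(k-1)} on every other state. Both endpoints are doubly
#' stochastic, so the stationary distribution is uniform and the entropy
#' rate has the closed form used for root-finding.
#'
#' @param target_bits desired entropy rate in bits, in
#'   `[0, log2(n_states - 1)]`.
#' @param n_states number of states (default 8).
#' @return row-stochastic matrix with zero diagonal whose entropy rate is
#'   `target_bits` (to root-finding tolerance).
#' @export
entropy_matched_matrix <- function(target_bits, n_states = 8) {
  m <- n_states - 1
  hmax <- log2(m)
  if (target_bits < 0 || target_bits > hmax + 1e-9)
    stop(sprintf("target_bits must be in [0, %.3f] for %d states",
                 hmax, n_states))
  h_theta <- function(th) {
    p1 <- (1 - th) + th / m
    pr <- th / m
    -(p1 * log2(p1) +
        if (pr > 0) (m - 1) * pr * log2(pr) else 0)
  }
  th <- if (target_bits <= 0) 0
        else if (target_bits >= hmax) 1
        else stats::uniroot(function(t) h_theta(t) - target_bits,
                            c(1e-12, 1), tol = 1e-12)$root
  P <- matrix(th / m, n_states, n_states)
  for (i in seq_len(n_states))
    P[i, if (i < n_states) i + 1 else 1] <- (1 - th) + th / m
  diag(P) <- 0
  P / rowSums(P)
}

.label_modalities <- function(label) {
  if (label == "none") return(character(0))
  SENSORY_MODALITIES[match(strsplit(label, "")[[1]],
                           unname(.MOD_ABBREV))]
}

#' Simulate a caregiver sensory event log
#'
#' Realizes the configured Markov chain and converts the composite-state
#' path into modality on/off events. Deterministic given the seed; the
#' induced state path is attached as attribute `"state_path"` so
#' round-trips through [events_to_state_sequence()] can be audited.
#'
#' @param cfg a [caregiver_sim_config()].
#' @return a [sensory_event_log()] with attributes `state_path` and
#'   `change_times_s`.
#' @export
simulate_caregiver_sequence <- function(cfg) {
  stopifnot(inherits(cfg, "caregiver_sim_config"))
  set.seed(cfg$seed)
  P <- cfg$transition_matrix
  k <- nrow(P)
  cum <- t(apply(P, 1, cumsum))
  st <- markov_entropy_rate(P)$stationary
  n_target <- if (!is.null(cfg$n_transitions)) cfg$n_transitions + 1 else
    max(20, ceiling(cfg$duration_s / cfg$mean_dwell_s * 1.5) + 10)
  path <- integer(n_target)
  path[1] <- sample.int(k, 1, prob = st)
  u <- stats::runif(n_target - 1)
  for (i in 2:n_target)
    path[i] <- findInterval(u[i - 1], cum[path[i - 1], ]) + 1L
  dwell <- stats::rexp(n_target, rate = 1 / cfg$mean_dwell_s)
  if (is.null(cfg$n_transitions)) {
    t_change <- c(0, cumsum(dwell))
    nkeep <- findInterval(cfg$duration_s, t_change)
    nkeep <- max(2, min(nkeep, n_target))
    path <- path[seq_len(nkeep)]
    t_change <- t_change[seq_len(nkeep)]
    dur <- cfg$duration_s
  } else {
    path <- path[seq_len(cfg$n_transitions + 1)]
    t_change <- c(0, cumsum(dwell[seq_len(cfg$n_transitions)]))
    dur <- t_change[length(t_change)] +
      dwell[cfg$n_transitions + 1]
  }
  labels <- cfg$state_labels[path]
  seg_start <- t_change
  seg_end <- c(t_change[-1], dur)
  ev <- list()
  ulab <- unique(labels)
  for (m in SENSORY_MODALITIES) {
    has_u <- vapply(ulab, function(l) m %in% .label_modalities(l),
                    logical(1))
    has <- has_u[match(labels, ulab)]
    if (!any(has)) next
    r <- rle(has)
    ends <- cumsum(r$lengths)
    starts <- c(1, ends[-length(ends)] + 1)
    on <- which(r$values)
    ev[[m]] <- data.frame(modality = m,
                          onset_s = seg_start[starts[on]],
                          offset_s = seg_end[ends[on]])
  }
  events <- if (length(ev)) do.call(rbind, ev) else NULL
  log <- sensory_event_log(events, session_duration_s = dur)
  attr(log, "state_path") <- labels
  attr(log, "change_times_s") <- t_change
  log
}

#' Cardiac simulation configuration
#'
#' Beat-to-beat IBI model: a fixed baseline plus AR(1) jitter plus a
#' respiratory-frequency sinusoid, with step increases planted during
#' deceleration epochs. The AR innovation SD and sinusoid amplitude are set
#' by a closed-form mapping so that the expected sample RMSSD equals
#' `rmssd_target_ms`: for AR(1) with coefficient \eqn{\phi} the expected
#' squared successive difference is \eqn{2\sigma^2/(1+\phi)}, and for a
#' sinusoid of amplitude A sampled every mean-IBI seconds it is
#' \eqn{A^2(1 - \cos 2\pi f \bar T)} (phase-averaged).
#'
#' @param baseline_ibi_ms mean IBI in ms (must lie in 250--1000; default
#'   400, about 150 bpm).
#' @param rmssd_target_ms target sample RMSSD in ms (0 gives a constant
#'   series).
#' @param decel_epochs data.frame with columns `onset_s`, `offset_s`,
#'   `delta_ibi_ms` of planted, non-overlapping deceleration epochs.
#' @param duration_s recording length in seconds (default 300).
#' @param ar_phi AR(1) coefficient of the beat-to-beat jitter (default 0.3).
#' @param resp_hz respiratory sinusoid frequency in Hz (default 0.6,
#'   infant respiration).
#' @param resp_frac fraction of squared RMSSD carried by the sinusoid
#'   (default 0.5).
#' @param seed integer seed.
#' @return object of class `cardiac_sim_config`.
#' @export
cardiac_sim_config <- function(baseline_ibi_ms = 400, rmssd_target_ms = 11.23,
                               decel_epochs = NULL, duration_s = 300,
                               ar_phi = 0.3, resp_hz = 0.6, resp_frac = 0.5,
                               seed = 1) {
  if (baseline_ibi_ms < 250 || baseline_ibi_ms > 1000)
    stop("baseline_ibi_ms must lie in [250, 1000]")
  if (rmssd_target_ms < 0) stop("rmssd_target_ms must be >= 0")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (is.null(decel_epochs) || !nrow(decel_epochs)) {
    decel_epochs <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                               delta_ibi_ms = numeric(0))
  }
  if (nrow(decel_epochs)) {
    stopifnot(all(c("onset_s", "offset_s", "delta_ibi_ms") %in%
                    names(decel_epochs)))
    decel_epochs <- decel_epochs[order(decel_epochs$onset_s), , drop = FALSE]
    if (any(decel_epochs$onset_s < 0) ||
        any(decel_epochs$offset_s > duration_s + 1e-9) ||
        any(decel_epochs$offset_s <= decel_epochs$onset_s))
      stop("decel epochs must be within [0, duration_s] with onset < offset")
    if (nrow(decel_epochs) > 1 &&
        any(decel_epochs$onset_s[-1] <
            decel_epochs$offset_s[-nrow(decel_epochs)]))
      stop("decel epochs must not overlap")
  }
  structure(list(baseline_ibi_ms = baseline_ibi_ms,
                 rmssd_target_ms = rmssd_target_ms,
                 decel_epochs = decel_epochs, duration_s = duration_s,
                 ar_phi = ar_phi, resp_hz = resp_hz, resp_frac = resp_frac,
                 seed = seed),
            class = "cardiac_sim_config")
}

#' Simulate an inter-beat-interval series
#'
#' @param cfg a [cardiac_sim_config()].
#' @return an [ibi_series()] starting at t = 0; errors if fewer than 10
#'   beats fit in `duration_s`.
#' @export
simulate_ibi <- function(cfg) {
  stopifnot(inherits(cfg, "cardiac_sim_config"))
  set.seed(cfg$seed)
  R <- cfg$rmssd_target_ms
  phi <- cfg$ar_phi
  n_max <- ceiling(cfg$duration_s * 1000 / cfg$baseline_ibi_ms * 1.5) + 20
  if (R > 0) {
    sf <- cfg$resp_frac
    sigma <- R * sqrt((1 - sf) * (1 + phi) / 2)
    Tbar <- cfg$baseline_ibi_ms / 1000
    A <- R * sqrt(sf / (1 - cos(2 * pi * cfg$resp_hz * Tbar)))
    init <- stats::rnorm(1, 0, sigma / sqrt(1 - phi^2))
    x <- as.numeric(stats::filter(stats::rnorm(n_max, 0, sigma), phi,
                                  method = "recursive", init = init))
    phase <- stats::runif(1, 0, 2 * pi)
  } else {
    x <- rep(0, n_max); A <- 0; phase <- 0
  }
  delta_at <- function(t) {
    d <- rep(0, length(t))
    ep <- cfg$decel_epochs
    if (nrow(ep)) {
      for (i in seq_len(nrow(ep)))
        d[t >= ep$onset_s[i] & t < ep$offset_s[i]] <- ep$delta_ibi_ms[i]
    }
    d
  }
  # two-pass beat-time construction: approximate beat times from the
  # baseline + jitter, then add time-dependent terms at those times
  t0 <- c(0, cumsum(cfg$baseline_ibi_ms + x)[-n_max]) / 1000
  s <- if (A > 0) A * sin(2 * pi * cfg$resp_hz * t0 + phase) else 0
  ibi <- cfg$baseline_ibi_ms + x + s + delta_at(t0)
  ibi <- pmax(ibi, 1)  # guard against non-physical non-positive intervals
  bt <- c(0, cumsum(ibi) / 1000)
  nkeep <- sum(bt <= cfg$duration_s + 1e-9)
  if (nkeep < 10) stop("duration too short: fewer than 10 beats")
  ibi_series(beat_times_s = bt[seq_len(nkeep)])
}

#' Simulate an EEG record of labeled 1-second segments
#'
#' Pink-noise (1/f power) channels synthesized in the frequency domain,
#' with 4--6 Hz power multiplied by `theta_gain` during sustained-attention
#' phases. Segments are aligned to task seconds and labeled by phase
#' midpoint, mirroring [segment_eeg()].
#'
#' @param phases an `attention_phases` data.frame
#'   (from [detect_sustained_attention()]), or `NULL` for unmodulated noise
#'   over `task_duration_s` seconds.
#' @param sr_hz sampling rate (>= 125; default 250).
#' @param n_channels number of channels (default 64).
#' @param theta_gain multiplicative 4--6 Hz power gain during attention
#'   (>= 0; 1 = no planted effect).
#' @param task_onset_s,task_duration_s task window when `phases` is `NULL`.
#' @param amplitude_uv per-channel RMS amplitude in microvolts (default 20).
#' @param seed integer seed.
#' @param frontal_channels passed to [eeg_segment_set()].
#' @return an [eeg_segment_set()].
#' @export
simulate_eeg <- function(phases = NULL, sr_hz = 250, n_channels = 64,
                         theta_gain = 1, task_onset_s = 0,
                         task_duration_s = 281, amplitude_uv = 20,
                         seed = 1, frontal_channels = NULL) {
  if (sr_hz < 125) stop("sr_hz must be >= 125")
  if (theta_gain < 0) stop("theta_gain must be >= 0")
  set.seed(seed)
  if (!is.null(phases)) {
    task_onset_s <- attr(phases, "task_onset_s")
    task_duration_s <- attr(phases, "task_end_s") - task_onset_s
    sa <- phases[phases$kind == "sustained_attention", , drop = FALSE]
  } else {
    sa <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  }
  n <- round(sr_hz)
  half <- floor(n / 2)
  freqs <- seq_len(half)
  base_amp <- freqs^(-0.5)
  starts <- task_onset_s + seq_len(floor(task_duration_s)) - 1
  labs <- vapply(starts, function(s)
    if (nrow(sa) && any(sa$onset_s <= s + 0.5 & s + 0.5 < sa$offset_s))
      "attention" else "inattention", character(1))
  theta_idx <- which(freqs >= 4 & freqs <= 6)
  nseg <- length(starts)
  segs <- array(0, dim = c(n_channels, n, nseg))
  for (g in seq_len(nseg)) {
    amp <- base_amp
    if (labs[g] == "attention") amp[theta_idx] <- amp[theta_idx] *
        sqrt(theta_gain)
    for (ch in seq_len(n_channels)) {
      z <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) *
        amp / sqrt(2)
      X <- complex(real = rep(0, n))
      X[1 + freqs] <- z
      X[n + 1 - freqs[freqs < half | n %% 2 == 1]] <-
        Conj(z[freqs < half | n %% 2 == 1])
      if (n %% 2 == 0) X[half + 1] <- complex(real = Re(z[half]) * sqrt(2))
      xr <- Re(stats::fft(X, inverse = TRUE)) / n
      sdx <- stats::sd(xr)
      segs[ch, , g] <- if (sdx > 0) xr / sdx * amplitude_uv else xr
    }
  }
  eeg_segment_set(segs, sr_hz, labs, frontal_channels = frontal_channels)
}

#' Cohort simulation configuration
#'
#' Linear structural model on standardized latent scales with planted
#' standardized effects, rescaled to realistic units, with per-variable
#' MCAR missingness at rates drawn from `missing_rate_range`. Defaults
#' match the study conditions the analysis chain assumes: n = 104 dyads,
#' standardized effects of about |0.25|, and missingness between 11% and
#' 23%.
#'
#' @param n number of dyads (default 104; at least 4).
#' @param beta_entropy_theta,beta_entropy_decel,beta_entropy_hrv,beta_hrv_decel
#'   planted standardized effects, each in (-1, 1). Defaults -0.24, -0.26,
#'   -0.25 and 0.25.
#' @param missing_rate_range per-variable MCAR rate range (default
#'   `c(0.11, 0.23)`).
#' @param covariate_effects named list of standardized effects of
#'   `age_months`, `sex`, `gestational_age_weeks` applied to every outcome
#'   (default 0.1 each).
#' @param p_male probability an infant is male (default 64/104).
#' @param seed integer seed.
#' @return object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n = 104,
                              beta_entropy_theta = -0.24,
                              beta_entropy_decel = -0.26,
                              beta_entropy_hrv = -0.25,
                              beta_hrv_decel = 0.25,
                              missing_rate_range = c(0.11, 0.23),
                              covariate_effects = list(
                                age_months = 0.1, sex = 0.1,
                                gestational_age_weeks = 0.1),
                              p_male = 64 / 104, seed = 1) {
  if (n < 4) stop("n must be >= 4")
  betas <- c(beta_entropy_theta, beta_entropy_decel, beta_entropy_hrv,
             beta_hrv_decel)
  if (any(abs(betas) >= 1)) stop("planted betas must lie in (-1, 1)")
  if (any(missing_rate_range < 0) || any(missing_rate_range >= 1) ||
      missing_rate_range[1] > missing_rate_range[2])
    stop("missing_rate_range must satisfy 0 <= low <= high < 1")
  structure(list(n = n, beta_entropy_theta = beta_entropy_theta,
                 beta_entropy_decel = beta_entropy_decel,
                 beta_entropy_hrv = beta_entropy_hrv,
                 beta_hrv_decel = beta_hrv_decel,
                 missing_rate_range = missing_rate_range,
                 covariate_effects = covariate_effects,
                 p_male = p_male, seed = seed),
            class = "cohort_sim_config")
}

# target means/SDs used to place latent z-scores on familiar scales
.COHORT_SCALES <- list(
  entropy_bits = c(0.79, 0.32),
  rmssd_ms = c(11.23, 4.65),
  mean_hr_bpm = c(150, 12),
  sa_duration_s = c(124.13, 67.12),
  deceleration_ms = c(20.16, 22.83),
  theta_change = c(0.01, 0.02),
  age_months = c(3.47, 0.39),
  gestational_age_weeks = c(39.21, 1.22))

#' Simulate a cohort of dyad records
#'
#' Draws standardized exogenous variables (caregiver entropy, infant age,
#' sex, gestational age), generates outcomes from the planted linear
#' structural model, rescales everything to familiar units (affine maps, so
#' standardized coefficients are unchanged), and applies per-variable MCAR
#' masks to the six study variables (covariates stay complete, as
#' demographics typically are). Errors if the planted coefficients imply a
#' non-positive residual variance for any outcome.
#'
#' @param cfg a [cohort_sim_config()].
#' @return data.frame of dyad records with columns `dyad_id`,
#'   `entropy_bits`, `rmssd_ms`, `mean_hr_bpm`, `sa_duration_s`,
#'   `deceleration_ms`, `theta_change`, `age_months`, `sex` (0/1),
#'   `gestational_age_weeks`; attributes `missing_rates` and `planted`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  g <- cfg$covariate_effects
  gam <- c(age = g$age_months %||% 0, sex = g$sex %||% 0,
           ga = g$gestational_age_weeks %||% 0)
  z_ent <- stats::rnorm(n)
  z_age <- stats::rnorm(n)
  sex <- stats::rbinom(n, 1, cfg$p_male)
  z_sex <- (sex - cfg$p_male) / sqrt(cfg$p_male * (1 - cfg$p_male))
  z_ga <- stats::rnorm(n)
  covs <- cbind(z_age, z_sex, z_ga)
  cov_part <- as.numeric(covs %*% gam)
  resid_sd <- function(var_sys, what) {
    v <- 1 - var_sys
    if (v <= 1e-8)
      stop("planted model implies non-positive residual variance for ", what)
    sqrt(v)
  }
  # hrv: b_eh * ent + gam * covs + e
  b_eh <- cfg$beta_entropy_hrv
  s_h <- resid_sd(b_eh^2 + sum(gam^2), "hrv")
  e_h <- stats::rnorm(n, 0, s_h)
  z_hrv <- b_eh * z_ent + cov_part + e_h
  # deceleration: b_ed * ent + b_hd * hrv + gam * covs + e. In terms of the
  # independent shocks, the systematic variance is
  # (b_ed + b_hd b_eh)^2 + sum((gam (1 + b_hd))^2) + b_hd^2 s_h^2
  b_ed <- cfg$beta_entropy_decel; b_hd <- cfg$beta_hrv_decel
  var_sys_d <- (b_ed + b_hd * b_eh)^2 + sum((gam * (1 + b_hd))^2) +
    b_hd^2 * s_h^2
  s_d <- resid_sd(var_sys_d, "deceleration")
  z_dec <- b_ed * z_ent + b_hd * z_hrv + cov_part + stats::rnorm(n, 0, s_d)
  # theta: b_et * ent + gam * covs + e
  b_et <- cfg$beta_entropy_theta
  s_t <- resid_sd(b_et^2 + sum(gam^2), "theta")
  z_th <- b_et * z_ent + cov_part + stats::rnorm(n, 0, s_t)
  # sustained-attention duration: covariates only (no planted signal effect)
  s_s <- resid_sd(sum(gam^2), "sa_duration")
  z_sa <- cov_part + stats::rnorm(n, 0, s_s)
  # mean HR: negatively related to HRV (HR-HRV dependence), rho = -0.3
  rho_hh <- -0.3
  z_hr <- rho_hh * z_hrv + stats::rnorm(n, 0, sqrt(1 - rho_hh^2))
  sc <- .COHORT_SCALES
  df <- data.frame(
    dyad_id = sprintf("dyad%03d", seq_len(n)),
    entropy_bits = sc$entropy_bits[1] + sc$entropy_bits[2] * z_ent,
    rmssd_ms = sc$rmssd_ms[1] + sc$rmssd_ms[2] * z_hrv,
    mean_hr_bpm = sc$mean_hr_bpm[1] + sc$mean_hr_bpm[2] * z_hr,
    sa_duration_s = sc$sa_duration_s[1] + sc$sa_duration_s[2] * z_sa,
    deceleration_ms = sc$deceleration_ms[1] + sc$deceleration_ms[2] * z_dec,
    theta_change = sc$theta_change[1] + sc$theta_change[2] * z_th,
    age_months = sc$age_months[1] + sc$age_months[2] * z_age,
    sex = sex,
    gestational_age_weeks = sc$gestational_age_weeks[1] +
      sc$gestational_age_weeks[2] * z_ga,
    stringsAsFactors = FALSE)
  study_vars <- c("entropy_bits", "rmssd_ms", "mean_hr_bpm", "sa_duration_s",
                  "deceleration_ms", "theta_change")
  rates <- stats::runif(length(study_vars), cfg$missing_rate_range[1],
                        cfg$missing_rate_range[2])
  names(rates) <- study_vars
  for (v in study_vars)
    df[[v]][stats::runif(n) < rates[v]] <- NA_real_
  attr(df, "missing_rates") <- rates
  attr(df, "planted") <- list(beta_entropy_theta = b_et,
                              beta_entropy_decel = b_ed,
                              beta_entropy_hrv = b_eh,
                              beta_hrv_decel = b_hd,
                              covariate_effects = gam)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
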