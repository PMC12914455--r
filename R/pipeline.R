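# End-to-end orchestration: simulate dyads, score entropy / HRV / attention
# / theta, assemble the cohort table, and fit the regression models, with a
# run manifest recording seeds, hashes and per-dyad exclusions.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every stage parameter named, so
#' deviations from defaults are visible in diffs. Stage toggles select
#' which measurement stages run; the stats stage consumes whatever
#' variables earlier stages produced. All randomness flows from the root
#' `seed` through per-stage, per-dyad derived seeds recorded in the
#' manifest.
#'
#' @param n_dyads number of dyads (default 104).
#' @param seed root seed (default 1).
#' @param stages character subset of
#'   `c("entropy", "hrv", "attention", "eeg", "stats")`; the synthetic
#'   input stage always runs. EEG is the costliest stage and can be
#'   dropped for large simulation studies.
#' @return nested configuration list (class `run_config`).
#' @export
default_run_config <- function(n_dyads = 104, seed = 1,
                               stages = c("entropy", "hrv", "attention",
                                          "stats")) {
  structure(list(
    n_dyads = n_dyads,
    seed = seed,
    stages = stages,
    caregiver = list(mean_dwell_s = 2, duration_s = 300,
                     entropy_mean_bits = 0.79, entropy_sd_bits = 0.32,
                     n_states = 8),
    cardiac = list(baseline_ibi_ms = 400, baseline_duration_s = 300,
                   rmssd_mean_ms = 11.23, rmssd_sd_ms = 4.65,
                   min_duration_s = 60),
    attention = list(task_duration_s = 281, prestim_window_s = 5,
                     run_len = 5, baseline_len = 5,
                     decel_mean_ms = 20.16, decel_sd_ms = 22.83,
                     epoch_starts_s = c(10, 105, 200),
                     epoch_length_s = 70),
    eeg = list(sr_hz = 250, n_channels = 64, theta_gain_base = 1.5,
               theta_gain_log2_sd = 0.4, reject_z = 3, min_segments = 20,
               theta_band = c(4, 6), total_band = c(1, 50)),
    effects = list(beta_entropy_hrv = -0.25, beta_entropy_decel = -0.26,
                   beta_entropy_theta = -0.24, beta_hrv_decel = 0.25),
    missing_rate_range = c(0.11, 0.23),
    models = list(
      list(outcome = "rmssd_ms", predictors = "entropy_bits",
           covariates = c("age_months", "sex", "gestational_age_weeks")),
      list(outcome = "deceleration_ms", predictors = "entropy_bits",
           covariates = c("age_months", "sex", "gestational_age_weeks"))),
    winsorize_hrv = c(5, 95)),
    class = "run_config")
}

.validate_run_config <- function(config) {
  if (inherits(config, "run_config")) return(config)
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  base <- default_run_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(base, config)
  if (!is.numeric(merged$n_dyads) || merged$n_dyads < 1)
    stop("n_dyads must be a positive integer")
  bad <- setdiff(merged$stages, c("entropy", "hrv", "attention", "eeg",
                                  "stats"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  class(merged) <- "run_config"
  merged
}

# small deterministic string hash (djb2 variant) for manifest bookkeeping
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

.stage_seed <- function(root, stage, dyad = 0) {
  (root * 100003 + stage * 10007 + dyad * 101) %% 2147483647
}

#' Run the full synthetic-dyad pipeline
#'
#' For each dyad: simulate a caregiver signal sequence whose target entropy
#' rate, baseline RMSSD, planted deceleration and theta gain follow the
#' configured linear structural model; run the enabled measurement stages
#' (entropy scoring, baseline HRV, heart-rate-defined sustained attention,
#' relative frontal theta); assemble the per-dyad records (with MCAR
#' missingness applied to the measured study variables); winsorize RMSSD at
#' the cohort level; and fit the configured FIML regressions. Mean baseline
#' heart rate is added as a covariate to any model involving RMSSD. The
#' run is deterministic given the root seed; a manifest records derived
#' seeds, a config hash, and a machine-readable exclusion reason for every
#' dyad-variable hole the pipeline created.
#'
#' @param config a config list from [default_run_config()], a partial list
#'   of overrides, or a YAML file path.
#' @param outdir optional directory: writes `cohort.csv`, `results.csv`
#'   and `manifest.yaml` when given.
#' @return list of class `run_result`: `cohort` (data.frame), `fits` (list
#'   of `regression_result`), `descriptives`, `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), outdir = NULL) {
  config <- .validate_run_config(config)
  n <- config$n_dyads
  root <- config$seed
  stages <- config$stages
  ef <- config$effects
  set.seed(.stage_seed(root, 1))
  z_ent <- stats::rnorm(n)
  z_age <- stats::rnorm(n)
  sex <- stats::rbinom(n, 1, 64 / 104)
  z_ga <- stats::rnorm(n)
  gam <- 0.1
  covp <- gam * (z_age + (sex - mean(sex)) / max(stats::sd(sex), 1e-6) +
                   z_ga)
  s_h <- sqrt(1 - ef$beta_entropy_hrv^2 - 3 * gam^2)
  z_hrv <- ef$beta_entropy_hrv * z_ent + covp +
    stats::rnorm(n, 0, s_h)
  var_dec <- (ef$beta_entropy_decel + ef$beta_hrv_decel *
                ef$beta_entropy_hrv)^2 +
    3 * (gam * (1 + ef$beta_hrv_decel))^2 + ef$beta_hrv_decel^2 * s_h^2
  if (var_dec >= 1) stop("planted effects imply non-positive residual variance")
  z_dec <- ef$beta_entropy_decel * z_ent + ef$beta_hrv_decel * z_hrv +
    covp + stats::rnorm(n, 0, sqrt(1 - var_dec))
  s_t <- sqrt(1 - ef$beta_entropy_theta^2 - 3 * gam^2)
  z_th <- ef$beta_entropy_theta * z_ent + covp + stats::rnorm(n, 0, s_t)
  cg <- config$caregiver; cd <- config$cardiac; at <- config$attention
  eg <- config$eeg
  hmax <- log2(cg$n_states - 1)
  target_h <- pmin(pmax(cg$entropy_mean_bits + cg$entropy_sd_bits * z_ent,
                        0.02), hmax - 0.02)
  rmssd_target <- pmax(cd$rmssd_mean_ms + cd$rmssd_sd_ms * z_hrv, 0.5)
  decel_delta <- at$decel_mean_ms + at$decel_sd_ms * z_dec
  theta_gain <- pmax(eg$theta_gain_base * 2^(eg$theta_gain_log2_sd * z_th),
                     0.05)
  rows <- list()
  exclusions <- list()
  seeds <- list()
  exclude <- function(dyad, variable, reason) {
    exclusions[[length(exclusions) + 1]] <<- data.frame(
      dyad_id = dyad, variable = variable, reason = reason)
  }
  for (i in seq_len(n)) {
    id <- sprintf("dyad%03d", i)
    rec <- list(dyad_id = id,
                age_months = 3.47 + 0.39 * z_age[i],
                sex = sex[i],
                gestational_age_weeks = 39.21 + 1.22 * z_ga[i])
    if ("entropy" %in% stages) {
      sd_cg <- .stage_seed(root, 2, i)
      seeds[[paste0("entropy_", id)]] <- sd_cg
      cfg <- caregiver_sim_config(
        transition_matrix = entropy_matched_matrix(target_h[i],
                                                   cg$n_states),
        mean_dwell_s = cg$mean_dwell_s, duration_s = cg$duration_s,
        seed = sd_cg)
      log <- simulate_caregiver_sequence(cfg)
      seqn <- events_to_state_sequence(log)
      if (length(seqn$states) < 2) {
        rec$entropy_bits <- NA_real_
        exclude(id, "entropy_bits", "fewer than 2 coded states")
      } else {
        er <- entropy_rate(estimate_transition_model(seqn))
        rec$entropy_bits <- er$value_bits
        rec$n_transitions <- er$n_transitions
      }
    }
    if ("hrv" %in% stages) {
      sd_hb <- .stage_seed(root, 3, i)
      seeds[[paste0("hrv_", id)]] <- sd_hb
      base <- simulate_ibi(cardiac_sim_config(
        baseline_ibi_ms = cd$baseline_ibi_ms,
        rmssd_target_ms = rmssd_target[i],
        duration_s = cd$baseline_duration_s, seed = sd_hb))
      hrv <- baseline_hrv(base, min_duration_s = cd$min_duration_s)
      if (!hrv$usable) {
        rec$rmssd_ms <- NA_real_
        rec$mean_hr_bpm <- NA_real_
        exclude(id, "rmssd_ms", "baseline recording below usable duration")
      } else {
        rec$rmssd_ms <- hrv$rmssd_ms
        rec$mean_hr_bpm <- hrv$mean_hr_bpm
      }
    }
    task <- NULL
    phases <- NULL
    if ("attention" %in% stages || "eeg" %in% stages) {
      sd_tk <- .stage_seed(root, 4, i)
      seeds[[paste0("attention_", id)]] <- sd_tk
      epochs <- data.frame(
        onset_s = at$epoch_starts_s + at$prestim_window_s,
        offset_s = at$epoch_starts_s + at$prestim_window_s +
          at$epoch_length_s,
        delta_ibi_ms = decel_delta[i])
      task <- simulate_ibi(cardiac_sim_config(
        baseline_ibi_ms = cd$baseline_ibi_ms,
        rmssd_target_ms = rmssd_target[i],
        decel_epochs = epochs,
        duration_s = at$task_duration_s + at$prestim_window_s,
        seed = sd_tk))
      # looking is coupled to the attention-eliciting epochs: screen-directed
      # gaze co-occurs with the planted decelerations, gating SA onsets
      look <- looking_record(
        data.frame(onset_s = epochs$onset_s, offset_s = epochs$offset_s),
        task_onset_s = at$prestim_window_s,
        task_duration_s = at$task_duration_s)
      phases <- detect_sustained_attention(task, look,
                                           run_len = at$run_len,
                                           baseline_len = at$baseline_len)
      if ("attention" %in% stages) {
        summ <- attention_summary(task, phases,
                                  prestim_window_s = at$prestim_window_s)
        rec$sa_duration_s <- summ$total_sa_duration_s
        if (is.na(summ$mean_deceleration_ms))
          exclude(id, "deceleration_ms", "no sustained-attention phase")
        rec$deceleration_ms <- summ$mean_deceleration_ms
      }
    }
    if ("eeg" %in% stages) {
      sd_eeg <- .stage_seed(root, 5, i)
      seeds[[paste0("eeg_", id)]] <- sd_eeg
      segs <- simulate_eeg(phases, sr_hz = eg$sr_hz,
                           n_channels = eg$n_channels,
                           theta_gain = theta_gain[i], seed = sd_eeg)
      segs <- reject_amplitude_outliers(segs, z = eg$reject_z)
      spec <- relative_theta(segs, theta_band = eg$theta_band,
                             total_band = eg$total_band,
                             min_segments = eg$min_segments)
      if (!spec$usable)
        exclude(id, "theta_change",
                sprintf("fewer than %d usable EEG segments",
                        eg$min_segments))
      if (spec$usable && is.na(spec$theta_change))
        exclude(id, "theta_change", "a condition has zero segments")
      rec$theta_change <- spec$theta_change
    }
    rows[[i]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  allcols <- unique(unlist(lapply(rows, names)))
  cohort <- assemble_cohort(list(measurements = do.call(
    rbind, lapply(rows, function(r) {
      for (cn in setdiff(allcols, names(r))) r[[cn]] <- NA
      r[allcols]
    }))))
  # MCAR masks on measured study variables
  set.seed(.stage_seed(root, 6))
  study_vars <- intersect(c("entropy_bits", "rmssd_ms", "mean_hr_bpm",
                            "sa_duration_s", "deceleration_ms",
                            "theta_change"), names(cohort))
  rates <- stats::runif(length(study_vars), config$missing_rate_range[1],
                        config$missing_rate_range[2])
  names(rates) <- study_vars
  for (v in study_vars) {
    hit <- stats::runif(n) < rates[v] & !is.na(cohort[[v]])
    cohort[[v]][hit] <- NA
    for (j in which(hit))
      exclude(cohort$dyad_id[j], v, "MCAR mask")
  }
  if ("rmssd_ms" %in% names(cohort)) {
    cohort$rmssd_raw_ms <- cohort$rmssd_ms
    cohort$rmssd_ms <- winsorize(cohort$rmssd_ms,
                                 config$winsorize_hrv[1],
                                 config$winsorize_hrv[2])
  }
  fits <- list()
  if ("stats" %in% stages) {
    for (mi in seq_along(config$models)) {
      ms <- config$models[[mi]]
      have <- c(ms$outcome, ms$predictors, ms$covariates) %in% names(cohort)
      if (!all(have)) next
      covs <- ms$covariates
      if (("rmssd_ms" %in% c(ms$outcome, ms$predictors)) &&
          "mean_hr_bpm" %in% names(cohort) &&
          !"mean_hr_bpm" %in% c(covs, ms$predictors, ms$outcome))
        covs <- c(covs, "mean_hr_bpm")  # enforced HR covariate with RMSSD
      fits[[paste0(ms$outcome, "~", paste(ms$predictors, collapse = "+"))]] <-
        fit_fiml_regression(cohort, ms$outcome, ms$predictors, covs)
    }
  }
  excl <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(dyad_id = character(0), variable = character(0),
               reason = character(0))
  manifest <- list(config_hash = .config_hash(config),
                   seed = root,
                   stage_seeds = seeds,
                   n_dyads = n,
                   n_analyzed = nrow(cohort),
                   exclusions = excl,
                   missing_rates = rates,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   package_version = as.character(
                     utils::packageVersion("predyad")))
  out <- structure(list(cohort = cohort, fits = fits,
                        descriptives = cohort_report(cohort),
                        manifest = manifest),
                   class = "run_result")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cohort, file.path(outdir, "cohort.csv"),
                     row.names = FALSE)
    res <- do.call(rbind, lapply(names(fits), function(nm) {
      cf <- fits[[nm]]$coefficients
      cbind(model = nm, cf, estimator = fits[[nm]]$estimator,
            n = fits[[nm]]$n_effective)
    }))
    if (!is.null(res))
      utils::write.csv(res, file.path(outdir, "results.csv"),
                       row.names = FALSE)
    man <- manifest
    man$exclusions <- NULL
    man$timestamp <- NULL  # keep written outputs byte-identical across runs
    yaml::write_yaml(man, file.path(outdir, "manifest.yaml"))
    utils::write.csv(excl, file.path(outdir, "exclusions.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %d dyads, %d model fits, %d exclusion records\n",
              x$manifest$n_dyads, length(x$fits),
              nrow(x$manifest$exclusions)))
  invisible(x)
}

#' Assemble per-stage outputs into one cohort table
#'
#' Outer join across stage output tables on `dyad_id`; measurements absent
#' from a stage's output become missing values. Duplicate `dyad_id` within
#' a stage is an error. The result is sorted by `dyad_id` so assembly is
#' invariant to input row order.
#'
#' @param stage_tables named list of data.frames, each with a `dyad_id`
#'   column.
#' @return data.frame keyed by `dyad_id`.
#' @export
assemble_cohort <- function(stage_tables) {
  stopifnot(is.list(stage_tables), length(stage_tables) >= 1)
  for (nm in names(stage_tables)) {
    tb <- stage_tables[[nm]]
    if (!"dyad_id" %in% names(tb))
      stop("stage table lacks dyad_id: ", nm)
    if (anyDuplicated(tb$dyad_id))
      stop("duplicate dyad_id in stage table: ", nm)
  }
  out <- Reduce(function(a, b) merge(a, b, by = "dyad_id", all = TRUE),
                stage_tables)
  out <- out[order(out$dyad_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Descriptive statistics table for a cohort
#'
#' Mean, SD, range, skewness and excess kurtosis for every numeric study
#' variable, computed on observed values.
#'
#' @param cohort cohort data.frame.
#' @return data.frame of descriptives.
#' @export
cohort_report <- function(cohort) {
  vars <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  vars <- setdiff(vars, "sex")
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]][!is.na(cohort[[v]])]
    if (length(x) < 2) {
      return(data.frame(variable = v, n = length(x), mean = NA, sd = NA,
                        min = NA, max = NA, skew = NA, kurtosis = NA))
    }
    m <- mean(x); s <- stats::sd(x)
    z <- (x - m) / s
    data.frame(variable = v, n = length(x), mean = m, sd = s,
               min = min(x), max = max(x),
               skew = mean(z^3),
               kurtosis = mean(z^4) - 3)
  })
  do.call(rbind, rows)
}
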