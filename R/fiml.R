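# Regression under missing data: FIML with observed-information or sandwich
# standard errors, multiple imputation by chained equations, listwise
# deletion, covariate screening, quadratic and sex-moderation checks, and
# sensitivity (minimal-detectable-effect) power analysis.
#
# FIML here maximizes the observed-data multivariate-normal log-likelihood
# over the saturated mean/covariance of (outcome, predictors) via EM;
# regression coefficients are derived from the fitted covariance and
# standardized using the FIML-estimated full-sample variances (not
# complete-case SDs), for consistency under missingness. p-values are
# two-sided Wald tests; no multiple-testing correction is applied.

# standardized regression betas implied by a joint (mu, Sigma); variable 1
# is the outcome
.std_betas_from_sigma <- function(Sigma) {
  p <- ncol(Sigma)
  Sxx <- Sigma[-1, -1, drop = FALSE]
  Sxy <- Sigma[-1, 1]
  b_raw <- solve(Sxx, Sxy)
  b_raw * sqrt(diag(Sxx)) / sqrt(Sigma[1, 1])
}

.regression_result <- function(outcome, terms, beta, se, estimator, n,
                               converged = TRUE, loglik = NA_real_,
                               df = Inf, extra = list()) {
  z <- beta / se
  p <- if (is.finite(df[1])) 2 * stats::pt(-abs(z), df)
       else 2 * stats::pnorm(-abs(z))
  coef <- data.frame(term = terms, beta = beta, se = se, statistic = z,
                     p_value = p, row.names = NULL)
  structure(c(list(outcome = outcome, coefficients = coef,
                   estimator = estimator, n_effective = n,
                   converged = converged, loglik = loglik), extra),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s regression of %s (n = %d%s)\n",
              x$estimator, x$outcome, x$n_effective,
              if (isTRUE(x$converged)) "" else ", NOT CONVERGED"))
  cf <- x$coefficients
  cf$beta <- round(cf$beta, 4); cf$se <- round(cf$se, 4)
  cf$statistic <- round(cf$statistic, 3); cf$p_value <- signif(cf$p_value, 3)
  print(cf)
  if (any(abs(x$coefficients$beta) > 1))
    cat("  note: |standardized beta| > 1 for some term\n")
  invisible(x)
}

#' Tidy coefficients of a regression result
#' @param x a `regression_result`.
#' @return data.frame with term, beta, se, statistic, p_value.
#' @export
coef_table <- function(x) x$coefficients

.build_model_matrix <- function(data, outcome, predictors, covariates) {
  terms <- unique(c(predictors, covariates))
  Y <- .model_matrix_vars(data, c(outcome, terms))
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]
  for (v in colnames(Y)) {
    if (all(is.na(Y[, v])))
      stop("variable has no observed values: ", v)
    if (stats::var(Y[, v], na.rm = TRUE) < 1e-12)
      stop("variable is constant: ", v)
  }
  Y
}

#' Full-information maximum-likelihood regression
#'
#' Fits a linear regression of `outcome` on `predictors` and `covariates`
#' using all available data: the joint multivariate-normal mean and
#' covariance of the model variables is estimated by EM over missingness
#' patterns (every case contributes its observed variables), and the
#' regression coefficients are read off the fitted covariance.
#' Standardized betas use the FIML-estimated variances. Standard errors
#' come from the observed information matrix (numeric Hessian of the
#' observed-data log-likelihood) carried through the delta method;
#' `robust = TRUE` replaces them with sandwich (Huber-White) standard
#' errors built from per-case scores. With complete data the estimates
#' coincide with ordinary least squares.
#'
#' @param data data.frame of dyad records (`NA` = missing).
#' @param outcome outcome variable name.
#' @param predictors character vector of focal predictor names.
#' @param covariates character vector of covariate names (reported too; all
#'   coefficients are standardized).
#' @param se compute standard errors (default `TRUE`; skipping them makes
#'   repeated fits in simulations much faster).
#' @param robust use sandwich standard errors (default `FALSE`).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @return a `regression_result`; non-convergence of EM is reported in
#'   `$converged` and a singular model errors with diagnostics.
#' @export
fit_fiml_regression <- function(data, outcome, predictors,
                                covariates = character(0), se = TRUE,
                                robust = FALSE, tol = 1e-8) {
  Y <- .build_model_matrix(data, outcome, predictors, covariates)
  p <- ncol(Y)
  fit <- .mvn_em(Y, tol = tol)
  ch <- tryCatch(chol(fit$Sigma[-1, -1, drop = FALSE]),
                 error = function(e) NULL)
  if (is.null(ch))
    stop("singular predictor covariance; model not identified")
  beta <- .std_betas_from_sigma(fit$Sigma)
  terms <- colnames(Y)[-1]
  if (!se) {
    return(.regression_result(outcome, terms, beta,
                              rep(NA_real_, length(beta)),
                              if (robust) "fiml_robust" else "fiml",
                              fit$n, fit$converged, fit$loglik,
                              extra = list(mu = fit$mu, Sigma = fit$Sigma)))
  }
  theta <- .theta_pack(fit$mu, fit$Sigma)
  pats <- fit$patterns
  f <- function(th) .obs_loglik_theta(th, p, pats)
  H <- .num_hessian(f, theta)
  A <- -H
  Vtheta <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Vtheta))
    stop("observed information is singular; cannot compute FIML SEs")
  g <- function(th) .std_betas_from_sigma(.theta_unpack(th, p)$Sigma)
  J <- .num_jacobian(g, theta)
  if (robust) {
    S <- .case_scores(theta, p, pats)
    B <- crossprod(S)
    Vtheta <- Vtheta %*% B %*% Vtheta
  }
  V <- J %*% Vtheta %*% t(J)
  se_b <- sqrt(pmax(diag(V), 0))
  .regression_result(outcome, terms, beta, se_b,
                     if (robust) "fiml_robust" else "fiml",
                     fit$n, fit$converged, fit$loglik,
                     extra = list(mu = fit$mu, Sigma = fit$Sigma))
}

# per-case score matrix (n x d) by central differences of case log-likelihoods
.case_scores <- function(theta, p, pats, eps = 1e-5) {
  n <- attr(pats, "n")
  case_ll <- function(th) {
    par <- .theta_unpack(th, p)
    out <- numeric(n)
    pos <- 1
    for (pt in pats) {
      o <- pt$obs
      ch <- chol(par$Sigma[o, o, drop = FALSE])
      logdet <- 2 * sum(log(diag(ch)))
      Sinv <- chol2inv(ch)
      D <- sweep(pt$Y, 2, par$mu[o])
      quad <- rowSums((D %*% Sinv) * D)
      out[pos:(pos + pt$n - 1)] <-
        -0.5 * (length(o) * log(2 * pi) + logdet + quad)
      pos <- pos + pt$n
    }
    out
  }
  d <- length(theta)
  h <- eps * (abs(theta) + 1)
  S <- matrix(0, n, d)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- h[i]
    S[, i] <- (case_ll(theta + ei) - case_ll(theta - ei)) / (2 * h[i])
  }
  S
}

#' FIML regression with robust (sandwich) standard errors
#'
#' @inheritParams fit_fiml_regression
#' @return a `regression_result` with `estimator = "fiml_robust"`.
#' @export
fit_robust <- function(data, outcome, predictors, covariates = character(0),
                       tol = 1e-8) {
  fit_fiml_regression(data, outcome, predictors, covariates,
                      se = TRUE, robust = TRUE, tol = tol)
}

#' Multiple imputation by chained equations (normal-linear conditionals)
#'
#' Imputes each incomplete model variable from a Bayesian normal linear
#' regression on the other variables (draws of the residual variance and
#' coefficients, then draws of the missing values), cycling `maxit` times
#' per imputation. Normal-linear conditionals (rather than
#' predictive-mean-matching) keep the procedure fully determined by the
#' seed. Per-imputation standardized OLS estimates are pooled by
#' combining rules (between/within variance, Barnard-Rubin style degrees
#' of freedom).
#'
#' @inheritParams fit_fiml_regression
#' @param m number of imputations (default 25).
#' @param maxit chained-equation cycles per imputation (default 10).
#' @param seed integer seed.
#' @return a `regression_result` with `estimator = "mice"`.
#' @export
fit_mice <- function(data, outcome, predictors, covariates = character(0),
                     m = 25, maxit = 10, seed = 1) {
  Y <- .build_model_matrix(data, outcome, predictors, covariates)
  set.seed(seed)
  p <- ncol(Y)
  n <- nrow(Y)
  miss_cols <- which(colSums(is.na(Y)) > 0)
  qs <- matrix(0, m, p - 1)
  us <- matrix(0, m, p - 1)
  for (imp in seq_len(m)) {
    Z <- Y
    for (j in miss_cols) {
      nas <- is.na(Z[, j])
      Z[nas, j] <- sample(Z[!nas, j], sum(nas), replace = TRUE)
    }
    if (length(miss_cols)) {
      for (it in seq_len(maxit)) {
        for (j in miss_cols) {
          nas <- is.na(Y[, j])
          if (!any(nas)) next
          X <- cbind(1, Z[, -j, drop = FALSE])
          yobs <- Z[!nas, j]
          Xo <- X[!nas, , drop = FALSE]
          XtX <- crossprod(Xo)
          R <- tryCatch(chol(XtX), error = function(e)
            chol(XtX + diag(1e-8 * mean(diag(XtX)), ncol(XtX))))
          bhat <- backsolve(R, forwardsolve(t(R), crossprod(Xo, yobs)))
          res <- yobs - Xo %*% bhat
          df <- max(1, sum(!nas) - ncol(Xo))
          sigma2 <- sum(res^2) / stats::rchisq(1, df)
          bstar <- bhat + backsolve(R, stats::rnorm(ncol(Xo))) * sqrt(sigma2)
          Z[nas, j] <- X[nas, , drop = FALSE] %*% bstar +
            stats::rnorm(sum(nas), 0, sqrt(sigma2))
        }
      }
    }
    fit <- .std_ols(Z)
    qs[imp, ] <- fit$beta
    us[imp, ] <- fit$se^2
  }
  qbar <- colMeans(qs)
  W <- colMeans(us)
  B <- if (m > 1) apply(qs, 2, stats::var) else rep(0, p - 1)
  Tvar <- W + (1 + 1 / m) * B
  r <- ifelse(W > 0, (1 + 1 / m) * B / W, Inf)
  df <- ifelse(B > 0, (m - 1) * (1 + 1 / r)^2, Inf)
  .regression_result(colnames(Y)[1], colnames(Y)[-1], qbar, sqrt(Tvar),
                     "mice", n, TRUE, df = df)
}

# standardized OLS on a complete numeric matrix (outcome first)
.std_ols <- function(Z) {
  Zs <- scale(Z)
  fit <- stats::lm.fit(cbind(1, Zs[, -1, drop = FALSE]), Zs[, 1])
  res <- fit$residuals
  dfres <- nrow(Zs) - ncol(Zs)
  s2 <- sum(res^2) / dfres
  XtXinv <- chol2inv(chol(crossprod(cbind(1, Zs[, -1, drop = FALSE]))))
  se <- sqrt(s2 * diag(XtXinv))[-1]
  list(beta = fit$coefficients[-1], se = se, df = dfres)
}

#' Listwise-deletion (complete-case) regression
#'
#' Standardized OLS on cases observed on every model variable.
#'
#' @inheritParams fit_fiml_regression
#' @return a `regression_result` with `estimator = "listwise"`.
#' @export
fit_listwise <- function(data, outcome, predictors,
                         covariates = character(0)) {
  Y <- .build_model_matrix(data, outcome, predictors, covariates)
  cc <- stats::complete.cases(Y)
  k <- ncol(Y) - 1
  if (sum(cc) < k + 2)
    stop("fewer complete cases than predictors + 2")
  Z <- Y[cc, , drop = FALSE]
  fit <- .std_ols(Z)
  .regression_result(colnames(Y)[1], colnames(Y)[-1], fit$beta, fit$se,
                     "listwise", sum(cc), df = fit$df)
}

#' Screen candidate covariates by bivariate association
#'
#' Tests each candidate against every focal variable (predictors and
#' outcomes) using a fixed mapping by variable type: Pearson correlation
#' for two continuous variables, a two-sample t test when exactly one of
#' the pair is binary, and a chi-square contingency test when both are
#' binary/categorical. A candidate is selected when any of its tests has
#' `p < alpha`. Constant candidates are skipped with a warning.
#'
#' @param data data.frame.
#' @param candidates character vector of candidate covariate names.
#' @param targets character vector of focal predictor/outcome names.
#' @param alpha selection threshold (default 0.10).
#' @return list with `selected` (character) and `tests` (data.frame of
#'   candidate, target, test, statistic, p_value).
#' @export
covariate_screen <- function(data, candidates, targets, alpha = 0.10) {
  is_bin <- function(x) length(unique(x[!is.na(x)])) <= 2
  rows <- list()
  for (cand in candidates) {
    x <- data[[cand]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("skipping constant candidate: ", cand)
      next
    }
    for (tg in targets) {
      y <- data[[tg]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 10) next
      xx <- x[ok]; yy <- y[ok]
      res <- tryCatch({
        if (!is.numeric(xx) || !is.numeric(yy) ||
            (is_bin(xx) && is_bin(yy))) {
          tst <- suppressWarnings(stats::chisq.test(table(xx, yy)))
          c("chisq", unname(tst$statistic), tst$p.value)
        } else if (is_bin(xx)) {
          tst <- stats::t.test(yy ~ factor(xx))
          c("t", unname(tst$statistic), tst$p.value)
        } else if (is_bin(yy)) {
          tst <- stats::t.test(xx ~ factor(yy))
          c("t", unname(tst$statistic), tst$p.value)
        } else {
          tst <- stats::cor.test(xx, yy)
          c("cor", unname(tst$estimate), tst$p.value)
        }
      }, error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1]] <- data.frame(
        candidate = cand, target = tg, test = res[1],
        statistic = as.numeric(res[2]), p_value = as.numeric(res[3]))
    }
  }
  tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(candidate = character(0), target = character(0),
               test = character(0), statistic = numeric(0),
               p_value = numeric(0))
  sel <- unique(tests$candidate[tests$p_value < alpha])
  list(selected = sel, tests = tests)
}

#' Quadratic robustness check for a focal predictor
#'
#' Adds a centered-and-squared focal term to the model and reports its
#' coefficient and p-value, to assess whether a linear association is
#' driven by extreme values.
#'
#' @inheritParams fit_fiml_regression
#' @param focal name of the focal (continuous) predictor.
#' @return a `regression_result`; the quadratic term is named
#'   `<focal>_sq` and flagged in `$quadratic_term`.
#' @export
quadratic_check <- function(data, outcome, focal,
                            covariates = character(0), tol = 1e-8) {
  x <- data[[focal]]
  if (sum(!is.na(x)) < 10) stop("focal observed for fewer than 10 records")
  if (stats::var(x, na.rm = TRUE) < 1e-12) stop("focal is constant")
  sq <- paste0(focal, "_sq")
  data[[sq]] <- (x - mean(x, na.rm = TRUE))^2
  res <- fit_fiml_regression(data, outcome, c(focal, sq), covariates,
                             tol = tol)
  res$quadratic_term <- sq
  res
}

#' Sex-moderation (interaction) check
#'
#' Fits `outcome ~ predictor + sex + predictor:sex (+ covariates)` with the
#' interaction built from centered components, and reports the interaction
#' coefficient and p-value.
#'
#' @inheritParams fit_fiml_regression
#' @param predictor focal predictor name.
#' @param sex_var binary sex variable name (default `"sex"`).
#' @return a `regression_result`; the interaction term is flagged in
#'   `$interaction_term`.
#' @export
sex_moderation <- function(data, outcome, predictor,
                           covariates = character(0), sex_var = "sex",
                           tol = 1e-8) {
  s <- data[[sex_var]]
  if (length(unique(s[!is.na(s)])) < 2)
    stop("both sexes must be present")
  int <- paste0(predictor, "_x_", sex_var)
  pc <- data[[predictor]] - mean(data[[predictor]], na.rm = TRUE)
  sc <- s - mean(s, na.rm = TRUE)
  data[[int]] <- pc * sc
  res <- fit_fiml_regression(data, outcome, c(predictor, sex_var, int),
                             covariates, tol = tol)
  res$interaction_term <- int
  res
}

#' Minimal detectable standardized effect (sensitivity analysis)
#'
#' Smallest standardized coefficient of one focal predictor (with
#' `n_covariates` mutually uncorrelated covariates also in the model) whose
#' two-sided test reaches the target power at the given alpha and sample
#' size. Solved by inverting the noncentral-F power function of the
#' 1-numerator-df test: with standardized effect \eqn{\beta}, the effect
#' size is \eqn{f^2 = \beta^2/(1-\beta^2)} and the noncentrality is
#' \eqn{\lambda = n f^2} on \eqn{F(1, n - k - 2)} with `k = n_covariates`.
#' [mde_power_sim()] provides the Monte-Carlo cross-check.
#'
#' @param n sample size (must exceed `n_covariates + 2`).
#' @param alpha two-sided type-I error rate (default 0.05).
#' @param power target power (default 0.80).
#' @param n_covariates number of covariates in the model (default 3).
#' @return list with `mde_beta`, `df2`, `ncp`, plus the inputs; errors if
#'   the target power is unattainable.
#' @export
sensitivity_mde <- function(n, alpha = 0.05, power = 0.80,
                            n_covariates = 3) {
  if (n <= n_covariates + 2) stop("n must exceed n_covariates + 2")
  df2 <- n - n_covariates - 2
  crit <- stats::qf(1 - alpha, 1, df2)
  pw <- function(beta) {
    f2 <- beta^2 / (1 - beta^2)
    1 - stats::pf(crit, 1, df2, ncp = n * f2)
  }
  if (pw(0.999) < power) stop("target power unattainable at this n")
  root <- stats::uniroot(function(b) pw(b) - power, c(1e-8, 0.999),
                         tol = 1e-10)$root
  list(mde_beta = root, n = n, alpha = alpha, power = power,
       n_covariates = n_covariates, df2 = df2,
       ncp = n * root^2 / (1 - root^2))
}

#' Monte-Carlo power of the focal-coefficient test
#'
#' Simulation cross-check for [sensitivity_mde()]: generates `reps`
#' datasets whose focal predictor and covariates are exactly mutually
#' uncorrelated in-sample with unit variance (orthogonalized Gaussian
#' designs — the setting the analytic inversion assumes; covariates have
#' zero true effect), fits OLS, and reports the fraction of two-sided
#' focal p-values below `alpha`.
#'
#' @param beta true standardized focal effect.
#' @param n sample size.
#' @param n_covariates number of covariates (default 3).
#' @param reps simulation replicates (default 2000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @return empirical power (numeric scalar).
#' @export
mde_power_sim <- function(beta, n, n_covariates = 3, reps = 2000,
                          alpha = 0.05, seed = 1) {
  set.seed(seed)
  hits <- 0L
  sd_res <- sqrt(1 - beta^2)
  for (r in seq_len(reps)) {
    X <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n * (n_covariates + 1)),
                                 n))))[, -1] * sqrt(n - 1)
    y <- beta * X[, 1] + stats::rnorm(n, 0, sd_res)
    Xd <- cbind(1, X)
    fit <- stats::lm.fit(Xd, y)
    res <- fit$residuals
    df2 <- n - ncol(Xd)
    s2 <- sum(res^2) / df2
    XtXinv <- chol2inv(chol(crossprod(Xd)))
    tstat <- fit$coefficients[2] / sqrt(s2 * XtXinv[2, 2])
    if (2 * stats::pt(-abs(tstat), df2) < alpha) hits <- hits + 1L
  }
  hits / reps
}
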