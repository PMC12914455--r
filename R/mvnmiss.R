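# Multivariate-normal machinery for incomplete data: missingness-pattern
# bookkeeping, EM estimation of (mu, Sigma), the observed-data
# log-likelihood, and Little's MCAR test. This is the engine behind the
# FIML regression estimator.

# Group rows of a numeric matrix by missingness pattern. Rows with no
# observed values are dropped (they carry no likelihood information).
.miss_patterns <- function(Y) {
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1, paste, collapse = "")
  pats <- lapply(split(seq_len(nrow(Y)), key), function(idx) {
    o <- which(obs[idx[1], ])
    Yo <- Y[idx, o, drop = FALSE]
    m <- colMeans(Yo)
    S <- crossprod(sweep(Yo, 2, m))  # scatter about the pattern mean
    list(obs = o, n = length(idx), mean = m, scatter = S, rows = idx,
         Y = Yo)
  })
  attr(pats, "n") <- nrow(Y)
  attr(pats, "p") <- ncol(Y)
  attr(pats, "dropped") <- sum(!keep)
  pats
}

# Observed-data log-likelihood of (mu, Sigma) given pattern stats.
.mvn_obs_loglik <- function(mu, Sigma, pats) {
  ll <- 0
  for (pt in pats) {
    o <- pt$obs
    So <- Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet <- 2 * sum(log(diag(ch)))
    d <- pt$mean - mu[o]
    Sinv <- chol2inv(ch)
    quad <- sum(Sinv * pt$scatter) + pt$n * drop(t(d) %*% Sinv %*% d)
    ll <- ll - 0.5 * (pt$n * (length(o) * log(2 * pi) + logdet) + quad)
  }
  ll
}

# EM for the MVN mean and covariance under arbitrary missingness (MCAR/MAR).
# Returns the ML estimates (denominator n), the final observed-data
# log-likelihood and convergence info.
.mvn_em <- function(Y, tol = 1e-8, max_iter = 2000) {
  p <- ncol(Y)
  pats <- .miss_patterns(Y)
  n <- attr(pats, "n")
  if (n < 2) stop("need at least 2 rows with observed data")
  mu <- vapply(seq_len(p), function(j) mean(Y[, j], na.rm = TRUE),
               numeric(1))
  if (any(!is.finite(mu))) stop("a variable has no observed values")
  v <- vapply(seq_len(p), function(j) stats::var(Y[, j], na.rm = TRUE),
              numeric(1))
  v[!is.finite(v) | v <= 0] <- 1
  Sigma <- diag(v, p)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (pt in pats) {
      o <- pt$obs
      m <- setdiff(seq_len(p), o)
      Yo <- pt$Y
      if (length(m) == 0) {
        T1[o] <- T1[o] + colSums(Yo)
        T2[o, o] <- T2[o, o] + crossprod(Yo)
        next
      }
      Soo_inv <- chol2inv(chol(Sigma[o, o, drop = FALSE]))
      B <- Sigma[m, o, drop = FALSE] %*% Soo_inv
      Em <- matrix(mu[m], pt$n, length(m), byrow = TRUE) +
        sweep(Yo, 2, mu[o]) %*% t(B)
      C <- Sigma[m, m, drop = FALSE] -
        B %*% Sigma[o, m, drop = FALSE]
      T1[o] <- T1[o] + colSums(Yo)
      T1[m] <- T1[m] + colSums(Em)
      T2[o, o] <- T2[o, o] + crossprod(Yo)
      T2[o, m] <- T2[o, m] + crossprod(Yo, Em)
      T2[m, o] <- T2[m, o] + crossprod(Em, Yo)
      T2[m, m] <- T2[m, m] + crossprod(Em) + pt$n * C
    }
    mu <- T1 / n
    Sigma <- T2 / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- .mvn_obs_loglik(mu, Sigma, pats)
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  dimnames(Sigma) <- list(colnames(Y), colnames(Y))
  names(mu) <- colnames(Y)
  list(mu = mu, Sigma = Sigma, loglik = ll_old, n = n,
       iterations = it, converged = converged, patterns = pats)
}

# pack/unpack (mu, vech(Sigma)) <-> parameter vector
.theta_pack <- function(mu, Sigma) {
  c(mu, Sigma[lower.tri(Sigma, diag = TRUE)])
}
.theta_unpack <- function(theta, p) {
  mu <- theta[seq_len(p)]
  S <- matrix(0, p, p)
  S[lower.tri(S, diag = TRUE)] <- theta[-seq_len(p)]
  S <- S + t(S) - diag(diag(S))
  list(mu = mu, Sigma = S)
}

# numeric Hessian (central differences) of the observed-data log-likelihood
# at theta-hat; used for observed-information standard errors
.obs_loglik_theta <- function(theta, p, pats) {
  par <- .theta_unpack(theta, p)
  .mvn_obs_loglik(par$mu, par$Sigma, pats)
}

.num_hessian <- function(f, theta, eps = 1e-4) {
  d <- length(theta)
  h <- eps * (abs(theta) + 1)
  H <- matrix(0, d, d)
  f0 <- f(theta)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- h[i]
    H[i, i] <- (f(theta + ei) - 2 * f0 + f(theta - ei)) / h[i]^2
    if (i < d) for (j in (i + 1):d) {
      ej <- numeric(d); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(theta + ei + ej) - f(theta + ei - ej) -
           f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

.num_jacobian <- function(g, theta, eps = 1e-6) {
  h <- eps * (abs(theta) + 1)
  g0 <- g(theta)
  J <- matrix(0, length(g0), length(theta))
  for (i in seq_along(theta)) {
    ei <- numeric(length(theta)); ei[i] <- h[i]
    J[, i] <- (g(theta + ei) - g(theta - ei)) / (2 * h[i])
  }
  J
}

#' Little's MCAR test
#'
#' Chi-square test of the missing-completely-at-random hypothesis:
#' compares each missingness pattern's observed means against the
#' EM-estimated grand mean and covariance,
#' \deqn{d^2 = \sum_j n_j (\bar y_j - \hat\mu_{o_j})' \hat\Sigma_{o_j
#' o_j}^{-1} (\bar y_j - \hat\mu_{o_j}),}
#' with degrees of freedom \eqn{\sum_j k_j - p} (observed-variable counts
#' over patterns minus the number of variables). Not applicable with a
#' single missingness pattern (in particular, complete data).
#'
#' @param data data.frame or matrix of numeric study variables (`NA` =
#'   missing).
#' @param vars optional column subset.
#' @return list with `statistic`, `df`, `p_value`, `n_patterns`,
#'   `applicable`.
#' @export
little_mcar_test <- function(data, vars = NULL) {
  Y <- .model_matrix_vars(data, vars)
  pats <- .miss_patterns(Y)
  if (length(pats) < 2) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                n_patterns = length(pats), applicable = FALSE))
  }
  fit <- .mvn_em(Y)
  d2 <- 0; kk <- 0
  for (pt in fit$patterns) {
    o <- pt$obs
    Sinv <- chol2inv(chol(fit$Sigma[o, o, drop = FALSE]))
    d <- pt$mean - fit$mu[o]
    d2 <- d2 + pt$n * drop(t(d) %*% Sinv %*% d)
    kk <- kk + length(o)
  }
  df <- kk - ncol(Y)
  list(statistic = d2, df = df,
       p_value = stats::pchisq(d2, df, lower.tail = FALSE),
       n_patterns = length(pats), applicable = TRUE)
}

# coerce selected columns of a data.frame to a numeric matrix
.model_matrix_vars <- function(data, vars = NULL) {
  if (is.null(vars)) {
    if (is.matrix(data)) return(data)
    num <- vapply(data, is.numeric, logical(1))
    vars <- names(data)[num]
    vars <- setdiff(vars, "dyad_id")
  }
  miss <- setdiff(vars, colnames(data))
  if (length(miss)) stop("variables not found: ", paste(miss, collapse = ", "))
  Y <- as.matrix(as.data.frame(data)[, vars, drop = FALSE])
  storage.mode(Y) <- "double"
  Y
}
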