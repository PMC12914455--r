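covars <- c("age_months", "sex", "gestational_age_weeks")

test_that("FIML equals OLS on complete data", {
  d <- simulate_cohort(cohort_sim_config(n = 150,
                                         missing_rate_range = c(0, 0),
                                         seed = 21))
  f <- fit_fiml_regression(d, "theta_change", "entropy_bits", covars)
  o <- fit_listwise(d, "theta_change", "entropy_bits", covars)
  expect_equal(f$coefficients$beta, o$coefficients$beta, tolerance = 1e-6)
  # the three sensitivity estimators also coincide without missingness
  r <- fit_robust(d, "theta_change", "entropy_bits", covars)
  m <- fit_mice(d, "theta_change", "entropy_bits", covars, m = 3, seed = 1)
  expect_equal(r$coefficients$beta, f$coefficients$beta, tolerance = 1e-6)
  expect_equal(m$coefficients$beta, f$coefficients$beta, tolerance = 1e-6)
})

test_that("FIML is consistent under MCAR and agrees with MICE", {
  cfg <- cohort_sim_config(n = 10000, beta_entropy_hrv = -0.25,
                           missing_rate_range = c(0.2, 0.2), seed = 22,
                           covariate_effects = list(
                             age_months = 0, sex = 0,
                             gestational_age_weeks = 0))
  d <- simulate_cohort(cfg)
  f <- fit_fiml_regression(d, "rmssd_ms", "entropy_bits", se = FALSE)
  expect_equal(f$coefficients$beta[1], -0.25, tolerance = 0.02)
  m <- fit_mice(d, "rmssd_ms", "entropy_bits", m = 5, seed = 2)
  expect_equal(m$coefficients$beta[1], f$coefficients$beta[1],
               tolerance = 0.03)
})

test_that("EM matches direct numerical maximization of the likelihood", {
  set.seed(23)
  n <- 60
  Y <- matrix(rnorm(3 * n), n, 3) %*%
    matrix(c(1, .4, .2, 0, 1, .3, 0, 0, 1), 3, byrow = TRUE)
  Y[sample(n, 12), 1] <- NA
  Y[sample(n, 10), 3] <- NA
  colnames(Y) <- c("a", "b", "c")
  em <- predyad:::.mvn_em(Y, tol = 1e-12)
  pats <- em$patterns
  # independent route: quasi-Newton on a Cholesky parameterization
  negll <- function(par) {
    mu <- par[1:3]
    L <- matrix(0, 3, 3)
    L[lower.tri(L, diag = TRUE)] <- par[4:9]
    diag(L) <- exp(diag(L))
    -predyad:::.mvn_obs_loglik(mu, L %*% t(L), pats)
  }
  opt <- stats::optim(c(colMeans(Y, na.rm = TRUE), 0, 0, 0, 0, 0, 0),
                      negll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(-opt$value, em$loglik, tolerance = 1e-6)
  L <- matrix(0, 3, 3)
  L[lower.tri(L, diag = TRUE)] <- opt$par[4:9]
  diag(L) <- exp(diag(L))
  expect_equal(L %*% t(L), unname(em$Sigma), tolerance = 1e-3)
  expect_equal(unname(opt$par[1:3]), unname(em$mu), tolerance = 1e-3)
})

test_that("standardized betas are invariant to affine rescaling", {
  d <- simulate_cohort(cohort_sim_config(n = 300, seed = 24))
  d2 <- d
  d2$entropy_bits <- d$entropy_bits * 100 - 7
  d2$theta_change <- d$theta_change / 0.02 + 3
  d2$age_months <- d$age_months * 12
  for (fitter in list(
    function(x) fit_fiml_regression(x, "theta_change", "entropy_bits",
                                    covars, se = FALSE, tol = 1e-12),
    function(x) fit_listwise(x, "theta_change", "entropy_bits", covars))) {
    expect_equal(fitter(d2)$coefficients$beta, fitter(d)$coefficients$beta,
                 tolerance = 1e-5)
  }
})

test_that("robust standard errors exceed classical ones under heteroskedasticity", {
  wins <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 400
    x <- rnorm(n)
    y <- 0.3 * x + rnorm(n, 0, sqrt(0.5 + 2 * x^2))  # variance grows with x
    d <- data.frame(y = y, x = x)
    fr <- fit_robust(d, "y", "x")
    fc <- fit_fiml_regression(d, "y", "x")
    if (fr$coefficients$se[1] > fc$coefficients$se[1]) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("listwise deletion guards its sample-size floor", {
  d <- simulate_cohort(cohort_sim_config(n = 104, seed = 25))
  l <- fit_listwise(d, "theta_change", "entropy_bits", covars)
  expect_lt(l$n_effective, 104)
  tiny <- d[1:5, ]
  tiny$theta_change[1:3] <- NA
  expect_error(fit_listwise(tiny, "theta_change", "entropy_bits", covars),
               "complete cases")
})

test_that("Little's MCAR test is inapplicable for complete data and powered for MAR", {
  d <- simulate_cohort(cohort_sim_config(n = 80,
                                         missing_rate_range = c(0, 0),
                                         seed = 26))
  expect_false(little_mcar_test(d, c("entropy_bits", "rmssd_ms"))$applicable)
  # missingness driven by an observed variable (MAR on observables):
  # rejections far above the nominal rate
  rej <- mean(sapply(1:25, function(s) {
    set.seed(500 + s)
    n <- 200
    x <- rnorm(n); y <- 0.3 * x + rnorm(n); z <- rnorm(n)
    y[x > 0.3] <- NA  # deterministic dependence on observed x
    little_mcar_test(data.frame(x = x, y = y, z = z))$p_value < 0.05
  }))
  expect_gt(rej, 0.5)
})

test_that("covariate screening selects by the p < alpha rule", {
  set.seed(27)
  n <- 104
  d <- data.frame(outcome = rnorm(n), pred = rnorm(n))
  d$related <- 0.5 * d$outcome + rnorm(n)  # strongly associated
  d$noise <- rnorm(n)
  d$konstant <- 1
  expect_warning(
    scr <- covariate_screen(d, c("related", "noise", "konstant"),
                            c("outcome", "pred")),
    "constant")
  expect_true("related" %in% scr$selected)
  # a candidate identical to the outcome is always selected
  d$self <- d$outcome
  scr2 <- covariate_screen(d, "self", "outcome")
  expect_true("self" %in% scr2$selected)
  # planted r = 0.3 at n = 104 is selected in most seeds
  hits <- mean(sapply(1:30, function(s) {
    set.seed(600 + s)
    dd <- data.frame(y = rnorm(104))
    dd$cand <- 0.3 * dd$y + sqrt(1 - 0.09) * rnorm(104)
    "cand" %in% covariate_screen(dd, "cand", "y")$selected
  }))
  expect_gt(hits, 0.85)
})

test_that("quadratic check flags curvature and errors on constants", {
  set.seed(28)
  n <- 1500
  d <- data.frame(x = rnorm(n))
  d$y <- 0.2 * d$x + 0.3 * (d$x - mean(d$x))^2 + rnorm(n)
  q <- quadratic_check(d, "y", "x")
  iq <- match(q$quadratic_term, q$coefficients$term)
  expect_lt(q$coefficients$p_value[iq], 0.05)
  # linear-only data: quadratic term is null
  d$y2 <- 0.3 * d$x + rnorm(n)
  q2 <- quadratic_check(d, "y2", "x")
  expect_gt(q2$coefficients$p_value[match(q2$quadratic_term,
                                          q2$coefficients$term)], 1e-4)
  d$z <- 1
  expect_error(quadratic_check(d, "y", "z"), "constant")
})

test_that("sex moderation detects a planted interaction and guards input", {
  set.seed(29)
  n <- 4000
  d <- data.frame(x = rnorm(n), sex = rbinom(n, 1, 0.5))
  d$y <- 0.2 * d$x + 0.4 * d$x * (d$sex - 0.5) + rnorm(n)
  m <- sex_moderation(d, "y", "x")
  ii <- match(m$interaction_term, m$coefficients$term)
  expect_lt(m$coefficients$p_value[ii], 0.001)
  expect_gt(m$coefficients$beta[ii], 0)
  d$sex1 <- 1
  expect_error(sex_moderation(d, "y", "x", sex_var = "sex1"),
               "both sexes")
})

test_that("minimal detectable effect is monotone in n and cross-checks", {
  m104 <- sensitivity_mde(104)
  expect_gte(m104$mde_beta, 0.25)
  expect_lt(m104$mde_beta, 0.35)
  ns <- c(50, 104, 500, 5000)
  mdes <- sapply(ns, function(n) sensitivity_mde(n)$mde_beta)
  expect_true(all(diff(mdes) < 0))
  expect_lt(mdes[4], 0.05)
  pw <- mde_power_sim(m104$mde_beta, 104, reps = 1000, seed = 30)
  expect_lt(abs(pw - 0.80), 0.04)
  expect_error(sensitivity_mde(5), "exceed")
})
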