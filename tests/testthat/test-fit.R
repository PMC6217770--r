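test_that("analytic scores match numeric gradients of the log-likelihood", {
  set.seed(5)
  y <- c(19, 25, 31, 36, 42)
  eta <- list(mu = rep(30, 5), sigma = rep(log(0.1), 5),
              nu = rep(0.8, 5), tau = rep(log(8), 5))
  ll_at <- function(eta) {
    th <- gwgchart:::.theta_from_eta(eta)
    gwgchart:::.bct_loglik_vec(y, th$mu, th$sigma, th$nu, th$tau)
  }
  for (p in c("mu", "sigma", "nu", "tau")) {
    th <- gwgchart:::.theta_from_eta(eta)
    ana <- gwgchart:::.bct_score_eta(p, y, th$mu, th$sigma, th$nu, th$tau)
    h <- 1e-6
    up <- eta; up[[p]] <- eta[[p]] + h
    dn <- eta; dn[[p]] <- eta[[p]] - h
    num <- (ll_at(up) - ll_at(dn)) / (2 * h)
    expect_lt(max(abs(ana - num)), 1e-4)
  }
  # the nu score limit at nu = 0 is continuous
  eta0 <- eta; eta0$nu <- rep(0, 5)
  eta_eps <- eta; eta_eps$nu <- rep(1e-4, 5)
  th0 <- gwgchart:::.theta_from_eta(eta0)
  the <- gwgchart:::.theta_from_eta(eta_eps)
  s0 <- gwgchart:::.bct_score_eta("nu", y, th0$mu, th0$sigma, th0$nu, th0$tau)
  se <- gwgchart:::.bct_score_eta("nu", y, the$mu, the$sigma, the$nu, the$tau)
  expect_lt(max(abs(s0 - se)), 1e-3)
})

test_that("the fitted median curve recovers the generating truth", {
  fx <- recovery_fixture()
  truth <- fx$truth
  for (w in c(20, 40)) {
    fitted_p50 <- predict_params(fx$chart, w)[["mu"]] - 20
    expect_lt(abs(fitted_p50 - truth$mu_curve(w)), 0.3)
  }
  expect_true(fx$chart$converged)
})

test_that("median recovery holds across replicate cohorts", {
  errs <- unlist(lapply(1:3, function(r) {
    fx <- fixture(paste0("rep", r),
                  chart_fixture("normal", n_women = 2000, seed = 100 + r))
    vapply(c(13, 20, 26, 33, 40), function(w)
      abs(predict_params(fx$chart, w)[["mu"]] - 20 - fx$truth$mu_curve(w)), 0)
  }))
  expect_lt(mean(errs), 0.3)
})

test_that("constant generating S/L/T curves are fitted without spurious wiggle", {
  fx <- recovery_fixture()
  tgrid <- seq(6, 42, by = 0.5)
  pf <- predict_params(fx$chart, tgrid)
  expect_lt(diff(range(pf$sigma)), 0.03)        # truth sigma = 0.06 constant
  expect_lt(diff(range(pf$nu)), 1.2)            # truth nu = 0.8 constant
  expect_lt(diff(range(log(pf$tau))), 2)        # truth tau = 12 constant
  expect_lt(abs(mean(pf$sigma) - 0.06), 0.02)
})

test_that("the fitting criterion is non-increasing across outer iterations", {
  for (fx in list(recovery_fixture(), small_fixture()))
    expect_true(all(diff(fx$chart$criterion_trace) <= 1e-6))
})

test_that("refitting identical data and spec reproduces the deviance", {
  fx <- small_fixture()
  refit <- suppressWarnings(fit_gamlss_bct(fx$shifted, model_spec()))
  expect_equal(refit$global_deviance, fx$chart$global_deviance,
               tolerance = 1e-9)
  expect_identical(refit$iterations, fx$chart$iterations)
})

test_that("on age-free data the fit approaches the constant-parameter ML oracle", {
  # y i.i.d. BCT regardless of gestational age: the four curves have
  # nothing to track, so the flexible fit's deviance must sit between the
  # 4-parameter maximum-likelihood deviance and that minus a small
  # overfitting allowance from the extra effective df
  set.seed(13)
  n <- 1500
  ga <- c(rep(0, 300), runif(n - 300, 6, 42))
  p0 <- bct_params(mu = 30, sigma = 0.1, nu = 0.8, tau = 12)
  y <- vapply(runif(n), bct_quantile, 0, p = p0)
  dat <- data.frame(ga_weeks = ga, y = y)
  chart <- suppressWarnings(fit_gamlss_bct(dat))
  oracle <- stats::optim(
    c(30, log(0.1), 0.8, log(12)),
    function(par) -2 * sum(gwgchart:::.bct_loglik_vec(
      y, rep(par[1], n), rep(exp(par[2]), n), rep(par[3], n),
      rep(exp(par[4]), n))),
    method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-10))
  expect_lte(chart$global_deviance, oracle$value + 0.1)
  slack <- 2.5 * (chart$effective_df_total - 4) + 5
  expect_gte(chart$global_deviance, oracle$value - slack)
})

test_that("fit guards reject unusable data", {
  small <- data.frame(ga_weeks = runif(100, 0, 45), y = runif(100, 18, 40))
  expect_error(fit_gamlss_bct(small), ">= 200")
  narrow <- data.frame(ga_weeks = rep(c(10, 11, 12), 100),
                       y = runif(300, 18, 40))
  expect_error(fit_gamlss_bct(narrow), "distinct gestational weeks")
  leak <- data.frame(woman_id = seq_len(300),
                     ga_weeks = c(runif(299, 0, 45), 20),
                     y = c(runif(299, 18, 40), -1))
  expect_error(fit_gamlss_bct(leak), "y > 0")
})

test_that("predicted parameters respect their domains everywhere", {
  fx <- small_fixture()
  set.seed(1)
  t <- runif(10000, 0, 45)
  pf <- predict_params(fx$chart, t)
  expect_true(all(pf$sigma > 0))
  expect_true(all(pf$tau > 0))
  expect_error(predict_params(fx$chart, 46), "\\[0, 45\\]")
  # scalar evaluation agrees with the exported grid at week 40
  g40 <- fx$grid[fx$grid$week == 40, ]
  p40 <- predict_params(fx$chart, 40)
  expect_equal(p40[["mu"]], g40$mu, tolerance = 1e-12)
})

test_that("linear baseline reproduces exact lines and consistent slopes", {
  t <- seq(1, 40, by = 1)
  exact <- data.frame(ga_weeks = t, gain = 2 + 0.35 * t)
  fit <- fit_linear_baseline(exact)
  expect_equal(fit$slope, 0.35, tolerance = 1e-12)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-10)
  set.seed(7)
  tt <- runif(1000, 0, 42)
  noisy <- data.frame(ga_weeks = tt, gain = 0.35 * tt + rnorm(1000, 0, 1))
  fit2 <- fit_linear_baseline(noisy)
  expect_lt(abs(fit2$slope - 0.35), 0.02)
  expect_error(fit_linear_baseline(data.frame(ga_weeks = rep(5, 10),
                                              gain = rnorm(10))), "degenerate")
})

test_that("BIC of the chart is the deviance plus the log-n df penalty", {
  fx <- small_fixture()
  ch <- fx$chart
  expect_equal(ch$bic,
               ch$global_deviance + log(ch$n_observations) * ch$effective_df_total)
})
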