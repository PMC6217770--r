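# GAMLSS-style fitting of the four BCT parameter curves over gestational
# age by penalized maximum likelihood with Rigby-Stasinopoulos (RS)
# backfitting: for each distributional parameter in turn, form the working
# response from the score on the link scale and solve a penalized weighted
# least-squares problem, holding the other three fixed. Weights are the
# observed information on the link scale, obtained by central differencing
# of the analytic score; per-parameter step-halving keeps the fitting
# criterion monotone.

#' Model specification for a chart fit
#'
#' Fixed links: identity for mu and nu, log for sigma and tau. The M-curve
#' is a degree-3 regression B-spline with the given internal breakpoints
#' (weeks); S/L/T are penalized cubic splines with the given effective
#' degrees of freedom.
#'
#' @param m_breakpoints internal breakpoints of the median curve, strictly
#'   increasing, inside (0, 45). Default {12, 20, 28, 34}.
#' @param m_degree B-spline degree of the median curve (default 3).
#' @param s_df,l_df,t_df effective df of the sigma/nu/tau curves
#'   (defaults 3, 2, 2; df = 2 is a straight line on the link scale).
#' @param tol convergence tolerance on the change in the fitting criterion
#'   (default 1e-3).
#' @param max_iter maximum outer backfitting cycles (default 50).
#' @return object of class \code{"gwg_model_spec"}.
#' @export
model_spec <- function(m_breakpoints = c(12, 20, 28, 34), m_degree = 3,
                       s_df = 3, l_df = 2, t_df = 2,
                       tol = 1e-3, max_iter = 50) {
  if (any(diff(m_breakpoints) <= 0)) stop("breakpoints must be strictly increasing")
  if (any(m_breakpoints <= 0 | m_breakpoints >= 45))
    stop("breakpoints must lie inside (0, 45)")
  if (min(s_df, l_df, t_df) < 1) stop("smoothing df must be >= 1")
  structure(list(m_breakpoints = m_breakpoints, m_degree = m_degree,
                 s_df = s_df, l_df = l_df, t_df = t_df,
                 links = c(mu = "identity", sigma = "log",
                           nu = "identity", tau = "log"),
                 tol = tol, max_iter = max_iter),
            class = "gwg_model_spec")
}

# ---- vectorized BCT likelihood and scores (fitting path) -------------------
# Truncation mass is carried in the log-likelihood but ignored in the
# derivatives (it is ~1e-10 at chart-scale parameters), the standard
# GAMLSS treatment.

.z_of <- function(y, mu, sigma, nu) {
  small <- abs(nu) < .BCT_NU_EPS
  z <- numeric(length(y))
  if (any(small)) z[small] <- log(y[small] / mu[small]) / sigma[small]
  if (any(!small)) {
    i <- !small
    z[i] <- ((y[i] / mu[i])^nu[i] - 1) / (nu[i] * sigma[i])
  }
  z
}

.bct_loglik_vec <- function(y, mu, sigma, nu, tau) {
  if (any(mu <= 0) || any(sigma <= 0) || any(tau <= 0)) return(rep(-Inf, length(y)))
  z <- .z_of(y, mu, sigma, nu)
  mass <- ifelse(abs(nu) < .BCT_NU_EPS, 1,
                 stats::pt(1 / (sigma * abs(nu)), df = tau))
  (nu - 1) * log(y) - nu * log(mu) - log(sigma) +
    stats::dt(z, df = tau, log = TRUE) - log(mass)
}

# scores on the link scale; param in {"mu","sigma","nu","tau"}
.bct_score_eta <- function(param, y, mu, sigma, nu, tau) {
  z <- .z_of(y, mu, sigma, nu)
  r <- (tau + 1) * z / (tau + z^2)
  switch(param,
    mu = (r / sigma + nu * (r * z - 1)) / mu,          # identity link
    sigma = r * z - 1,                                 # log link: sigma * dl/dsigma
    nu = {                                             # identity link
      L <- log(y / mu)
      small <- abs(nu) < .BCT_NU_EPS
      out <- numeric(length(y))
      if (any(small)) {
        i <- small
        out[i] <- L[i] - r[i] * L[i]^2 / (2 * sigma[i])
      }
      if (any(!small)) {
        i <- !small
        g <- 1 + nu[i] * sigma[i] * z[i]
        out[i] <- L[i] - r[i] * L[i] * g / (nu[i] * sigma[i]) + r[i] * z[i] / nu[i]
      }
      out
    },
    tau = {                                            # log link: tau * dl/dtau
      dldt <- 0.5 * (digamma((tau + 1) / 2) - digamma(tau / 2) - 1 / tau -
                       log1p(z^2 / tau) + (tau + 1) * z^2 / (tau * (tau + z^2)))
      tau * dldt
    })
}

.ETA_CLAMP <- list(mu = c(0.05, 200), sigma = log(c(1e-4, 5)),
                   nu = c(-10, 10), tau = log(c(0.2, 1e7)))

.theta_from_eta <- function(eta) {
  list(mu = eta$mu, sigma = exp(eta$sigma), nu = eta$nu, tau = exp(eta$tau))
}

# observed information on the link scale by central differencing of the
# analytic score in the perturbed parameter only
.bct_weight_eta <- function(param, y, eta) {
  h <- 1e-3 * pmax(1, abs(eta[[param]]))
  up <- eta; up[[param]] <- eta[[param]] + h
  dn <- eta; dn[[param]] <- eta[[param]] - h
  tu <- .theta_from_eta(up); td <- .theta_from_eta(dn)
  su <- .bct_score_eta(param, y, tu$mu, tu$sigma, tu$nu, tu$tau)
  sd_ <- .bct_score_eta(param, y, td$mu, td$sigma, td$nu, td$tau)
  w <- -(su - sd_) / (2 * h)
  w[!is.finite(w)] <- 1e-4
  pmin(pmax(w, 1e-4), 1e6)
}

.chart_deviance <- function(y, eta) {
  th <- .theta_from_eta(eta)
  -2 * sum(.bct_loglik_vec(y, th$mu, th$sigma, th$nu, th$tau))
}

# ---- the fitter ------------------------------------------------------------

#' Fit the four BCT parameter curves for one BMI group
#'
#' Maximizes the penalized BCT log-likelihood of the shifted gains
#' \code{y = gain + 20} over gestational age by cyclic RS backfitting
#' until the change in the fitting criterion (global deviance plus
#' roughness penalties) falls below \code{spec$tol}. Week-0 rows
#' participate like all others, which is what the nudge makes possible.
#'
#' @param data data.frame of shifted gain records for a single BMI group:
#'   columns \code{ga_weeks} and \code{y} (all > 0); typically the output
#'   of [apply_offset()] subset to one group.
#' @param spec a [model_spec()].
#' @return object of class \code{"fitted_chart"}: per-curve coefficients
#'   and knots, \code{global_deviance} (-2 log-likelihood),
#'   \code{effective_df_total}, \code{bic}, \code{n_observations},
#'   \code{nudge_seed} (from the data attribute, if present),
#'   \code{converged}, \code{iterations}, and the per-iteration
#'   \code{criterion_trace} / \code{deviance_trace}.
#' @export
fit_gamlss_bct <- function(data, spec = model_spec()) {
  stopifnot(inherits(spec, "gwg_model_spec"))
  if (!all(c("ga_weeks", "y") %in% names(data)))
    stop("data must carry columns 'ga_weeks' and 'y' (shifted gain)")
  y <- data$y; t <- data$ga_weeks
  if (any(!is.finite(y) | y <= 0)) {
    bad <- which(!is.finite(y) | y <= 0)[1]
    stop("non-positive or non-finite shifted gain at row ", bad,
         " (woman ", data$woman_id[bad], "): the +20 kg offset must leave y > 0")
  }
  n <- length(y)
  if (n < 200) stop("need >= 200 observations to fit a chart (got ", n,
                    "); pool more data or use a coarser model")
  if (length(unique(round(t))) < 20)
    stop("observations must span >= 20 distinct gestational weeks")

  designs <- list(
    mu = build_design(t, list(basis = "bspline", degree = spec$m_degree,
                              breakpoints = spec$m_breakpoints)),
    sigma = build_design(t, list(basis = "smooth", df = spec$s_df)),
    nu = build_design(t, list(basis = "smooth", df = spec$l_df)),
    tau = build_design(t, list(basis = "smooth", df = spec$t_df)))

  # warm start: mu through smoothed weekly running medians; constant
  # sigma at the robust CV of y; nu = 1; tau = 10.
  wk <- round(t)
  med <- tapply(y, wk, stats::median)
  cnt <- tapply(y, wk, length)
  Bmed <- eval_design(designs$mu, as.numeric(names(med)))
  beta <- list()
  beta$mu <- .pwls(Bmed, designs$mu$P, as.numeric(cnt), as.numeric(med), 0)$beta
  s0 <- max(stats::mad(y) / stats::median(y), 1e-3)
  k_of <- function(p) ncol(designs[[p]]$B)
  beta$sigma <- rep(log(s0), k_of("sigma"))   # B-splines: partition of unity
  beta$nu <- rep(1, k_of("nu"))
  beta$tau <- rep(log(10), k_of("tau"))

  eta_of <- function(b) list(mu = drop(designs$mu$B %*% b$mu),
                             sigma = drop(designs$sigma$B %*% b$sigma),
                             nu = drop(designs$nu$B %*% b$nu),
                             tau = drop(designs$tau$B %*% b$tau))
  clamp_eta <- function(eta) {
    for (p in names(eta)) {
      cl <- .ETA_CLAMP[[p]]
      eta[[p]] <- pmin(pmax(eta[[p]], cl[1]), cl[2])
    }
    eta
  }
  penalty_of <- function(b, lam) {
    sum(vapply(names(b), function(p)
      lam[[p]] * drop(crossprod(b[[p]], designs[[p]]$P %*% b[[p]])), 0))
  }

  lambda <- list(mu = 0, sigma = NA, nu = NA, tau = NA)
  edf <- c(mu = k_of("mu"), sigma = spec$s_df, nu = spec$l_df, tau = spec$t_df)

  eta <- clamp_eta(eta_of(beta))
  crit <- .chart_deviance(y, eta)   # penalties are 0 at the constant start
  crit_trace <- crit
  dev_trace <- .chart_deviance(y, eta)
  converged <- FALSE
  iter <- 0

  for (iter in seq_len(spec$max_iter)) {
    crit_prev <- crit
    for (p in c("mu", "sigma", "nu", "tau")) {
      eta <- clamp_eta(eta_of(beta))
      th <- .theta_from_eta(eta)
      u <- .bct_score_eta(p, y, th$mu, th$sigma, th$nu, th$tau)
      u[!is.finite(u)] <- 0
      w <- .bct_weight_eta(p, y, eta)
      e <- eta[[p]] + u / w
      D <- designs[[p]]
      # solve lambda to match the df target during the first cycles, then
      # freeze so the fitting criterion is a fixed objective
      if (p != "mu" && (iter <= 3 || is.na(lambda[[p]])))
        lambda[[p]] <- .lambda_for_df(D$B, D$P, w, D$df)
      fit <- .pwls(D$B, D$P, w, e, lambda[[p]])
      if (p != "mu") edf[p] <- fit$edf
      # step-halving on the penalized criterion
      b_old <- beta[[p]]
      step <- 1
      repeat {
        b_try <- b_old + step * (fit$beta - b_old)
        beta[[p]] <- b_try
        crit_try <- .chart_deviance(y, clamp_eta(eta_of(beta))) +
          penalty_of(beta, lambda)
        if (is.finite(crit_try) && crit_try <= crit + 1e-8) {
          crit <- crit_try
          break
        }
        step <- step / 2
        if (step < 1e-4) { beta[[p]] <- b_old; break }
      }
    }
    eta <- clamp_eta(eta_of(beta))
    crit <- .chart_deviance(y, eta) + penalty_of(beta, lambda)
    crit_trace <- c(crit_trace, crit)
    dev_trace <- c(dev_trace, .chart_deviance(y, eta))
    if (abs(crit_prev - crit) < spec$tol) { converged <- TRUE; break }
  }

  dev <- .chart_deviance(y, eta)
  edf_total <- sum(edf)
  chart <- structure(list(
    bmi_group = if (!is.null(data$bmi_group)) as.character(data$bmi_group[1]) else NA_character_,
    spec = spec,
    designs = lapply(designs, function(d) d[c("knots", "degree", "type")]),
    beta = beta,
    lambda = lambda,
    edf = edf,
    global_deviance = dev,
    effective_df_total = edf_total,
    bic = dev + log(n) * edf_total,
    n_observations = n,
    nudge_seed = attr(data, "nudge_seed"),
    converged = converged,
    iterations = iter,
    criterion_trace = crit_trace,
    deviance_trace = dev_trace), class = "fitted_chart")
  if (!converged)
    warning("backfitting did not converge in ", spec$max_iter,
            " iterations (last criterion change ",
            signif(abs(diff(utils::tail(crit_trace, 2))), 3), ")")
  chart
}

#' @export
print.fitted_chart <- function(x, ...) {
  cat("<fitted_chart> group:", x$bmi_group, "| n =", x$n_observations,
      "| deviance =", round(x$global_deviance, 2),
      "| edf =", round(x$effective_df_total, 2),
      "| BIC =", round(x$bic, 2),
      "|", if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations\n")
  invisible(x)
}

#' Evaluate the fitted parameter curves at gestational ages
#'
#' Applies the inverse links so the returned parameters always satisfy the
#' BCT domain constraints (sigma, tau > 0 by the log links).
#'
#' @param chart a [fit_gamlss_bct()] result.
#' @param t gestational age(s) in \code{[0, 45]} weeks.
#' @return for scalar \code{t}, a [bct_params()]; for vector \code{t}, a
#'   data.frame with columns \code{t, mu, sigma, nu, tau}.
#' @export
predict_params <- function(chart, t) {
  stopifnot(inherits(chart, "fitted_chart"))
  if (any(t < 0 | t > 45)) stop("gestational age must lie in [0, 45] weeks")
  ev <- function(p) {
    d <- chart$designs[[p]]
    drop(splines::splineDesign(d$knots, t, ord = d$degree + 1L) %*% chart$beta[[p]])
  }
  mu <- ev("mu"); sigma <- exp(ev("sigma")); nu <- ev("nu"); tau <- exp(ev("tau"))
  if (length(t) == 1) return(bct_params(mu, sigma, nu, tau))
  data.frame(t = t, mu = mu, sigma = sigma, nu = nu, tau = tau)
}

#' Simple linear Gaussian baseline for BIC comparison
#'
#' Ordinary least squares of gain on gestational age with a Gaussian
#' likelihood; \code{bic = n*log(RSS/n) + n*(log(2*pi)+1) + 3*log(n)}
#' (three parameters: intercept, slope, residual variance). The reference
#' model against which the non-linear chart's BIC is judged.
#'
#' @param data data.frame with columns \code{ga_weeks} and \code{gain}.
#' @return object of class \code{"linear_baseline_fit"}: intercept, slope
#'   (kg/week), residual_sd, bic, n.
#' @export
fit_linear_baseline <- function(data) {
  t <- data$ga_weeks; g <- data$gain
  n <- length(g)
  if (n < 3) stop("need >= 3 observations")
  if (length(unique(t)) < 2) stop("degenerate gestational ages: no spread to fit a slope")
  fit <- stats::lm.fit(cbind(1, t), g)
  rss <- sum(fit$residuals^2)
  bic <- n * log(rss / n) + n * (log(2 * pi) + 1) + 3 * log(n)
  structure(list(intercept = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2]),
                 residual_sd = sqrt(rss / n),
                 bic = bic, n = n),
            class = "linear_baseline_fit")
}
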