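# Model-adequacy diagnostics: worm plots, Royston-Wright Q statistics,
# centile coverage, BIC comparison against the linear baseline, and a
# subgroup-consistency screen. All are pure functions of their inputs.

# equal-count GA grouping; week-0 rows form their own bin when they exceed
# 10% of the data (they are a point mass in gestational age)
.ga_bins <- function(ga, n_bins) {
  is0 <- ga == 0
  out <- integer(length(ga))
  if (mean(is0) > 0.10 && n_bins > 1) {
    out[is0] <- 1L
    qs <- stats::quantile(ga[!is0], probs = seq(0, 1, length.out = n_bins),
                          type = 1)
    out[!is0] <- 1L + as.integer(cut(ga[!is0], breaks = unique(qs),
                                     include.lowest = TRUE))
  } else {
    qs <- stats::quantile(ga, probs = seq(0, 1, length.out = n_bins + 1),
                          type = 1)
    out <- as.integer(cut(ga, breaks = unique(qs), include.lowest = TRUE))
  }
  out
}

#' Worm-plot data (detrended QQ plots by gestational-age bin)
#'
#' Splits gestational age into \code{n_bins} equal-count bins; within each
#' bin pairs the ordered normal-equivalent residuals with standard-normal
#' order-statistic medians (Blom's approximation), reports the deviation
#' (empirical minus theoretical) and the pointwise 95% band half-width
#' \code{1.96*sqrt(p(1-p)/n)/dnorm(q)}.
#'
#' @param z_normal normal-equivalent residuals.
#' @param ga gestational ages (weeks), same length.
#' @param n_bins number of bins (>= 1; 1 gives a plain detrended QQ plot).
#' @return list of per-bin data.frames with columns \code{theoretical},
#'   \code{deviation}, \code{band}; names give the bin GA ranges.
#' @export
worm_plot_data <- function(z_normal, ga, n_bins = 8) {
  stopifnot(n_bins >= 1, length(z_normal) == length(ga))
  if (any(!is.finite(z_normal))) stop("residuals must be finite")
  bin <- if (n_bins == 1) rep(1L, length(ga)) else .ga_bins(ga, n_bins)
  out <- lapply(sort(unique(bin)), function(b) {
    z <- sort(z_normal[bin == b])
    n <- length(z)
    if (n < 20) warning("worm-plot bin with fewer than 20 points (n = ", n, ")")
    i <- seq_len(n)
    q <- stats::qnorm((i - 0.375) / (n + 0.25))
    p <- stats::pnorm(q)
    data.frame(theoretical = q, deviation = z - q,
               band = 1.96 * sqrt(p * (1 - p) / n) / stats::dnorm(q))
  })
  names(out) <- vapply(sort(unique(bin)), function(b)
    paste0("ga_", round(min(ga[bin == b]), 1), "_", round(max(ga[bin == b]), 1)), "")
  out
}

# D'Agostino (1970) transformation of sample skewness to a standard
# normal deviate
.skewness_u <- function(z) {
  n <- length(z)
  m2 <- mean((z - mean(z))^2); m3 <- mean((z - mean(z))^3)
  g1 <- m3 / m2^1.5
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  delta * asinh(Y / alpha)
}

# Anscombe-Glynn (1983) transformation of sample kurtosis
.kurtosis_u <- function(z) {
  n <- length(z)
  m2 <- mean((z - mean(z))^2); m4 <- mean((z - mean(z))^4)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  x <- (b2 - eb2) / sqrt(vb2)
  beta <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta * (2 / beta + sqrt(1 + 4 / beta^2))
  ((1 - 2 / (9 * A)) - ((1 - 2 / A) / (1 + x * sqrt(2 / (A - 4))))^(1/3)) /
    sqrt(2 / (9 * A))
}

#' Q statistics for residual adequacy by gestational-age group
#'
#' Royston-Wright-style chi-square screens on the first four moments of
#' the normal-equivalent residuals within equal-count gestational-age
#' groups. Per group g of size n_g the standardized departures are:
#' mean, \code{u = m_g * sqrt(n_g)}; variance, the Wilson-Hilferty
#' cube-root chi-square standardization of the sample variance; skewness
#' and kurtosis, the D'Agostino and Anscombe-Glynn normal deviates. Each
#' moment's \code{Q = sum(u^2)} is referred to a chi-square with
#' \code{n_groups} minus the df absorbed by the corresponding fitted curve
#' (mean: M, variance: S, skewness: L, kurtosis: T), floored at 1.
#'
#' @param z_normal normal-equivalent residuals.
#' @param ga gestational ages (weeks).
#' @param n_groups number of equal-count groups (>= 2; default 8).
#' @param fitted_df named vector of curve effective df to subtract
#'   (\code{c(mu=, sigma=, nu=, tau=)}); 0s when the residuals do not come
#'   from a fitted chart.
#' @return data.frame with one row per moment: statistic, df, p_value
#'   (NA when any group is smaller than 10).
#' @export
q_statistics <- function(z_normal, ga, n_groups = 8,
                         fitted_df = c(mu = 0, sigma = 0, nu = 0, tau = 0)) {
  stopifnot(n_groups >= 2, length(z_normal) == length(ga))
  bin <- .ga_bins(ga, n_groups)
  groups <- split(z_normal, bin)
  G <- length(groups)
  ng <- lengths(groups)
  u <- sapply(groups, function(z) {
    n <- length(z)
    c(mean = mean(z) * sqrt(n),
      variance = {
        v <- stats::var(z)
        f <- 2 / (9 * (n - 1))
        (v^(1/3) - (1 - f)) / sqrt(f)
      },
      skewness = .skewness_u(z),
      kurtosis = .kurtosis_u(z))
  })
  absorbed <- c(mean = unname(fitted_df["mu"]), variance = unname(fitted_df["sigma"]),
                skewness = unname(fitted_df["nu"]), kurtosis = unname(fitted_df["tau"]))
  absorbed[is.na(absorbed)] <- 0
  out <- data.frame(moment = rownames(u),
                    statistic = rowSums(u^2),
                    df = pmax(G - absorbed[rownames(u)], 1))
  out$p_value <- stats::pchisq(out$statistic, out$df, lower.tail = FALSE)
  if (any(ng < 10)) {
    warning("group(s) with fewer than 10 residuals: p-values withheld")
    out$p_value <- NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Empirical centile coverage
#'
#' For each nominal percentile label, the fraction of observations whose
#' gain lies below the centile value at their (interpolated) gestational
#' age. Near the nominal fraction under a well-fitting model.
#'
#' @param data shifted gain records (columns \code{ga_weeks}, \code{gain}).
#' @param grid the group's \code{parameter_grid}.
#' @param percentiles labels to check (default the chart's five).
#' @return data.frame: percentile, nominal, coverage.
#' @export
centile_coverage <- function(data, grid, percentiles = c(2.3, 16, 50, 84, 97.7)) {
  lab <- .sd_labels()
  ga <- pmin(data$ga_weeks, max(grid$week))  # grid covers the chart domain
  params <- lapply(ga, function(g) .interp_params(grid, g))
  cov <- vapply(percentiles, function(p) {
    i <- match(p, lab$percentile)
    prob <- if (!is.na(i)) lab$prob[i] else p / 100
    cent <- vapply(params, function(pp) bct_quantile(prob, pp) - 20, 0)
    mean(data$gain < cent)
  }, 0)
  data.frame(percentile = percentiles,
             nominal = ifelse(is.na(match(percentiles, lab$percentile)),
                              percentiles / 100,
                              lab$prob[match(percentiles, lab$percentile)]),
             coverage = cov)
}

#' BIC comparison of the chart against the linear baseline
#'
#' @param chart a [fit_gamlss_bct()] result.
#' @param baseline a [fit_linear_baseline()] result on the same rows.
#' @return \code{delta_bic = baseline$bic - chart$bic}; positive favors
#'   the non-linear chart.
#' @export
compare_bic <- function(chart, baseline) {
  stopifnot(inherits(chart, "fitted_chart"),
            inherits(baseline, "linear_baseline_fit"))
  if (chart$n_observations != baseline$n)
    stop("chart and baseline were fit to different numbers of observations (",
         chart$n_observations, " vs ", baseline$n, ")")
  baseline$bic - chart$bic
}

#' Subgroup consistency of fitted medians
#'
#' For charts fit to subgroups of one BMI group (e.g. cohorts or
#' countries), computes per integer week the variance across subgroups of
#' the fitted median gain (mu(week) - 20) and reports the maximum over
#' weeks, judged against the 0.98 kg^2 measurement-error variance: spread
#' below measurement error means the subgroups share one chart.
#'
#' @param charts list of >= 2 [fit_gamlss_bct()] results.
#' @param weeks common grid (default 0:42).
#' @return list: \code{max_spread} (kg^2), \code{below_measurement_error}
#'   (logical), \code{per_week} data.frame.
#' @export
subgroup_median_spread <- function(charts, weeks = 0:42) {
  stopifnot(length(charts) >= 2)
  med <- sapply(charts, function(ch) predict_params(ch, weeks)$mu - 20)
  v <- apply(med, 1, stats::var)
  list(max_spread = max(v),
       below_measurement_error = max(v) < nudge_variance(),
       per_week = data.frame(week = weeks, spread = v))
}
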