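# Synthetic cohort generator: emulates the statistical structure the chart
# pipeline assumes (six WHO BMI groups, one weight per early/mid/late
# window, skewed non-linear gain trajectories anchored at published median
# gains, 0.70 kg dial measurement error, binary complication flags) so
# every stage is testable without cohort data.

# published all-women median gains (kg) at 20 and 40 weeks per BMI group
.anchor_medians <- data.frame(
  group = c("underweight", "normal", "overweight", "obese1", "obese2", "obese3"),
  p50_20 = c(4.20, 3.90, 3.35, 1.95, 0.93, -0.35),
  p50_40 = c(14.20, 14.49, 13.86, 11.19, 8.73, 6.27))

# BMI sampling intervals per group (underweight floored at 15, obese3
# capped at 50: the open WHO classes need simulation bounds)
.bmi_intervals <- data.frame(
  group = c("underweight", "normal", "overweight", "obese1", "obese2", "obese3"),
  lo = c(15, 18.5, 25, 30, 35, 40),
  hi = c(18.5, 25, 30, 35, 40, 50))

# cubic Hermite evaluation on one interval
.hermite <- function(x, x1, x2, y1, y2, m1, m2) {
  h <- x2 - x1
  s <- (x - x1) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y1 + h10 * h * m1 + h01 * y2 + h11 * h * m2
}

#' Default synthetic truth for one BMI group
#'
#' The generating median-gain curve is a shape-preserving cubic Hermite
#' through the anchors (0 weeks, 0 kg), (20, published P50 at 20) and
#' (40, published P50 at 40), with the derivative at week 0 set to half
#' the 0-20 secant slope (the early-pregnancy lag: gain accrues slower in
#' the first half) and a Fritsch-Carlson derivative at 20 so the curve
#' never overshoots its anchors; beyond 40 weeks it continues linearly.
#' The remaining truth parameters default to constants sigma = 0.06,
#' nu = 0.8, tau = 12 (realistic but conventional values; the recovery
#' tests assert recovery of whatever truth is configured).
#'
#' @param group a BMI group label from [bmi_groups()].
#' @param sigma,nu,tau constant truth values for the non-location
#'   parameters.
#' @return object of class \code{"synthetic_truth"}: \code{mu_curve(t)}
#'   (median gain, kg), \code{params_at(t)} (the full [bct_params()] of
#'   the shifted gain y = gain + 20), and the anchors.
#' @export
default_truth <- function(group, sigma = 0.06, nu = 0.8, tau = 12) {
  group <- match.arg(group, bmi_groups())
  a <- .anchor_medians[.anchor_medians$group == group, ]
  x <- c(0, 20, 40); yv <- c(0, a$p50_20, a$p50_40)
  s1 <- (yv[2] - yv[1]) / 20; s2 <- (yv[3] - yv[2]) / 20
  m0 <- s1 / 2
  # Fritsch-Carlson: harmonic mean of adjacent secants, 0 at a sign change
  m1 <- if (s1 * s2 <= 0) 0 else 2 / (1 / s1 + 1 / s2)
  m2 <- s2   # one-sided endpoint slope, continued linearly past 40
  mu_curve <- function(t) {
    out <- numeric(length(t))
    seg1 <- t <= 20; seg2 <- t > 20 & t <= 40; seg3 <- t > 40
    out[seg1] <- .hermite(t[seg1], 0, 20, yv[1], yv[2], m0, m1)
    out[seg2] <- .hermite(t[seg2], 20, 40, yv[2], yv[3], m1, m2)
    out[seg3] <- yv[3] + m2 * (t[seg3] - 40)
    out
  }
  stopifnot(mu_curve(0) == 0, all(mu_curve(seq(0, 45, by = 0.5)) + 20 > 0))
  structure(list(group = group, mu_curve = mu_curve,
                 sigma_curve = function(t) rep(sigma, length(t)),
                 nu_curve = function(t) rep(nu, length(t)),
                 tau_curve = function(t) rep(tau, length(t)),
                 params_at = function(t) bct_params(mu_curve(t) + 20, sigma, nu, tau),
                 anchors = data.frame(week = x, median_gain = yv)),
            class = "synthetic_truth")
}

#' Synthetic cohort configuration
#'
#' @param n_women women per BMI group.
#' @param groups BMI groups to simulate (default all six).
#' @param missingness per-window probability that the early/mid/late
#'   weight is absent (default 0.10 each).
#' @param measurement_error_sd sd of a single dial weighing, kg
#'   (default 0.70).
#' @param complication_prevalence named Bernoulli rates for the four flags.
#' @param seed RNG seed.
#' @return object of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_women = 2000, groups = bmi_groups(),
                             missingness = c(early = 0.10, mid = 0.10, late = 0.10),
                             measurement_error_sd = 0.70,
                             complication_prevalence = c(hypertensive = 0.08,
                                                         diabetic = 0.05,
                                                         preterm = 0.06,
                                                         sga_lga = 0.20),
                             seed = 2018) {
  stopifnot(n_women >= 1, all(missingness >= 0 & missingness <= 1),
            all(complication_prevalence >= 0 & complication_prevalence <= 1),
            measurement_error_sd >= 0)
  structure(list(n_women = n_women, groups = match.arg(groups, bmi_groups(), TRUE),
                 missingness = missingness,
                 measurement_error_sd = measurement_error_sd,
                 complication_prevalence = complication_prevalence,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate a synthetic pregnancy-weight cohort
#'
#' Per woman: BMI uniform within her group's interval; height Normal(1.65,
#' 0.07) m truncated to 1.40-1.95; pre-pregnancy weight = BMI * height^2.
#' One gestational age per non-missing window, uniform over 6-19.9 /
#' 20-31.9 / 32-42 weeks. The true gain at each age is the truth-model
#' quantile at one woman-level uniform shared across her windows, so each
#' cross-sectional margin is exactly the configured BCT while trajectories
#' track within woman (a correlation the cross-sectional fit deliberately
#' ignores). Observed weight adds Normal(0, 0.70^2) dial error.
#' Complication flags are independent Bernoulli draws. Fully reproducible
#' from \code{config$seed}.
#'
#' @param config a [synthetic_config()].
#' @param truths named list of [default_truth()] objects per group
#'   (defaults to the published-anchor truths).
#' @return a [cohort_table()]; attribute \code{true_gain} holds the
#'   noise-free gains alongside the observation table for truth-recovery
#'   tests.
#' @export
simulate_cohort <- function(config = synthetic_config(), truths = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(truths))
    truths <- stats::setNames(lapply(config$groups, default_truth), config$groups)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  women_l <- list(); obs_l <- list()
  for (g in config$groups) {
    n <- config$n_women
    iv <- .bmi_intervals[.bmi_intervals$group == g, ]
    bmi <- stats::runif(n, iv$lo, iv$hi)
    h <- stats::rnorm(n, 1.65, 0.07)
    while (any(bad <- h < 1.40 | h > 1.95)) h[bad] <- stats::rnorm(sum(bad), 1.65, 0.07)
    pre <- bmi * h^2
    uw <- stats::runif(n)                       # woman-level trajectory uniform
    id <- sprintf("%s_%05d", g, seq_len(n))
    fl <- lapply(config$complication_prevalence, function(p)
      stats::runif(n) < p)
    women_l[[g]] <- data.frame(woman_id = id, prepregnancy_weight = pre,
                               height_m = h,
                               hypertensive = fl$hypertensive,
                               diabetic = fl$diabetic,
                               preterm = fl$preterm,
                               sga_lga = fl$sga_lga,
                               stringsAsFactors = FALSE)
    tr <- truths[[g]]
    win <- data.frame(window = c("early", "mid", "late"),
                      lo = c(6, 20, 32), hi = c(19.9, 31.9, 42))
    rows <- list(data.frame(woman_id = id, ga_weeks = 0, weight_kg = pre,
                            true_gain = 0, stringsAsFactors = FALSE))
    for (k in seq_len(3)) {
      present <- stats::runif(n) >= config$missingness[[win$window[k]]]
      ga <- stats::runif(n, win$lo[k], win$hi[k])
      gain <- vapply(seq_len(n), function(i)
        bct_quantile(uw[i], tr$params_at(ga[i])) - 20, 0)
      err <- stats::rnorm(n, 0, config$measurement_error_sd)
      rows[[k + 1]] <- data.frame(woman_id = id[present],
                                  ga_weeks = ga[present],
                                  weight_kg = (pre + gain + err)[present],
                                  true_gain = gain[present],
                                  stringsAsFactors = FALSE)
    }
    obs_l[[g]] <- do.call(rbind, rows)
  }
  women <- do.call(rbind, women_l)
  obs <- do.call(rbind, obs_l)
  rownames(women) <- rownames(obs) <- NULL
  out <- cohort_table(women, obs[, c("woman_id", "ga_weeks", "weight_kg")],
                      provenance = paste0("synthetic (seed ", config$seed, ")"))
  attr(out, "true_gain") <- obs[, c("woman_id", "ga_weeks", "true_gain")]
  out
}

#' Simulate total gains with designed IOM adequacy proportions
#'
#' Builds a cohort of women with a single term (40-week) weight whose
#' total gains realize given insufficient/adequate/excessive proportions:
#' category counts are fixed up front and each gain is drawn from the
#' group's truth distribution at 40 weeks conditioned on its category's
#' gain range (inverse-cdf on the category's probability band). Realized
#' proportions therefore match the targets to rounding (well within 2%).
#' No measurement error is added, so classify-then-tally reproduces the
#' targets exactly.
#'
#' @param config a [synthetic_config()] (supplies n_women and seed).
#' @param targets proportions (insufficient, adequate, excessive) summing
#'   to 1.
#' @param group BMI group label.
#' @param truth optional [default_truth()] override.
#' @return a [cohort_table()] of \code{config$n_women} women, one
#'   40-week observation each.
#' @export
simulate_iom_mix <- function(config = synthetic_config(), targets,
                             group = "normal", truth = NULL) {
  stopifnot(length(targets) == 3, abs(sum(targets) - 1) < 1e-8, all(targets >= 0))
  group <- match.arg(group, bmi_groups())
  if (is.null(truth)) truth <- default_truth(group)
  n <- config$n_women
  counts <- diff(c(0, round(cumsum(targets) * n)))  # sums exactly to n
  p40 <- truth$params_at(40)
  rng <- .iom_ranges[.iom_ranges$group == group, ]
  # probability bands of the three categories under the truth at 40 weeks
  p_lo <- bct_cdf(rng$low + 20, p40)
  p_hi <- bct_cdf(rng$high + 20, p40)
  bands <- rbind(c(1e-9, p_lo), c(p_lo, p_hi), c(p_hi, 1 - 1e-9))
  if (any(counts > 0 & (bands[, 2] - bands[, 1]) < 1e-6))
    stop("infeasible targets: a requested category has no support under ",
         "the truth distribution at 40 weeks")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  cat_idx <- rep(1:3, counts)
  u <- stats::runif(n, bands[cat_idx, 1], bands[cat_idx, 2])
  gain <- vapply(u, function(ui) bct_quantile(ui, p40) - 20, 0)
  bmi_iv <- .bmi_intervals[.bmi_intervals$group == group, ]
  bmi <- stats::runif(n, bmi_iv$lo, bmi_iv$hi)
  h <- stats::rnorm(n, 1.65, 0.07)
  while (any(bad <- h < 1.40 | h > 1.95)) h[bad] <- stats::rnorm(sum(bad), 1.65, 0.07)
  pre <- bmi * h^2
  id <- sprintf("iom_%s_%05d", group, seq_len(n))
  women <- data.frame(woman_id = id, prepregnancy_weight = pre, height_m = h,
                      hypertensive = FALSE, diabetic = FALSE,
                      preterm = FALSE, sga_lga = FALSE,
                      stringsAsFactors = FALSE)
  obs <- rbind(
    data.frame(woman_id = id, ga_weeks = 0, weight_kg = pre,
               stringsAsFactors = FALSE),
    data.frame(woman_id = id, ga_weeks = 40, weight_kg = pre + gain,
               stringsAsFactors = FALSE))
  out <- cohort_table(women, obs,
                      provenance = paste0("synthetic IOM mix (seed ", config$seed, ")"))
  attr(out, "category") <- factor(c("insufficient", "adequate", "excessive")[cat_idx],
                                  levels = c("insufficient", "adequate", "excessive"))
  out
}
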