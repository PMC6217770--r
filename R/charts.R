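# Chart deliverables: week-indexed parameter grids, centile curves, the
# exact-age z-score calculator, and IOM adequacy classification.

#' Export the week-indexed BCT parameter grid
#'
#' Evaluates the fitted parameter curves at integer gestational weeks
#' 0..42, the exchange format consumed by the z-score calculator and the
#' on-disk grid CSV ([write_parameter_grid()]).
#'
#' @param chart a [fit_gamlss_bct()] result.
#' @param weeks integer weeks to export (default 0:42).
#' @return a \code{parameter_grid} data.frame with columns
#'   \code{week, mu, sigma, nu, tau}; attribute \code{bmi_group}.
#' @export
export_parameter_grid <- function(chart, weeks = 0:42) {
  stopifnot(inherits(chart, "fitted_chart"))
  if (!chart$converged)
    warning("exporting a grid from a non-converged fit")
  pf <- predict_params(chart, weeks)
  grid <- data.frame(week = as.integer(weeks), mu = pf$mu, sigma = pf$sigma,
                     nu = pf$nu, tau = pf$tau)
  structure(grid, bmi_group = chart$bmi_group,
            class = c("parameter_grid", "data.frame"))
}

.grid_params_at <- function(grid, week) {
  i <- match(week, grid$week)
  bct_params(grid$mu[i], grid$sigma[i], grid$nu[i], grid$tau[i])
}

# per-parameter linear interpolation between bracketing integer weeks;
# linear extrapolation from the terminal pair beyond the grid (warned).
.interp_params <- function(grid, ga) {
  wk <- grid$week
  if (ga < min(wk) || ga > max(wk)) {
    warning("gestational age ", ga, " outside the grid (",
            min(wk), "-", max(wk), " weeks): extrapolating parameters")
    if (ga > max(wk)) idx <- c(nrow(grid) - 1L, nrow(grid)) else idx <- c(1L, 2L)
  } else {
    lo <- max(which(wk <= ga))
    idx <- if (wk[lo] == ga) c(lo, lo) else c(lo, lo + 1L)
  }
  w1 <- wk[idx[1]]; w2 <- wk[idx[2]]
  a <- if (w2 == w1) 0 else (ga - w1) / (w2 - w1)
  val <- function(col) (1 - a) * grid[[col]][idx[1]] + a * grid[[col]][idx[2]]
  bct_params(val("mu"), val("sigma"), val("nu"), val("tau"))
}

# SD label <-> percentile mapping of the chart (normal-equivalent scale)
.sd_labels <- function() {
  sd <- c(-2, -1, 0, 1, 2)
  data.frame(sd = sd, percentile = c(2.3, 16, 50, 84, 97.7),
             prob = stats::pnorm(sd))
}

#' Centile curve from a parameter grid
#'
#' Gain (kg) at a fixed percentile for every grid week:
#' \code{bct_quantile(prob, params) - 20}. The canonical chart labels 2.3,
#' 16, 50, 84, 97.7 are the normal-equivalent -2..+2 SD probabilities
#' (to full precision); any other percentile in (0, 100) uses
#' \code{percentile/100} directly.
#'
#' @param grid a \code{parameter_grid}.
#' @param percentile a single percentile in (0, 100).
#' @return data.frame with columns \code{week}, \code{gain}.
#' @export
centile_curve <- function(grid, percentile) {
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly inside (0, 100)")
  lab <- .sd_labels()
  i <- match(percentile, lab$percentile)
  prob <- if (!is.na(i)) lab$prob[i] else percentile / 100
  gain <- vapply(seq_len(nrow(grid)), function(j)
    bct_quantile(prob, .grid_params_at(grid, grid$week[j])) - 20, 0)
  data.frame(week = grid$week, gain = gain)
}

#' Full centile table (the chart's five curves)
#'
#' @param grid a \code{parameter_grid}.
#' @param percentiles labels to tabulate (default the chart's five).
#' @return data.frame week x one column per percentile (gain, kg).
#' @export
centile_table <- function(grid, percentiles = c(2.3, 16, 50, 84, 97.7)) {
  out <- data.frame(week = grid$week)
  for (p in percentiles)
    out[[paste0("p", p)]] <- centile_curve(grid, p)$gain
  structure(out, bmi_group = attr(grid, "bmi_group"))
}

#' Gestational weight gain z score at an exact gestational age
#'
#' The published calculator: BCT parameters at the exact (decimal)
#' gestational age are obtained by linear interpolation of mu, sigma, nu,
#' tau between the two bracketing integer grid weeks (linear extrapolation
#' beyond the grid, with a warning), then the shifted gain
#' \code{y = gain + 20} is scored against that distribution.
#'
#' @param gain weight gain in kg (may be negative; must exceed -20).
#' @param ga gestational age in decimal weeks, in \code{[0, 45]}.
#' @param grid the \code{parameter_grid} of the woman's BMI group.
#' @return list with \code{z_raw} (the t-scale Box-Cox z), \code{z_normal}
#'   (the normal-equivalent chart z score), and \code{percentile}
#'   (100 * cdf).
#' @export
gain_to_zscore <- function(gain, ga, grid) {
  if (ga < 0 || ga > 45) stop("gestational age must lie in [0, 45] weeks")
  if (gain + 20 <= 0)
    stop("gain must exceed -20 kg: the model operates on gain + 20 kg, ",
         "which must be positive")
  p <- .interp_params(grid, ga)
  y <- gain + 20
  zn <- normalized_residual(y, p)
  list(z_raw = bct_transform(y, p), z_normal = zn,
       percentile = 100 * stats::pnorm(zn))
}

#' Gain at a given normal-equivalent z score (calculator inverse)
#'
#' @param z_normal normal-equivalent z score.
#' @param ga gestational age in decimal weeks, in \code{[0, 45]}.
#' @param grid the group's \code{parameter_grid}.
#' @return gain in kg.
#' @export
zscore_to_gain <- function(z_normal, ga, grid) {
  if (ga < 0 || ga > 45) stop("gestational age must lie in [0, 45] weeks")
  p <- .interp_params(grid, ga)
  bct_quantile(stats::pnorm(z_normal), p) - 20
}

# 2009 IOM recommended total-gain ranges (kg); the three obesity grades
# share the obese range.
.iom_ranges <- data.frame(
  group = c("underweight", "normal", "overweight", "obese1", "obese2", "obese3"),
  low = c(12.5, 11.5, 7, 5, 5, 5),
  high = c(18, 16, 11.5, 9, 9, 9))

#' IOM adequacy classification of total gestational weight gain
#'
#' Against the 2009 Institute of Medicine recommended ranges: 12.5-18 kg
#' (underweight), 11.5-16 kg (normal weight), 7-11.5 kg (overweight) and
#' 5-9 kg (all obesity grades), treated as closed intervals.
#'
#' @param total_gain total gain in kg; vectorized.
#' @param group BMI group label(s) from [bmi_groups()]; recycled.
#' @return factor with levels insufficient, adequate, excessive.
#' @export
iom_classify <- function(total_gain, group) {
  group <- as.character(group)
  i <- match(group, .iom_ranges$group)
  if (anyNA(i)) stop("unknown BMI group: ",
                     paste(unique(group[is.na(i)]), collapse = ", "))
  lo <- .iom_ranges$low[i]; hi <- .iom_ranges$high[i]
  out <- ifelse(total_gain < lo, "insufficient",
                ifelse(total_gain > hi, "excessive", "adequate"))
  factor(out, levels = c("insufficient", "adequate", "excessive"))
}
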