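#' WHO pre-pregnancy BMI classification
#'
#' Assigns a BMI (kg/m^2) to one of the six WHO classes used for the
#' charts: underweight (< 18.5), normal weight (18.5 to < 25), overweight
#' (25 to < 30), and obesity grades 1 (30 to < 35), 2 (35 to < 40) and
#' 3 (>= 40). Boundaries are half-open \code{[lower, upper)} so that every
#' positive BMI receives exactly one label.
#'
#' @param bmi numeric vector of BMI values, all > 0.
#' @return factor with levels [bmi_groups()].
#' @examples
#' classify_bmi(c(18.4, 25.0, 40.0))
#' @export
classify_bmi <- function(bmi) {
  if (any(!is.finite(bmi) | bmi <= 0)) stop("BMI must be finite and > 0")
  cut(bmi, breaks = c(0, 18.5, 25, 30, 35, 40, Inf),
      labels = bmi_groups(), right = FALSE)
}

#' @rdname classify_bmi
#' @export
bmi_groups <- function() {
  c("underweight", "normal", "overweight", "obese1", "obese2", "obese3")
}

# gestational-age windows: target week and admissible range
.gwg_windows <- data.frame(
  window = c("early", "mid", "late"),
  target = c(13, 26, 40),
  lo = c(6, 20, 32),
  hi = c(19.9, 31.9, 45),
  stringsAsFactors = FALSE
)

#' Week-0 nudge variance
#'
#' The variance of the Gaussian draw that replaces the degenerate zero
#' gain at week 0: a gain score is a difference of two weighings, each
#' with dial measurement error of about 0.70 kg, so its error variance is
#' 0.70^2 + 0.70^2 = 0.98 kg^2.
#'
#' @param measurement_error_sd single-weighing error sd in kg (default 0.70).
#' @return the nudge variance in kg^2.
#' @export
nudge_variance <- function(measurement_error_sd = 0.70) {
  2 * measurement_error_sd^2
}

#' Select the early/mid/late window measurement for one woman
#'
#' Per the chart data-request design, at most one weight per pregnancy
#' window is retained: the observation closest to 13 weeks within
#' gestational ages 6-19.9 (early), closest to 26 within 20-31.9 (mid),
#' and closest to 40 within 32-45 (late). Week-0 rows are never window
#' candidates. Ties in distance go to the earlier observation.
#'
#' @param obs data.frame with columns \code{ga_weeks}, \code{weight_kg}
#'   for one woman.
#' @return data.frame of at most three rows with an extra \code{window}
#'   column; zero rows when no observation falls in any window.
#' @export
select_window_measurements <- function(obs) {
  obs <- obs[obs$ga_weeks > 0, , drop = FALSE]
  out <- lapply(seq_len(nrow(.gwg_windows)), function(i) {
    w <- .gwg_windows[i, ]
    cand <- obs[obs$ga_weeks >= w$lo & obs$ga_weeks <= w$hi, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    d <- abs(cand$ga_weeks - w$target)
    # min distance; among ties the earliest gestational age
    best <- which(d == min(d))
    pick <- cand[best[which.min(cand$ga_weeks[best])], , drop = FALSE]
    pick$window <- w$window
    pick
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(ga_weeks = numeric(0), weight_kg = numeric(0),
                      window = character(0))
  rownames(out) <- NULL
  out
}

#' Build the long-format gain table from a cohort
#'
#' Per included woman: one week-0 record with gain exactly 0 (pre-pregnancy
#' weight against itself) plus one record per filled pregnancy window, with
#' gain = window weight minus pre-pregnancy weight (negative gains are
#' legal). Women without height (BMI unclassifiable) are excluded and
#' counted in \code{attr(, "excluded")}.
#'
#' @param cohort a [cohort_table()].
#' @return data.frame with columns \code{woman_id}, \code{ga_weeks},
#'   \code{gain}, \code{bmi_group}, \code{is_week0}; attribute
#'   \code{excluded} holds the count of women dropped for missing height.
#' @export
build_gain_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  women <- cohort$women
  ok <- is.finite(women$height_m) & women$height_m > 0 &
    is.finite(women$prepregnancy_weight)
  excluded <- sum(!ok)
  women <- women[ok, , drop = FALSE]
  if (nrow(women) == 0) {
    out <- data.frame(woman_id = character(0), ga_weeks = numeric(0),
                      gain = numeric(0),
                      bmi_group = factor(character(0), levels = bmi_groups()),
                      is_week0 = logical(0))
    attr(out, "excluded") <- excluded
    return(out)
  }
  bmi <- women$prepregnancy_weight / women$height_m^2
  grp <- classify_bmi(bmi)
  obs_split <- split(cohort$obs[, c("ga_weeks", "weight_kg")], cohort$obs$woman_id)
  pieces <- vector("list", nrow(women))
  for (i in seq_len(nrow(women))) {
    id <- women$woman_id[i]
    pre <- women$prepregnancy_weight[i]
    wobs <- obs_split[[id]]
    win <- if (is.null(wobs)) NULL else select_window_measurements(wobs)
    ga <- c(0, if (!is.null(win)) win$ga_weeks)
    gain <- c(0, if (!is.null(win)) win$weight_kg - pre)
    pieces[[i]] <- data.frame(
      woman_id = id, ga_weeks = ga, gain = gain,
      bmi_group = grp[i], is_week0 = ga == 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Nudge the week-0 gains
#'
#' Replaces each exact-zero week-0 gain by an independent draw from
#' Normal(0, variance 0.98 kg^2), twice the squared 0.70 kg dial
#' measurement error, so the week-0 outcome is no longer degenerate and
#' the likelihood is well behaved. Non-week-0 rows are untouched.
#' Reproducible given \code{seed}.
#'
#' @param records gain table from [build_gain_table()].
#' @param seed integer RNG seed for the draw.
#' @param variance nudge variance in kg^2 (default [nudge_variance()]).
#' @return the gain table with nudged week-0 gains; attribute
#'   \code{nudge_seed} records the seed.
#' @export
apply_nudge <- function(records, seed, variance = nudge_variance()) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  w0 <- which(records$is_week0)
  if (any(records$gain[w0] != 0))
    stop("week-0 rows must have gain exactly 0 before nudging")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  records$gain[w0] <- stats::rnorm(length(w0), mean = 0, sd = sqrt(variance))
  attr(records, "nudge_seed") <- as.integer(seed)
  records
}

#' Shift gains by +20 kg for the positive-support BCT model
#'
#' The BCT distribution lives on positive values, while gain can be
#' negative; -20 kg being an extremely low weight change, the model is fit
#' on \code{y = gain + 20}. Rows with \code{y <= 0} cannot enter the model
#' and are dropped and counted (\code{attr(, "dropped_nonpositive")}).
#' Applied after the week-0 nudge.
#'
#' @param records nudged gain table.
#' @param offset shift in kg (default 20).
#' @return the table with an extra column \code{y = gain + offset},
#'   restricted to \code{y > 0}.
#' @export
apply_offset <- function(records, offset = 20) {
  records$y <- records$gain + offset
  keep <- records$y > 0
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_nonpositive") <- sum(!keep)
  attr(out, "nudge_seed") <- attr(records, "nudge_seed")
  attr(out, "offset") <- offset
  out
}

#' Restrict a cohort to uncomplicated term pregnancies
#'
#' Keeps women with all four complication flags (hypertensive disorder,
#' diabetic disorder, preterm birth, small/large for gestational age at
#' birth) known and FALSE. Unknown (NA) flags exclude a woman from this
#' subset; she stays in the full table.
#'
#' @param cohort a [cohort_table()].
#' @return the restricted [cohort_table()].
#' @export
filter_uncomplicated <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  w <- cohort$women
  flags <- w[, c("hypertensive", "diabetic", "preterm", "sga_lga")]
  keep <- rowSums(is.na(flags)) == 0 & rowSums(flags, na.rm = TRUE) == 0
  keep_ids <- w$woman_id[keep]
  cohort$women <- w[keep, , drop = FALSE]
  cohort$obs <- cohort$obs[cohort$obs$woman_id %in% keep_ids, , drop = FALSE]
  rownames(cohort$women) <- rownames(cohort$obs) <- NULL
  cohort$provenance <- paste0(cohort$provenance, " [uncomplicated subset]")
  cohort
}
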