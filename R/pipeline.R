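#' Prepare the shifted gain records for one BMI group
#'
#' Convenience chain for the standard preprocessing: build the gain table,
#' restrict to one BMI group, nudge the week-0 gains, and apply the
#' +20 kg offset. The result feeds [fit_gamlss_bct()] directly.
#'
#' @param cohort a [cohort_table()].
#' @param group BMI group label from [bmi_groups()].
#' @param seed nudge RNG seed.
#' @return shifted gain records (columns woman_id, ga_weeks, gain,
#'   bmi_group, is_week0, y) for the group.
#' @export
prepare_shifted_gains <- function(cohort, group, seed = 2018) {
  group <- match.arg(group, bmi_groups())
  gt <- build_gain_table(cohort)
  gt <- gt[gt$bmi_group == group, , drop = FALSE]
  rownames(gt) <- NULL
  apply_offset(apply_nudge(gt, seed = seed))
}
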