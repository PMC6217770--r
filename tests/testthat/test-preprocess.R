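test_that("WHO BMI classification matches the group boundaries", {
  expect_equal(as.character(classify_bmi(18.4)), "underweight")
  expect_equal(as.character(classify_bmi(25.0)), "overweight")
  expect_equal(as.character(classify_bmi(40.0)), "obese3")
  expect_equal(as.character(classify_bmi(c(18.5, 24.99, 30, 34.9, 35, 39.95))),
               c("normal", "normal", "obese1", "obese1", "obese2", "obese2"))
  expect_error(classify_bmi(0), "> 0")
  expect_error(classify_bmi(-5), "> 0")
})

test_that("BMI classification partitions the positive line with monotone boundaries", {
  bmi <- seq(10, 60, by = 0.01)
  g <- classify_bmi(bmi)
  expect_false(anyNA(g))
  # labels only ever step upward along increasing BMI
  expect_true(all(diff(as.integer(g)) >= 0))
  expect_setequal(levels(g), bmi_groups())
})

test_that("window selection takes the closest observation per window", {
  obs <- data.frame(ga_weeks = c(12, 18), weight_kg = c(62, 64))
  w <- select_window_measurements(obs)
  expect_equal(w$ga_weeks, 12)
  obs3 <- data.frame(ga_weeks = c(8, 24, 39), weight_kg = c(60, 65, 72))
  w3 <- select_window_measurements(obs3)
  expect_equal(w3$window, c("early", "mid", "late"))
  # below the early-window floor: nothing retained
  expect_equal(nrow(select_window_measurements(
    data.frame(ga_weeks = 5.9, weight_kg = 60))), 0)
  # equidistant tie goes to the earlier observation
  tie <- select_window_measurements(
    data.frame(ga_weeks = c(12, 14), weight_kg = c(61, 63)))
  expect_equal(tie$ga_weeks, 12)
  # week-0 rows are never window candidates
  w0 <- select_window_measurements(
    data.frame(ga_weeks = c(0, 10), weight_kg = c(60, 61)))
  expect_equal(w0$ga_weeks, 10)
})

make_cohort <- function(women, obs) cohort_table(women, obs, "test")

test_that("gain table carries one week-0 row per woman and signed gains", {
  women <- data.frame(woman_id = c("a", "b", "c"),
                      prepregnancy_weight = c(60, 100, 55),
                      height_m = c(1.65, 1.70, 1.60),
                      hypertensive = FALSE, diabetic = FALSE,
                      preterm = FALSE, sga_lga = FALSE)
  obs <- data.frame(
    woman_id = c("a", "a", "b", "c", "c", "c"),
    ga_weeks = c(0, 40, 38, 0, 13, 27),
    weight_kg = c(60, 74, 95, 55, 57, 61))
  gt <- build_gain_table(make_cohort(women, obs))
  expect_equal(sum(gt$is_week0), 3)          # one week-0 record per woman
  expect_true(all(gt$gain[gt$is_week0] == 0))
  expect_equal(gt$gain[gt$woman_id == "a" & gt$ga_weeks == 40], 14)
  expect_equal(gt$gain[gt$woman_id == "b" & gt$ga_weeks == 38], -5)
  expect_equal(as.character(unique(gt$bmi_group[gt$woman_id == "b"])), "obese1")
})

test_that("three women with three windows each give 12 gain records", {
  women <- data.frame(woman_id = c("w1", "w2", "w3"),
                      prepregnancy_weight = c(60, 62, 64),
                      height_m = 1.65, hypertensive = FALSE, diabetic = FALSE,
                      preterm = FALSE, sga_lga = FALSE)
  obs <- do.call(rbind, lapply(c("w1", "w2", "w3"), function(id)
    data.frame(woman_id = id, ga_weeks = c(13, 26, 40),
               weight_kg = c(62, 67, 74))))
  gt <- build_gain_table(make_cohort(women, obs))
  expect_equal(nrow(gt), 12)
})

test_that("women without height are excluded and counted", {
  women <- data.frame(woman_id = c("a", "b"), prepregnancy_weight = c(60, 62),
                      height_m = c(1.65, NA), hypertensive = FALSE,
                      diabetic = FALSE, preterm = FALSE, sga_lga = FALSE)
  obs <- data.frame(woman_id = c("a", "b"), ga_weeks = c(20, 20),
                    weight_kg = c(65, 66))
  gt <- build_gain_table(make_cohort(women, obs))
  expect_equal(attr(gt, "excluded"), 1)
  expect_false("b" %in% gt$woman_id)
})

test_that("nudge draws have the stated mean and variance and are seeded", {
  gt <- data.frame(woman_id = sprintf("w%d", 1:10000), ga_weeks = 0,
                   gain = 0, bmi_group = factor("normal", bmi_groups()),
                   is_week0 = TRUE)
  n1 <- apply_nudge(gt, seed = 1)
  expect_lt(abs(mean(n1$gain)), 0.03)
  expect_lt(abs(stats::var(n1$gain) - 0.98), 0.05)
  n2 <- apply_nudge(gt, seed = 1)
  expect_identical(n1$gain, n2$gain)
  # non-week-0 rows untouched
  mixed <- rbind(gt[1:5, ],
                 data.frame(woman_id = "x", ga_weeks = 20, gain = 4.2,
                            bmi_group = factor("normal", bmi_groups()),
                            is_week0 = FALSE))
  out <- apply_nudge(mixed, seed = 3)
  expect_equal(out$gain[out$woman_id == "x"], 4.2)
  # pre-nudged week-0 rows are rejected
  bad <- gt[1:3, ]; bad$gain <- 0.5
  expect_error(apply_nudge(bad, seed = 1), "exactly 0")
})

test_that("the nudge variance constant derives from the dial error", {
  expect_identical(nudge_variance(), 0.7^2 + 0.7^2)
  expect_equal(nudge_variance(0.5), 0.5)
})

test_that("the +20 kg offset shifts, drops non-positive y, and inverts", {
  gt <- data.frame(woman_id = c("a", "b", "c"), ga_weeks = c(20, 30, 40),
                   gain = c(-0.35, -20, 14.2),
                   bmi_group = factor("obese3", bmi_groups()),
                   is_week0 = FALSE)
  out <- apply_offset(gt)
  expect_equal(out$y, c(19.65, 34.2))
  expect_equal(attr(out, "dropped_nonpositive"), 1)
  # subtracting the offset recovers the gains (to machine precision)
  expect_equal(out$y - 20, out$gain, tolerance = 1e-13)
})

test_that("uncomplicated filter keeps only all-false flag women", {
  women <- data.frame(
    woman_id = c("ok", "pre", "unk"),
    prepregnancy_weight = 60, height_m = 1.65,
    hypertensive = c(FALSE, FALSE, NA),
    diabetic = FALSE,
    preterm = c(FALSE, TRUE, FALSE),
    sga_lga = FALSE)
  obs <- data.frame(woman_id = c("ok", "pre", "unk"), ga_weeks = 20,
                    weight_kg = 65)
  co <- make_cohort(women, obs)
  sub <- filter_uncomplicated(co)
  expect_equal(sub$women$woman_id, "ok")
  expect_equal(sub$obs$woman_id, "ok")
  # the full table is untouched
  expect_equal(nrow(co$women), 3)
})
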