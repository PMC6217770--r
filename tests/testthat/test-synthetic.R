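test_that("default truths pass through the published anchor medians", {
  tn <- default_truth("normal")
  expect_equal(tn$mu_curve(20), 3.90)
  expect_equal(tn$mu_curve(40), 14.49)
  expect_equal(tn$mu_curve(0), 0)
  to3 <- default_truth("obese3")
  expect_equal(to3$mu_curve(20), -0.35)
  expect_equal(to3$mu_curve(40), 6.27)
  tu <- default_truth("underweight")
  expect_equal(tu$mu_curve(c(20, 40)), c(4.20, 14.20))
})

test_that("truth curves satisfy their domain invariants", {
  for (g in bmi_groups()) {
    tr <- default_truth(g)
    t <- seq(0, 45, by = 0.25)
    expect_true(all(tr$mu_curve(t) + 20 > 0))
    expect_true(all(tr$sigma_curve(t) > 0))
    expect_true(all(tr$tau_curve(t) > 0))
    # early lag: first-half gain slower than second-half gain
    expect_lt(tr$mu_curve(20) - tr$mu_curve(0),
              tr$mu_curve(40) - tr$mu_curve(20))
  }
})

test_that("simulated cohorts have the designed structure", {
  cfg <- synthetic_config(n_women = 1000, groups = "normal", seed = 11,
                          missingness = c(early = 0, mid = 0, late = 0))
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$women), 1000)
  in_preg <- co$obs[co$obs$ga_weeks > 0, ]
  expect_equal(nrow(in_preg), 3000)
  expect_true(all(
    (in_preg$ga_weeks >= 6 & in_preg$ga_weeks <= 19.9) |
    (in_preg$ga_weeks >= 20 & in_preg$ga_weeks <= 31.9) |
    (in_preg$ga_weeks >= 32 & in_preg$ga_weeks <= 42)))
  bmi <- co$women$prepregnancy_weight / co$women$height_m^2
  expect_true(all(bmi >= 18.5 & bmi < 25))
  expect_true(all(co$women$height_m >= 1.40 & co$women$height_m <= 1.95))
})

test_that("the empirical median gain near term matches the truth anchor", {
  cfg <- synthetic_config(n_women = 1000, groups = "normal", seed = 11)
  co <- simulate_cohort(cfg)
  gt <- build_gain_table(co)
  term <- gt$gain[gt$ga_weeks >= 39 & gt$ga_weeks <= 41]
  expect_gt(length(term), 100)
  tr <- default_truth("normal")
  expect_lt(abs(median(term) - tr$mu_curve(40)), 0.6)
})

test_that("simulation is reproducible down to the written bytes", {
  cfg <- synthetic_config(n_women = 60, groups = "obese1", seed = 33)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(simulate_cohort(cfg), f1)
  write_cohort_csv(simulate_cohort(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  cfg2 <- synthetic_config(n_women = 60, groups = "obese1", seed = 34)
  f3 <- tempfile(fileext = ".csv")
  write_cohort_csv(simulate_cohort(cfg2), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("noise-free residuals of the true model are standard normal", {
  # one observation per woman so the trajectory uniforms are independent
  cfg <- synthetic_config(n_women = 1500, groups = "overweight", seed = 27,
                          missingness = c(early = 0, mid = 1, late = 1),
                          measurement_error_sd = 0)
  co <- simulate_cohort(cfg)
  gt <- build_gain_table(co)
  tr <- default_truth("overweight")
  inp <- gt[!gt$is_week0, ]
  z <- vapply(seq_len(nrow(inp)), function(i)
    normalized_residual(inp$gain[i] + 20, tr$params_at(inp$ga_weeks[i])), 0)
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("week-0 weight tracks the early-pregnancy weight within woman", {
  cfg <- synthetic_config(n_women = 1200, groups = "normal", seed = 12,
                          missingness = c(early = 0, mid = 0, late = 0))
  co <- simulate_cohort(cfg)
  early <- co$obs[co$obs$ga_weeks >= 6 & co$obs$ga_weeks <= 19.9, ]
  m <- match(early$woman_id, co$women$woman_id)
  expect_gt(stats::cor(co$women$prepregnancy_weight[m], early$weight_kg), 0.95)
})

test_that("IOM mixes realize their designed adequacy proportions", {
  cfg <- synthetic_config(n_women = 2000, seed = 41)
  co <- simulate_iom_mix(cfg, targets = c(0.25, 0.50, 0.25), group = "normal")
  gt <- build_gain_table(co)
  total <- gt$gain[gt$ga_weeks == 40]
  cls <- iom_classify(total, "normal")
  prop <- as.numeric(table(cls) / length(cls))
  expect_lt(max(abs(prop - c(0.25, 0.50, 0.25))), 0.02)
  # the tally reproduces the designed categories exactly
  expect_identical(as.character(cls), as.character(attr(co, "category")))
})

test_that("a degenerate target puts every woman in one category", {
  cfg <- synthetic_config(n_women = 300, seed = 42)
  co <- simulate_iom_mix(cfg, targets = c(1, 0, 0), group = "normal")
  gt <- build_gain_table(co)
  total <- gt$gain[gt$ga_weeks == 40]
  expect_true(all(total < 11.5))
})

test_that("full pipeline on generated data recovers anchor medians", {
  fx <- recovery_fixture()
  p50 <- centile_table(fx$grid)$p50
  wk <- fx$grid$week
  for (w in c(20, 40))
    expect_lt(abs(p50[wk == w] - fx$truth$mu_curve(w)), 0.3)
})
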