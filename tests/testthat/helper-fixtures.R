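# Shared fixtures, memoised so that the expensive chart fits are computed
# once per test run regardless of which test file first needs them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# simulate -> preprocess -> fit -> grid for one group; returns everything
# downstream tests need
chart_fixture <- function(group = "normal", n_women = 2000, seed = 11,
                          spec = model_spec(), truths = NULL) {
  cfg <- synthetic_config(n_women = n_women, groups = group, seed = seed)
  cohort <- simulate_cohort(cfg, truths = truths)
  shifted <- prepare_shifted_gains(cohort, group, seed = seed)
  chart <- suppressWarnings(fit_gamlss_bct(shifted, spec))
  list(cohort = cohort, shifted = shifted, chart = chart,
       grid = export_parameter_grid(chart), truth = if (is.null(truths))
         default_truth(group) else truths[[group]])
}

# the reference recovery fit: normal-weight cohort of 5000 women, seed 11
recovery_fixture <- function() {
  fixture("recovery", chart_fixture("normal", n_women = 5000, seed = 11))
}

# a smaller normal-weight fit for structural tests
small_fixture <- function() {
  fixture("small", chart_fixture("normal", n_women = 800, seed = 4))
}

# reference BCT parameter sets exercising both skew directions and a
# near-log case
bct_test_params <- function() {
  list(bct_params(mu = 34, sigma = 0.11, nu = 0.8, tau = 12),
       bct_params(mu = 25, sigma = 0.05, nu = -0.6, tau = 6),
       bct_params(mu = 20, sigma = 0.04, nu = 0, tau = 30),
       bct_params(mu = 40, sigma = 0.2, nu = 2.5, tau = 4))
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
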