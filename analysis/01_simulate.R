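#!/usr/bin/env Rscript
# Simulate the study cohort: six pre-pregnancy BMI groups, 2000 women
# each, one weight per early/mid/late pregnancy window plus the implied
# week-0 weight, trajectories anchored at the published median gains,
# 0.70 kg dial measurement error, and Bernoulli complication flags.
# Writes one cohort CSV per group under results/cohorts/.

library(gwgchart)

SEED <- 301
N_WOMEN <- 2000

dir.create("results/cohorts", recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(n_women = N_WOMEN, groups = bmi_groups(), seed = SEED)
cohort <- simulate_cohort(cfg)
cat(sprintf("simulated %d women, %d weight observations (seed %d)\n",
            nrow(cohort$women), nrow(cohort$obs), SEED))

for (g in bmi_groups()) {
  ids <- cohort$women$woman_id[startsWith(cohort$women$woman_id, g)]
  sub <- cohort
  sub$women <- cohort$women[cohort$women$woman_id %in% ids, ]
  sub$obs <- cohort$obs[cohort$obs$woman_id %in% ids, ]
  path <- file.path("results/cohorts", paste0(g, ".csv"))
  write_cohort_csv(sub, path)
  cat(sprintf("  %-12s %5d women -> %s\n", g, nrow(sub$women), path))
}

# headline sanity figure: median observed gain near term per group
gt <- build_gain_table(cohort)
term <- gt[gt$ga_weeks >= 39 & gt$ga_weeks <= 41, ]
med <- tapply(term$gain, term$bmi_group, median)
cat("\nmedian observed gain in weeks 39-41 (kg):\n")
print(round(med, 2))
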