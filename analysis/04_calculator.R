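#!/usr/bin/env Rscript
# Use the exported grids the way the published calculator is used: score
# individual (gain, gestational age) pairs as z scores and percentiles at
# exact (decimal) ages, and tabulate IOM adequacy of total gain per group.
# Writes results/zscore_examples.csv and results/iom_adequacy.csv.

library(gwgchart)

grids <- lapply(bmi_groups(), function(g)
  read_parameter_grid(file.path("results/grids", paste0(g, ".csv"))))
names(grids) <- bmi_groups()

# worked examples: a 10 kg gain at 30.5 weeks across groups
examples <- do.call(rbind, lapply(bmi_groups(), function(g) {
  z <- gain_to_zscore(10, 30.5, grids[[g]])
  data.frame(group = g, gain_kg = 10, ga_weeks = 30.5,
             z_normal = round(z$z_normal, 3),
             percentile = round(z$percentile, 1))
}))
print(examples, row.names = FALSE)
utils::write.csv(examples, "results/zscore_examples.csv", row.names = FALSE)

# IOM adequacy of simulated total gain (the 40-week median trajectory
# value scored against the recommended ranges)
iom <- do.call(rbind, lapply(bmi_groups(), function(g) {
  cohort <- read_cohort_csv(file.path("results/cohorts", paste0(g, ".csv")))
  gt <- build_gain_table(cohort)
  late <- gt[gt$ga_weeks >= 37 & gt$ga_weeks <= 42, ]
  cls <- iom_classify(late$gain, g)
  data.frame(group = g, n = length(cls),
             insufficient = round(mean(cls == "insufficient"), 3),
             adequate = round(mean(cls == "adequate"), 3),
             excessive = round(mean(cls == "excessive"), 3))
}))
print(iom, row.names = FALSE)
utils::write.csv(iom, "results/iom_adequacy.csv", row.names = FALSE)
cat("\nwrote results/zscore_examples.csv, results/iom_adequacy.csv\n")
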