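#!/usr/bin/env Rscript
# Stage 5: aggregate fitted trajectories and rate-of-change curves to
# center level, summarise by size category, and compare categories with
# Welch t-tests (Bonferroni-adjusted).
suppressPackageStartupMessages(library(declinefpca))

enc <- read_encounters("results/cohort_encounters.csv")
cohort <- build_cohort(enc)
model <- import_fpca_model("results/fpca_model")
labels <- classify_decliners(model)

fc <- fitted_curves(model)
traj <- center_functional_mean(fc$fit, model$grid, labels, cohort$primary)
rate <- center_rate_mean(fc$deriv, model$grid, labels, cohort$primary)
ptab <- patient_table(cohort, model, labels)
profiles <- center_profiles(ptab)
table1 <- summarize_table1(profiles)
write_benchmark_tables(traj, rate, ptab, table1, "results")

cmp <- do.call(rbind, lapply(
  c("baseline_age", "baseline_fev1", "fpc1_score", "early", "middle", "late",
    "peak_extent", "peak_age"),
  function(v) compare_categories(profiles[[v]], profiles$size_category, v)))
utils::write.csv(cmp, "results/category_comparisons.csv", row.names = FALSE)

message("Table-1-style summary (category means):")
for (f in unique(table1$feature)) {
  d <- table1[table1$feature == f, ]
  message(sprintf("  %-42s %s", f,
                  paste(sprintf("%8.2f", d$mean), collapse = " ")))
}
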