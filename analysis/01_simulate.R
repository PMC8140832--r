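#!/usr/bin/env Rscript
# Stage 1: simulate a registry-like cohort with known latent structure.
# Writes the encounter table and the generator ground truth under results/.
suppressPackageStartupMessages(library(declinefpca))

cfg <- generator_config(
  n_patients = 1000,
  center_size_mix = c(small = 0.34, medium = 0.33, large = 0.33),
  seed = 1
)
gen <- generate_cohort(cfg)

dir.create("results", showWarnings = FALSE)
write_encounters(gen$encounters, "results/encounters.csv")
write_truth(gen$truth, "results/truth")

message(sprintf("simulated %d patients, %d encounters across %d centers",
                cfg$n_patients, nrow(gen$encounters), nrow(gen$truth$centers)))
message("size classes: ",
        paste(capture.output(table(gen$truth$centers$size_class)), collapse = " "))
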