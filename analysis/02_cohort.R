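#!/usr/bin/env Rscript
# Stage 2: apply the inclusion filters (ages 6-21, at least 7 FEV1
# measurements) and the primary-center rule; summarise center sizes.
suppressPackageStartupMessages(library(declinefpca))

enc <- read_encounters("results/encounters.csv")
cohort <- build_cohort(enc)
print(cohort)
write_encounters(cohort$encounters, "results/cohort_encounters.csv")
write_cohort_summary(cohort, "results/cohort_centers.csv")
utils::write.csv(cohort$primary, "results/primary_centers.csv", row.names = FALSE)
message(sprintf("retained %d of %d patients after filtering",
                nrow(cohort$primary), length(unique(enc$patient_id))))
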