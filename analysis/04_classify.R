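#!/usr/bin/env Rscript
# Stage 4: classify decline phenotypes from first-component scores by the
# cohort-wide quartile rule.
suppressPackageStartupMessages(library(declinefpca))

model <- import_fpca_model("results/fpca_model")
labels <- classify_decliners(model)
write_labels(labels, "results/labels.csv")
tab <- table(labels$label)
message(sprintf("phenotypes: early %d (%.1f%%), middle %d (%.1f%%), late %d (%.1f%%)",
                tab[["early"]], 100 * tab[["early"]] / sum(tab),
                tab[["middle"]], 100 * tab[["middle"]] / sum(tab),
                tab[["late"]], 100 * tab[["late"]] / sum(tab)))
message(sprintf("score quartiles: Q1 = %.2f, Q3 = %.2f",
                labels$q1[1], labels$q3[1]))
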