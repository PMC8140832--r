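#!/usr/bin/env Rscript
# Stage 3: fit sparse FPCA to the filtered cohort and export the model
# (mean curve, eigenfunctions, eigenvalues, error variance, scores).
suppressPackageStartupMessages(library(declinefpca))

enc <- read_encounters("results/cohort_encounters.csv")
model <- fit_fpca(enc)
print(model)
export_fpca_model(model, "results/fpca_model")
message("model exported to results/fpca_model/")
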