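Package: declinefpca
Title: Center-Level Functional Data Analysis of Rapid Lung-Function Decline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sparse functional principal components analysis (FPCA) of
    irregularly sampled FEV1 percent-predicted trajectories in cystic
    fibrosis registry-style data, with quartile-based classification of
    patients into early/middle/late rapid-decline phenotypes, center-level
    functional aggregation (mean trajectory and rate-of-change curves,
    peak-decline statistics, size-category comparisons), and generation of
    a static/animated benchmarking dashboard. Includes a synthetic registry
    generator with known latent structure so the whole pipeline is testable
    without access to confidential registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    png,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
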