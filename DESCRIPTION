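Package: scfapanel
Title: Case-Control Analysis of Maternal Plasma Short-Chain Fatty Acid Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing panels of short-chain fatty acid (SCFA)
    concentrations measured in maternal plasma at two gestational timepoints
    against a child disease outcome. Provides a seeded synthetic cohort
    generator with log-normal concentrations, limit-of-quantitation (LOQ)
    censoring and configurable group effects; quality-control filtering,
    analyte prevalence filtering and half-LOQ imputation; per-sample
    composition metrics (total concentration, Shannon index, centered
    log-ratio transform); covariate-adjusted linear association models; and a
    subject-level permutation test for the difference-in-differences of
    pairwise Pearson correlations between the two timepoints.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
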