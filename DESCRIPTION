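Package: cernascreen
Title: Screening Competing Endogenous RNA Axes in Occult Nodal Metastasis Cohorts
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering lncRNA/miRNA/mRNA competing
    endogenous RNA (ceRNA) axes associated with occult lymph node metastasis in
    clinically node-negative tumour cohorts. Provides differential-expression
    screening with median-of-ratios normalisation, lncRNA-PCG Pearson
    correlation networks, hypergeometric gene-set over-representation,
    TargetScan-style miRNA seed-site prediction with a noisy-OR interaction
    score, a multi-filter ceRNA axis screen with full audit trails, and a
    clinical association layer (exact contingency tests, Kaplan-Meier/log-rank,
    delta-delta-Ct). Ships a planted-truth synthetic cohort generator that
    emulates a paired tumour/normal design with an occult-metastasis split, so
    every stage of the screen can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
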