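Package: gxevc
Title: Genome-by-Environment Variance Components from Similarity Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the contribution of genetics (G), an environmental
    exposure (E), and their interaction (GxE) to trait variation using
    genome-wide similarity matrices and restricted maximum likelihood.
    Builds GCTA-style genomic relationship matrices, environmental
    relationship matrices from exposure principal components, and Hadamard
    interaction kernels; fits multi-kernel mixed linear models by AI-REML
    with likelihood-ratio tests; estimates genetic correlations by
    Haseman-Elston regression with jackknife standard errors; converts
    binary-trait variance proportions to the liability scale; and pools
    per-stratum estimates by inverse-variance meta-analysis. Includes a
    synthetic cohort generator emulating a biobank design (heritable
    trauma-questionnaire exposure, sibling pairs, liability-threshold
    phenotypes, geographic clusters, sex-specific interaction variance)
    so the full pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
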