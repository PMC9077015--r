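Package: pharmetab
Title: Integrative Systems Pharmacology and NMR Serum Metabonomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dual-arm pipeline for dissecting the mechanism of multi-herb
    medicines. Arm one screens herbal compounds by four ADME descriptors (oral
    bioavailability, blood-brain-barrier index, drug-likeness, half-life) with
    literature whitelists, filters predicted protein targets by rank and
    Z-score, and annotates them to pathways. Arm two takes one-dimensional
    proton NMR serum spectra through chemical-shift calibration, fixed-width
    bucketing with water-region exclusion, total-sum normalization, PCA and
    OPLS-DA with cross-validation, correlation-loading biomarker selection at
    the sample-size-dependent critical |r|, univariate ANOVA with Bonferroni
    correction, and hypergeometric pathway over-representation with
    betweenness-based topology impact. The two pathway sets are intersected
    after name canonicalization and the overlap is reverse-mapped to target
    proteins, active compounds and herbs as a typed network. A synthetic-data
    module generates compound tables, target hits, pathway libraries and
    serum-like Lorentzian spectra with planted ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
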