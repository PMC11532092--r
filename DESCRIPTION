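Package: MetGate
Title: Ratio-Gate Calling of MET Amplification Versus Chromosome 7 Polysomy
    from Targeted-Panel Copy Numbers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls MET copy-number status (focal amplification, whole
    chromosome 7 polysomy, or negative) from targeted-panel gene copy
    numbers using a conjunction of MET/denominator-gene ratio gates plus a
    MET copy-number cutoff. Re-derives such gate models from any paired
    NGS + FISH cohort by per-ratio ROC cutoff fitting (Youden's J) followed
    by exhaustive enumeration of denominator-gene subsets against FISH
    gold-standard labels, and quantifies NGS/FISH agreement with exact
    binomial confidence intervals, one-vs-rest operating characteristics
    and copy-number-stratified concordance. Also implements somatic
    variant filtering (population frequency, VAF, SIFT/PolyPhen2),
    mutation-landscape summaries and mutation/status association tests,
    together with a synthetic paired-cohort generator for testing every
    step without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: CopyNumberVariation, Classification, SomaticMutation,
    StatisticalMethod
RoxygenNote: 7.3.3
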