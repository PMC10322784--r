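Package: duplexmut
Title: Duplex-Sequencing Mutagenicity Analysis with Clonality-Aware
    Mutation Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for error-corrected duplex-sequencing
    mutagenesis studies in rodent models. Computes clonality-aware mutation
    frequencies (MF_Min and MF_Max) from filtered somatic variant calls over
    a targeted panel, fits quasibinomial dose-response models with
    Holm-Sidak-adjusted pairwise contrasts and binomial mixed models per
    target, builds pyrimidine-reference and trinucleotide (SBS96) mutation
    spectra with COSMIC signature comparison by cosine similarity, estimates
    benchmark doses by multi-model averaging with bootstrap confidence
    intervals, and provides a Monte-Carlo power and minimum-detectable-effect
    simulator for duplex-sequencing study design. Includes a synthetic-cohort
    generator emulating post-consensus variant tables with configurable
    clonal expansion and dose-dependent spectrum shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    SummarizedExperiment,
    IRanges,
    S4Vectors,
    Biostrings,
    VariantAnnotation,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
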