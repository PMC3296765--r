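Package: crossDE
Title: Replicate-Calibrated Differential Expression Between Diverged
    Species from RNA-Seq Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical framework for calling differentially expressed
    genes between diverged species from raw RNA-Seq unique-read counts.
    Differential expression is assessed with an over-dispersed two-by-one
    chi-square test against per-gene null means obtained by projecting the
    observed count pair onto a robust median-ratio normalization line.
    Per-gene non-Poisson variance is isolated from biological replicates,
    floored by a technical-replicate resolution limit, pooled across
    species with read-count weighting, and calibrated through a uniform
    over-dispersion parameter chosen so that the false-positive fraction
    in replicate self-comparisons matches the nominal p-value. Same-day
    batch pairs are tested independently and combined with Fisher's
    method, and log2 fold changes carry error-propagated confidence
    intervals. Downstream evolutionary analyses include lineage-consistent
    assignment of expression changes over a four-taxon phylogeny, linear
    regression of fold-change variance on intergenic substitution rate
    (an expression-divergence clock) with ANCOVA slope comparisons
    between gene classes, Spearman-distance hierarchical clustering of
    samples, and paralog expression contrasts after gene duplication.
    A count simulator with controlled over-dispersion and injected
    effect sizes supports validation of type-I error, power, confidence
    interval coverage, and calibration recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: RNASeq, DifferentialExpression, Normalization, Transcriptomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
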