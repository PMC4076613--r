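Package: secophen
Title: Secondary-Phenotype Association Testing in Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Secophen", "Maintainers", email = "maintainers@secophen.org",
           role = c("aut", "cre"))
Description: Association testing and effect estimation for quantitative
    secondary phenotypes collected under case-control ascertainment. Provides
    a proportional-odds cumulative-logit likelihood-ratio test of genotype
    association that conditions on disease status, a retrospective-likelihood
    maximum-likelihood estimator for follow-up effect estimation, a calibrated
    case-control ascertainment simulator, and a simulation-study harness for
    type-I-error and power experiments. Genotypes may be supplied as allele
    counts, imputed dosages, delimited matrices, or VCF GT/DS fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
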