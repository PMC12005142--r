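Package: pbscan
Title: Population Branch Statistic Selection Scans from Genotype Likelihoods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotype-likelihood based population genetics for low-coverage
    sequencing data. Computes genotype likelihoods from pileup read
    observations under an independent-error model, applies snpCleaner-style
    site filters (minimum-individuals coverage, exact excess-heterozygosity
    test, strand-bias test), estimates per-site minor allele frequencies and
    one- and two-dimensional site frequency spectra by EM, derives
    Hudson-type FST components and the population branch statistic (PBS) in
    sliding genomic windows with an outlier peak-calling rule, and infers
    admixture proportions and PCA covariance directly from genotype
    likelihoods. Includes a Balding-Nichols synthetic-data generator for a
    three-population low-coverage design with optional admixture and an
    implanted selection sweep, so every stage can be validated by
    parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
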