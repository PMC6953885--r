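Package: imputeBench
Title: Reference-Panel Genotype Imputation Benchmarking on Synthetic Admixed Haplotypes
Version: 0.3.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to benchmark genotype-imputation reference panels at desk scale.
    Includes a haplotype-mosaic simulator for admixed populations with a
    rare-variant-heavy site-frequency spectrum, a Li-Stephens haplotype-copying
    hidden Markov model imputation engine emitting genotype and haplotype dosages
    with the standard variance-ratio estimated R-squared, a post-imputation
    quality-control framework (adaptive per-MAF-bin estimated R-squared thresholds
    guaranteeing a mean quality target, true R-squared against held-out genotypes,
    heterozygote concordance, minor-allele-count stratified rescue tables,
    genome-wide extrapolation and filtering-stringency curves), and a downstream
    single-variant association stage with phenotype cleaning, inverse-variance
    weighted meta-analysis, genomic-control lambda and a linkage-disequilibrium
    aware novelty filter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
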