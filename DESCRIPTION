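Package: haploscan
Title: Indirect Detection of Chromosomal Inversions from Low-Coverage
    Genotype Likelihoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the indirect (linkage-disequilibrium based) detection of
    chromosomal inversion polymorphisms in low-coverage whole-genome sequencing
    data. Implements genotype-likelihood computation from read counts, depth
    filtering, EM minor-allele-frequency estimation and likelihood-ratio SNP
    calling, genotype-likelihood covariance PCA, two-locus haplotype-frequency
    EM for r2, LD decay and graph-based pruning, windowed LD heatmap statistics
    and haploblock calling, karyotype clustering with heterozygosity-based
    orientation and breakpoint refinement, sample-allele-frequency likelihoods
    with folded 2D-SFS EM and windowed Reynolds FST, redundancy analysis of
    hard-called genotypes against environmental predictors with permutation
    tests and loading outliers, and median-joining mitochondrial haplotype
    networks. A forward simulator with a planted inversion polymorphism
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    ape,
    igraph,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
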