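Package: deeprisk
Title: Deep Polygenic Risk Scores with a Gene-Informed Sparse Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements a biologically informed deep polygenic risk score for
    case/control cohorts: genotypes are encoded as two-dimensional
    reference/alternative allele counts, mapped to genes through a sparse
    partial-connection layer whose wiring follows a 250 kb SNP-to-gene window,
    and modelled per chromosome with a bidirectional LSTM feeding a sigmoid
    classification head trained with class-weighted cross-entropy. Ships the
    surrounding pipeline: readers for VCF, allele-count TSV, GWAS summary
    statistics and BED gene annotations; p-value thresholding with
    LD-clumping against a reference panel and the 20-candidate selection
    grid; pruning-and-thresholding and lasso baselines; odds-ratio risk
    stratification, percentile prevalence curves, AUC and stratified
    cross-validation; and a genotype/phenotype simulator with LD blocks and
    planted additive plus epistatic architectures for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
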