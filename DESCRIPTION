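Package: poolgt
Title: Pooled SNP Genotyping with Combinatorial Decoding and Likelihood-Aware Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for cost-saving SNP genotyping by combinatorial pooling
    (nonadaptive overlapping repeated block designs) followed by genotype
    imputation. Simulates pool genotyping on square transversal designs,
    decodes per-sample calls with block-level constraint propagation,
    estimates posterior genotype probabilities for ambiguous samples from
    block combinatorics (exact conditioning, marginal maximum likelihood,
    and a self-consistent EM-type estimator with heterozygote-degeneracy
    reweighting), imputes residual missingness with a genotype-likelihood
    aware diploid Li-Stephens hidden Markov model using all reference
    haplotypes as templates, and evaluates genotype reconstruction with
    concordance (half-mismatch rule) and cross-entropy metrics stratified
    by minor allele frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    Matrix,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    jsonlite,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
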