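Package: markervar
Title: Partitioning Marker and Background Genetic Variance in Replicated Inbred Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantitative-genetic analysis of replicated phenotypes
    measured on fully inbred (homozygous) accessions, such as rice diversity
    panels. Implements a multi-trait Bayesian hierarchical model that
    partitions phenotypic variance into a marker-captured component, a
    residual "background" genetic component, and measurement error, using
    eigenvector regression on a SNP relationship matrix with Student-t marker
    priors (a multivariate BayesA analog) fitted by Gibbs sampling. Also
    provides genotype filtering and relationship kernels (VanRaden,
    cross-product, Hadamard epistatic, Gaussian), posterior summaries (modes,
    highest-posterior-density intervals), a two-step mixed-model genome-wide
    association scan, kernel-based genomic prediction (GBLUP and RKHS) under
    repeated train/validation partitions summarized on the Fisher-z scale,
    and a synthetic-data generator that emulates the replicated inbred study
    design, including the rare-untagged-causal-allele regime in which
    broad-sense heritability is high while marker heritability is near zero.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    ggplot2,
    withr
Config/testthat/edition: 3
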