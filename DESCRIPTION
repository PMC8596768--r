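Package: lsdscan
Title: Genome Scans for Selection via Locus-Specific Demographic Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies loci under divergent selection as loci whose
    locus-specific effective migration rates are incompatible with a neutral
    point estimate obtained from putatively neutral loci. Provides a
    structured-coalescent simulator for discrete-deme demographic models, a
    forward Wright-Fisher simulator with migration and genotype-table
    selection for validation pseudogenomes, per-locus population-genetic
    summary statistics (with a pooled-sequencing emulation), partial least
    squares reduction of summary statistics, ABC-GLM posterior densities of
    reciprocal migration rates on a grid, highest-posterior-density outlier
    p-values, posterior asymmetry scores characterizing genetic trade-offs,
    and ROC/AUC power evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    withr,
    mixOmics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
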