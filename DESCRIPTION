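Package: farmcpu
Title: Iterative Fixed and Random Effect GWAS with Pseudo-QTN Covariates
Version: 0.1.0
Authors@R:
    person("M.", "Fielding", email = "mfielding@example.org",
           role = c("aut", "cre"))
Description: Genome-wide association studies using the FarmCPU method: an
    iterative procedure that alternates a fast single-marker fixed-effect
    scan (ordinary least squares with a partitioned design matrix and a
    compiled kernel) with bin-based selection of pseudo-QTN covariates,
    where competing pseudo-QTN configurations are scored by the restricted
    log-likelihood of a random-effects model whose kinship is built from
    the pseudo-QTN genotypes only. Includes a file-backed double-precision
    marker store that is never copied during scanning, deterministic
    parallel execution, a quantitative-trait simulator with controlled
    allele frequencies, adjacent-marker linkage disequilibrium and
    heritability, and manhattan/QQ plotting utilities with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    grDevices,
    graphics,
    jsonlite,
    optparse,
    parallel,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
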