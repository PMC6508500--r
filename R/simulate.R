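#' Simulation configuration
#'
#' Defaults follow the standard benchmarking protocol for this method:
#' per-marker coded-allele frequencies uniform on `[0.05, 0.5]` (so the
#' coded allele is the minor allele), adjacent-marker linkage
#' disequilibrium `D' = 0.75`, purely additive gene action (zero dominance
#' deviations), 3,000 QTNs with geometrically decaying effects
#' `effect_base^k` (k = 1, 2, ...), and Gaussian noise scaled to a target
#' narrow-sense heritability.
#'
#' @param n individuals.
#' @param m markers.
#' @param maf_low,maf_high allele-frequency bounds, `0 < low <= high <= 0.5`.
#' @param dprime target adjacent-marker D' in `[0, 1]`.
#' @param n_qtn number of causal markers (`<= m`).
#' @param effect_base base of the geometric effect series (default 0.9).
#' @param h2 narrow-sense heritability in `(0, 1]`.
#' @param seed integer RNG seed; genotype simulation uses `seed`, phenotype
#'   simulation uses `seed + 1` so the two draws are distinct streams.
#' @param n_chrom chromosomes; markers are split evenly across them.
#' @param spacing base pairs between adjacent markers (default 100).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n, m, maf_low = 0.05, maf_high = 0.5, dprime = 0.75,
                       n_qtn = 3000L, effect_base = 0.9, h2 = 0.3,
                       seed = 1L, n_chrom = 10L, spacing = 100) {
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("need 0 < maf_low <= maf_high <= 0.5")
  if (dprime < 0 || dprime > 1) stop("dprime must be in [0, 1]")
  if (n_qtn > m) stop("n_qtn must be <= m")
  if (h2 <= 0 || h2 > 1)
    stop("h2 must be in (0, 1]: the noise variance (1 - h2) * sigma_a2 / h2 is undefined at h2 = 0")
  n_chrom <- max(1L, min(as.integer(n_chrom), as.integer(m)))
  structure(list(n = as.integer(n), m = as.integer(m), maf_low = maf_low,
                 maf_high = maf_high, dprime = dprime,
                 n_qtn = as.integer(n_qtn), effect_base = effect_base,
                 h2 = h2, seed = as.integer(seed), n_chrom = n_chrom,
                 spacing = spacing),
            class = "sim_config")
}

#' Simulate a genotype panel with controlled allele frequency and LD
#'
#' Haplotypes are generated marker by marker as a first-order chain along
#' each chromosome. Each marker's coded-allele frequency `p` is drawn
#' uniform on `[maf_low, maf_high]`. For an adjacent pair with frequencies
#' `(p1, p2)` the chain targets `D = D' * Dmax` with
#' `Dmax = min(p1 (1 - p2), (1 - p1) p2)`, drawing the next allele from
#' the implied conditional frequencies `P(1|1) = (p1 p2 + D) / p1` and
#' `P(1|0) = (p2 (1 - p1) - D) / (1 - p1)`. Two independent haplotypes per
#' individual are summed into genotypes, so gene action is purely additive
#' (dominance deviations of zero) and raw scores are integers in
#' `{0, 1, 2}`. Everything is deterministic given `config$seed`.
#'
#' @param config [sim_config()].
#' @param keep_haplotypes also return the `2n x m` 0/1 haplotype matrix
#'   (needed to estimate D' directly from gametes).
#' @return list: `matrix` ([marker_matrix()]), `info` ([marker_info()]),
#'   `freq` (drawn allele frequencies), and `haplotypes` when requested.
#' @export
simulate_genotypes <- function(config, keep_haplotypes = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n; m <- config$m
  nh <- 2L * n
  chrom_of <- rep(seq_len(config$n_chrom), length.out = m)
  chrom_of <- sort(chrom_of)
  pos <- unlist(lapply(split(seq_len(m), chrom_of),
                       function(ix) config$spacing * seq_along(ix)),
                use.names = FALSE)
  freq <- stats::runif(m, config$maf_low, config$maf_high)
  H <- matrix(0, nh, m)
  prev <- NULL
  for (j in seq_len(m)) {
    p2 <- freq[j]
    new_chrom <- j == 1L || chrom_of[j] != chrom_of[j - 1L]
    u <- stats::runif(nh)
    if (new_chrom) {
      h <- as.numeric(u < p2)
    } else {
      p1 <- freq[j - 1L]
      dmax <- min(p1 * (1 - p2), (1 - p1) * p2)
      D <- config$dprime * dmax
      c11 <- (p1 * p2 + D) / p1
      c10 <- (p2 * (1 - p1) - D) / (1 - p1)
      h <- as.numeric(u < ifelse(prev == 1, c11, c10))
    }
    H[, j] <- h
    prev <- h
  }
  geno <- H[seq(1L, nh, by = 2L), , drop = FALSE] +
    H[seq(2L, nh, by = 2L), , drop = FALSE]
  info <- marker_info(name = sprintf("snp%d", seq_len(m)),
                      chrom = as.character(chrom_of), pos = pos)
  mm <- marker_matrix(geno, sample_ids = sprintf("ind%d", seq_len(n)),
                      marker_names = info$name)
  out <- list(matrix = mm, info = info, freq = freq)
  if (keep_haplotypes) out$haplotypes <- H
  out
}

#' Estimate adjacent-marker D' from haplotypes
#'
#' For every within-chromosome adjacent pair, computes empirical allele and
#' haplotype frequencies and returns the signed normalized disequilibrium
#' `D / Dmax`, where `Dmax` is the usual frequency-constrained bound (its
#' form depends on the sign of `D`). Pairs with a monomorphic member are
#' returned as `NA`.
#'
#' @param H `2n x m` 0/1 haplotype matrix.
#' @param info [marker_info()] for chromosome boundaries.
#' @return numeric vector, one value per within-chromosome adjacent pair.
#' @export
estimate_adjacent_dprime <- function(H, info) {
  m <- ncol(H)
  if (m < 2L) return(numeric(0))
  same_chrom <- info$chrom[-1] == info$chrom[-m]
  pairs <- which(same_chrom)
  out <- rep(NA_real_, length(pairs))
  for (k in seq_along(pairs)) {
    j <- pairs[k]
    p1 <- mean(H[, j]); p2 <- mean(H[, j + 1L])
    if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) next
    p11 <- mean(H[, j] * H[, j + 1L])
    D <- p11 - p1 * p2
    dmax <- if (D >= 0) min(p1 * (1 - p2), (1 - p1) * p2)
            else min(p1 * p2, (1 - p1) * (1 - p2))
    if (dmax > 0) out[k] <- D / dmax
  }
  out
}

#' Simulate a quantitative trait from a genotype panel
#'
#' Samples `n_qtn` markers without replacement as QTNs; the k-th sampled
#' QTN (k starting at 1) gets additive effect `effect_base^k` on the
#' genotype score. Genetic values are `g_i = sum_k effect_k * x_{i,k}`,
#' the genetic variance `sigma_a2` is the sample variance of `g`, and
#' i.i.d. Gaussian noise with variance `(1 - h2) * sigma_a2 / h2` is added
#' so the expected realized heritability is `h2`; at `h2 = 1` the noise is
#' exactly zero. Uses seed `config$seed + 1`.
#'
#' @param mat [marker_matrix()] (no missing genotypes).
#' @param config [sim_config()].
#' @return list of class `simulated_trait`: `y`, `g`, `e`, `qtn_idx`,
#'   `effects`, `sigma_a2`, `noise_var`, `h2`.
#' @export
simulate_phenotype <- function(mat, config) {
  stopifnot(inherits(mat, "marker_matrix"), inherits(config, "sim_config"))
  if (config$n_qtn > mat$m) stop("n_qtn must be <= m")
  set.seed(config$seed + 1L)
  qtn_idx <- sample.int(mat$m, config$n_qtn)
  effects <- config$effect_base^seq_len(config$n_qtn)
  g <- as.vector(mat$values[, qtn_idx, drop = FALSE] %*% effects)
  sigma_a2 <- stats::var(g)
  if (!is.finite(sigma_a2) || sigma_a2 <= 0)
    stop("genetic values are constant; cannot scale noise to a heritability")
  noise_var <- (1 - config$h2) * sigma_a2 / config$h2
  e <- if (noise_var > 0) stats::rnorm(mat$n, 0, sqrt(noise_var))
       else numeric(mat$n)
  structure(list(y = g + e, g = g, e = e, qtn_idx = qtn_idx,
                 effects = effects, sigma_a2 = sigma_a2,
                 noise_var = noise_var, h2 = config$h2,
                 seed = config$seed),
            class = "simulated_trait")
}

#' Simulate a full dataset (genotypes + trait)
#'
#' @param config [sim_config()].
#' @param keep_haplotypes see [simulate_genotypes()].
#' @return list: `matrix`, `info`, `freq`, `trait`, optional `haplotypes`.
#' @export
simulate_dataset <- function(config, keep_haplotypes = FALSE) {
  g <- simulate_genotypes(config, keep_haplotypes = keep_haplotypes)
  g$trait <- simulate_phenotype(g$matrix, config)
  g
}

#' Inject missing genotype cells
#'
#' Sets exactly `round(rate * n * m)` uniformly chosen cells to missing —
#' used to exercise imputation. Invalidates any backing store (the `path`
#' field is cleared).
#'
#' @param mat [marker_matrix()].
#' @param rate missingness rate in `[0, 1)`.
#' @param seed RNG seed.
#' @return the modified `marker_matrix`.
#' @export
inject_missing <- function(mat, rate, seed = 1L) {
  stopifnot(inherits(mat, "marker_matrix"), rate >= 0, rate < 1)
  n_cells <- round(rate * mat$n * mat$m)
  if (n_cells > 0) {
    set.seed(seed)
    cells <- sample.int(mat$n * mat$m, n_cells)
    mat$values[cells] <- NA_real_
  }
  mat$path <- NA_character_
  mat
}

#' Write a simulated dataset as TSV files
#'
#' Writes `genotypes.tsv` (markers in columns, readable back by
#' [read_genotypes()]), `map.tsv`, `phenotype.tsv` and `truth.tsv` (QTN
#' index, marker name, effect) into `outdir`.
#'
#' @param mat [marker_matrix()].
#' @param info [marker_info()].
#' @param trait `simulated_trait` from [simulate_phenotype()].
#' @param outdir output directory (created if absent).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_dataset <- function(mat, info, trait, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(outdir, "genotypes.tsv"),
             map = file.path(outdir, "map.tsv"),
             phenotype = file.path(outdir, "phenotype.tsv"),
             truth = file.path(outdir, "truth.tsv"))
  gt <- data.frame(taxa = mat$sample_ids, mat$values,
                   stringsAsFactors = FALSE, check.names = FALSE)
  colnames(gt) <- c("taxa", mat$marker_names)
  data.table::fwrite(gt, paths["genotypes"], sep = "\t", na = "NA")
  data.table::fwrite(data.frame(name = info$name, chrom = info$chrom,
                                pos = info$pos),
                     paths["map"], sep = "\t")
  data.table::fwrite(data.frame(taxa = mat$sample_ids, y = trait$y),
                     paths["phenotype"], sep = "\t", na = "NA")
  data.table::fwrite(data.frame(qtn_index = trait$qtn_idx,
                                marker = mat$marker_names[trait$qtn_idx],
                                effect = trait$effects),
                     paths["truth"], sep = "\t")
  invisible(paths)
}
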