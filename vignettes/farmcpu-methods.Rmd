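---
title: "Methods: iterative fixed/random-effect GWAS with pseudo-QTN covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative fixed/random-effect GWAS with pseudo-QTN covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(farmcpu)
```

## The model

A genome-wide association study tests, marker by marker, whether genotype
dosage predicts a quantitative trait. The core statistical difficulty is
confounding: population and family structure induce linkage between markers
and causal variants (QTNs) elsewhere in the genome, inflating false
positives, while single-marker tests leave the variance explained by other
QTNs in the residual, costing power.

The FarmCPU method addresses both by alternating two models until a set of
*pseudo-QTNs* — markers chosen to stand in for the unknown QTNs —
stabilizes:

1. **Fixed-effect scan.** For each marker $j$, ordinary least squares fits
   $$ y = \mathbf{1}\mu + C\beta_c + S\beta_s + x_j b_j + \varepsilon $$
   on the samples with observed phenotype, where $C$ is an $n \times q$
   matrix of population-structure covariates (for example principal
   components) and $S$ holds the $t$ current pseudo-QTN genotype columns.
   The test of $b_j$ uses the two-sided $t$-distribution with
   $n_\mathrm{eff} - (q + t + 2)$ degrees of freedom (equivalent to the
   1-df $F$ test).
2. **Pseudo-QTN selection.** The scan's p-values are reduced to candidate
   sets: the genome is partitioned into physical bins of width $b$ base
   pairs, the best marker per bin is kept (smallest $p$, provided
   $p \le$ an eligibility threshold), and the top $s$ candidates form one
   set per $(b, s)$ pair on a small grid.
3. **Random-effect model selection.** Each candidate set is scored by the
   restricted log-likelihood of
   $y \sim N(X\beta,\; \sigma_a^2 K + \sigma_e^2 I)$, where the kinship
   $K$ is built **only** from that set's genotype columns. The set with
   the largest REML log-likelihood wins and becomes the covariate set $S$
   for the next scan.

Iteration stops when the selected set equals the previous one (as a set),
when a period-2 cycle is detected, or at `max_iterations` (default 20,
reported distinctly as non-convergence).

### The partitioned scan

The design matrix splits into a *constant part* (intercept, covariates,
pseudo-QTNs) and a *variable part* (the current marker). The constant part
is factorized once per iteration (thin QR); by the Frisch–Waugh theorem the
marker coefficient in the full model equals the regression of the
residualized phenotype on the residualized marker, so each marker costs two
dot products and a norm — $O(n_\mathrm{eff}(q+t+2))$ — rather than a fresh
least-squares solve. The compiled kernel residualizes each marker with two
projection passes against the orthonormal basis, which keeps the results
equal to a from-scratch OLS refit to well below the tested $10^{-8}$
relative tolerance even for markers nearly collinear with the fixed part.

Missing phenotypes define the regression sample through an index mask that
is applied marker score by marker score inside the kernel; the genotype
matrix is never row-subsetted, so no second $n \times m$ array ever exists
(the test suite asserts this with allocation profiling). Missing
*genotypes* are handled once at load time by mean imputation — each missing
cell becomes the marker's non-missing mean, i.e. twice the coded-allele
frequency, which lies in $(0,1]$ under minor-allele coding — because
genotype missingness is marker-local and static, while phenotype
missingness defines the sample and belongs to the scan.

A marker is reported missing (NA) when it is constant on the masked samples
(variance below $10^{-12}$) or collinear with the fixed part (residual
squared norm below $10^{-10}$ of its original squared norm). Markers
currently serving as pseudo-QTNs are exactly collinear with the fixed part,
so they are never tested against themselves; instead their covariate
$t$-tests from the iteration's fixed design are substituted into the scan
table. The substitution is applied every iteration, not only in the final
output: without it a pseudo-QTN could never be re-selected from the scan it
conditions, and the set would oscillate by construction.

### The REML criterion

With $\delta = \sigma_e^2/\sigma_a^2$, rotating the model onto an
orthonormal basis $A$ of the orthogonal complement of
$\operatorname{span}(X)$ gives independent components
$\eta_i \sim N(0, \sigma_a^2(\lambda_i + \delta))$, where $\lambda_i$ are
the eigenvalues of $A^\top K A$. The restricted likelihood profiles
analytically over $\sigma_a^2$, leaving a smooth 1-D function of $\delta$.
Because the complement basis is constructed explicitly, the $k$ null
directions spanned by $X$ never enter, which avoids the eigenvalue
bookkeeping ambiguity of working with the projected kinship in the full
space (relevant here because a pseudo-QTN kinship built from $t$ markers
has rank at most $t \ll n$).

$\delta$ is searched on the log scale over $[10^{-5}, 10^5]$: a 41-point
deterministic grid locates the bracketing interval, then golden-section
refines it to $10^{-9}$; endpoints are checked and a boundary optimum is
returned with a warning. The grid guard was added because the REML profile
is not guaranteed unimodal; the procedure remains fully deterministic. REML
rather than ML is used because the fixed design $X$ (intercept +
structure covariates; pseudo-QTNs act only through $K$) is identical across
candidate sets, so restricted likelihoods are directly comparable.

The kinship is the VanRaden construction restricted to the pseudo-QTN
columns: centered by twice the allele frequency computed on the masked
samples (self-consistent with the regression sample) and scaled by
$2\sum_j p_j(1-p_j)$. Ties in the model selection (log-likelihoods within
$10^{-10}$) break toward fewer pseudo-QTNs, then the smaller bin size —
the more parsimonious model wins.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `max_iterations` | 20 | iterations | loop cap; non-convergence is reported |
| `bin_sizes` | keyed to $m$ | base pairs | four widths per density tier, e.g. $m \le 10^4 \to$ {500, 1000, 1500, 2000}; arbitrary $m$ snaps to the nearest tier on the log scale |
| `qtn_counts` | 10, 20, 30 | markers | candidate set sizes; brackets typical covariate loads |
| `eligibility_threshold` | 0.01 | p-value | lenient cap keeping pure-noise markers out of the covariate set in early iterations |
| `cor_filter` | 0.7 | $r^2$ | drops the later-ranked of any pseudo-QTN pair in high LD, protecting the fixed design's rank |
| `delta_range` | $[10^{-5}, 10^5]$ | ratio | REML search domain for $\sigma_e^2/\sigma_a^2$ |
| `n_workers_scan`, `n_workers_reml` | 1 | workers | forked parallelism; results are bitwise-identical to serial for any worker count |

The eligibility threshold and the candidate set sizes are not dictated by
the method's published description, which names only "the default options";
the values above are package choices, exposed as arguments and exercised in
tests. Bin-size re-optimization happens every iteration by default
(`reoptimize_bins = FALSE` freezes the first winner); the method's
description does not settle this, and re-optimizing is the more faithful
reading of a per-iteration model search.

## What the simulator emulates — and what it does not

`simulate_genotypes()` draws each marker's coded-allele frequency uniform
on $[0.05, 0.5]$ and generates haplotypes as a first-order chain along each
chromosome targeting adjacent-pair $D' = 0.75$: for frequencies
$(p_1, p_2)$ it sets $D = D' \min\{p_1(1-p_2), (1-p_1)p_2\}$ and draws the
next allele from the implied conditional frequencies. Two independent
haplotypes are summed per individual, so dominance deviations are exactly
zero. `simulate_phenotype()` samples 3,000 QTNs (configurable) without
replacement, assigns the $k$-th *sampled* QTN the additive effect $0.9^k$
(the series starts at $k = 1$, so the largest effect is 0.9; with 3,000
QTNs the tail effects underflow harmlessly to zero), sums genetic values
$g$, and adds i.i.d. Gaussian noise with variance
$(1-h^2)\,\sigma_a^2/h^2$ where $\sigma_a^2$ is the realized sample
variance of $g$ — so the expected realized heritability equals the target
$h^2$ (0.3 by default).

Marker positions are evenly spaced (100 bp, ten chromosomes by default);
with $m = 10{,}000$ this puts 5–20 markers in each default bin, which is
the regime the bin-size table is meant for. LD is controlled between
*adjacent* markers only — $D'$ between non-adjacent pairs decays
geometrically as the chain mixes, which is qualitatively reasonable but not
calibrated to any genetic map. The simulator has **no** population
structure, admixture, relatedness, allele-frequency spectrum realism, or
recombination hotspots. A green power test on these data therefore
establishes that the machinery ranks, selects and conditions correctly
under clean additive signal; it does not establish robustness to
structure-induced confounding, which is exactly the setting where the
user-supplied covariates $C$ must do the work.

## Numerical choices and degenerate inputs

- Genotype stores are double precision only; integer/byte-typed descriptors
  are rejected outright, because mean-imputed scores in $(0,1]$ would be
  silently truncated to 0, inflating homozygous-major counts. The backing
  format (raw little-endian column-major doubles + JSON sidecar) reattaches
  bitwise-identically.
- A marker with all scores missing cannot be imputed and errors with its
  name; rank deficiency of the fixed design errors with the offending
  column; sample-ID mismatches between genotypes and phenotype are strict
  errors, never silent intersections.
- Convergence is decided on set equality, order-insensitive. A period-2
  cycle (set equal to the set two iterations back) stops the loop and is
  reported as converged with reason `"cycle"`; exhausting
  `max_iterations` is reported as non-convergence with a warning.
- Parallelism is over pre-assigned contiguous marker chunks with results
  written back in chunk order, and over candidate REML fits reassembled in
  candidate order; there is no reduction-order nondeterminism, so serial
  and parallel runs are bitwise-identical (asserted in tests).
- All simulator randomness flows from the config seed (genotypes use
  `seed`, the trait uses `seed + 1` so the two stages draw from distinct
  streams but remain jointly reproducible).

## Known limitations

- No mixed-model association testing: the random-effects model is used
  only to compare pseudo-QTN configurations, never to test markers.
- Quantitative traits only; no logistic model, robust standard errors,
  dominance or epistasis terms.
- Physical base-pair bins only; no genetic-map or LD-based binning.
- No VCF/PLINK-BED input; conversion to the numeric dosage table is
  upstream of this package.
- The power/FDR utilities of the original method are intentionally out of
  scope, as are wall-clock benchmark comparisons.
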