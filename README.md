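# farmcpu

Genome-wide association studies (GWAS) with the FarmCPU method: an
iterative procedure that alternates a fast single-marker fixed-effect scan
with bin-based selection of *pseudo-QTN* covariates, scoring competing
covariate configurations by the restricted likelihood of a random-effects
model whose kinship is built from the pseudo-QTN genotypes only.

It is intended for quantitative geneticists running association scans on
large numeric dosage panels (thousands of samples, up to millions of
markers) who want the power/false-positive profile of the FarmCPU model
with deterministic, memory-disciplined execution: the genotype matrix is
held once, file-backed in double precision, and is never copied during a
scan.

## The model

For each marker $j$, ordinary least squares fits

$$ y = \mathbf{1}\mu + C\beta_c + S\beta_s + x_j b_j + \varepsilon $$

on the phenotype-complete samples, where $C$ holds optional
population-structure covariates and $S$ the current pseudo-QTN genotype
columns; $b_j$ is tested two-sided against $t_{n_\mathrm{eff}-(q+t+2)}$.
The scan's p-values are binned physically (one best marker per bin over a
grid of bin widths and set sizes), and each candidate pseudo-QTN set is
scored by the REML log-likelihood of
$y \sim N(X\beta, \sigma_a^2 K + \sigma_e^2 I)$ with $K$ the VanRaden
kinship of that set's markers. The winning set becomes $S$ for the next
scan; iteration stops when the set stops changing (at most 20 iterations
by default). The design matrix is split into a constant part, factorized
once per iteration, and a per-marker variable part, so each marker costs
$O(n_\mathrm{eff}(q+t+2))$ in a compiled kernel; serial and parallel scans
are bitwise-identical.

A matched simulator generates genotype panels with uniform $[0.05, 0.5]$
allele frequencies and adjacent-marker $D' = 0.75$, plus additive traits
with geometric QTN effects $0.9^k$ and heritability-scaled Gaussian noise,
so every component is testable without external data. See the methods
vignette (`vignettes/farmcpu-methods.Rmd`) for assumptions, parameter
choices and limitations.

## Worked example

```r
library(farmcpu)

# 300 individuals x 500 markers, 5 QTNs with effects 0.9^k, h2 = 0.7
cfg <- sim_config(n = 300, m = 500, n_qtn = 5, h2 = 0.7, seed = 42)
sim <- simulate_dataset(cfg)

res <- run_farmcpu(sim$matrix, sim$info, sim$trait$y)
print(res)
```

```
farmcpu_result: 500 markers, 3 iteration(s), converged=TRUE (stable)
  final pseudo-QTN set: 10 marker(s)
  top associations:
 marker chrom  pos    effect         se         t            p
  snp44     1 4400 0.8653950 0.04992394 17.334269 1.211462e-46
 snp149     3 4900 0.7665543 0.06086856 12.593601 2.754381e-29
 snp296     6 4600 0.7502221 0.08227665  9.118287 1.329391e-17
 snp196     4 4600 0.6874206 0.08873234  7.747125 1.602222e-13
  snp66     2 1600 0.4238647 0.08366534  5.066192 7.249425e-07
```

The five true QTNs in this simulation are markers 44, 66, 149, 196 and 296
with additive effects 0.90, 0.81, 0.73, 0.66 and 0.59 — the top five
associations are exactly these markers, with effect estimates near their
simulated values, and all five sit in the converged pseudo-QTN set.
`effect` is the marker's additive effect per dosage unit, `se`/`t`/`p` its
standard error, t-statistic and two-sided p-value; rows for markers that
served as covariates report their covariate t-tests (they are not tested
against themselves).

```r
manhattan_plot(res$results, file = "manhattan.png")  # Bonferroni 0.05/m line
qq_plot(res$results, file = "qq.png")
write_results(res, "out/")                            # results.tsv + history.tsv
```

Command line equivalents:

```sh
Rscript -e 'farmcpu::farmcpu_main()' simulate --n 300 --m 500 --n-qtn 5 --h2 0.7 --seed 42 --out sim/
Rscript -e 'farmcpu::farmcpu_main()' run --genotypes sim/genotypes.tsv \
    --map sim/map.tsv --phenotype sim/phenotype.tsv --out out/
Rscript -e 'farmcpu::farmcpu_main()' plot --results out/results.tsv --type manhattan --out manhattan.png
```

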