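# qtlmm — mixed-model QTL mapping and association in line crosses

`qtlmm` is an R package for statistical genetics built on one unifying
device: the linear mixed model

```
y = X b + Σ_k Z_k u_k + e,   u_k ~ N(0, K_k σ²_k),   e ~ N(0, I σ²_e)
```

Different genetic analyses are different choices of fixed-effect columns
in `X` and of covariance structures `K_k`:

* **Linkage (QTL) analysis in two-line crosses** — F2, F3 and backcross
  individuals analysed jointly. A forward–backward hidden Markov model
  under the Haldane map function turns marker data into posterior
  probabilities of the four ordered line-origin states at any map
  position; these become additive, dominance and parent-of-origin
  (imprinting) regression coefficients fitted as fixed effects and
  scanned along the genome by likelihood-ratio tests.
* **Polygenic (infinitesimal) effects** — a random term with the pedigree
  numerator relationship matrix `A` (tabular method; sparse inverse by
  Henderson's rules), which reduces false positives in scans.
* **Per-SNP association** — the −1/0/+1 genotype code fitted as a fixed
  effect (1-df LRT) or as a random effect whose variance component is
  tested against the ½χ²₀ + ½χ²₁ boundary null; imprinting variants use
  parent-of-origin codes resolved from trio genotypes, excluding
  undeterminable genotypes from the likelihood.
* **Structure correction** — molecular relationship matrices from SNP
  panels: raw allele-sharing `G = MM'/n` or frequency-standardized
  `G* = W D⁻¹ W'/n`, used as random-term covariances in association
  scans; arbitrary user matrices can be read from triplet files.
* **Epistasis** — products of per-locus coefficient columns
  (add×add, add×dom, …, or user-defined pairs).
* **Conditional linkage-vs-LD tests** — fit a QTL and a SNP jointly and
  test each conditional on the other, to ask whether a signal reflects
  linkage or population linkage disequilibrium.

Variance components are estimated by **EM-REML** through Henderson's
mixed-model equations; fixed-effect comparisons use ML likelihood-ratio
tests, variance-component tests use REML with the boundary mixture null.
A seed-controlled simulator (`simulate_cross()`, `simulate_snp_panel()`)
generates complete datasets — pedigree, genotypes under Haldane meiosis,
map, phenotypes, truth — in the package's file formats.

## Worked example

```r
library(qtlmm)

## an F2 intercross: 500 phenotyped individuals, markers every 5 cM,
## additive QTL a = -1 at 17 cM, polygenic h2 = 0.4
sim <- simulate_cross(sim_design(n_f2 = 500, h2 = 0.4,
                                 qtl = list(pos_cM = 17, a = -1, d = 0),
                                 seed = 42))
cr  <- sim$cross
rnd <- list(u = list(K_inv = pedigree_A_inverse(cr$ped)))

sc <- scan_qtl(y ~ sex, cr, random = rnd, effects = "add", fix_vc = TRUE)
sc
#> QTL scan profile: 51 test(s)
#> Maximum LRT 191.262 (df 1 , p 1.686e-43 ) at  1:17 cM

po  <- origin_posteriors(cr, "1", attr(sc, "argmax")$pos_cM,
                         individuals = cr$pheno$id)
co  <- qtl_coefficients(po[, , 1, drop = FALSE])[, "add", drop = FALSE]
colnames(co) <- "qtl_add"
fit <- qmm(y ~ sex, cr$pheno, random = rnd, qtl_columns = co)
fit
#> Linear mixed model fit by EM-REML (qmm)
#>   n = 500  fixed effects: 3  random terms: 1
#>   REML log-likelihood: -672.20018
#> Variance components:
#>        u residual
#>   0.2751   0.6465
#> Fixed effects:
#> (Intercept)        sexm     qtl_add
#>     10.1700      0.5254     -1.0050
```

The scan peaks exactly at the simulated QTL position (17 cM); the
additive effect (−1.005 ± 0.057) recovers the simulated −1, and the sex
effect (0.53) its simulated 0.5. The variance components estimate
ĥ² = 0.275/(0.275+0.647) ≈ 0.30 in this replicate against a simulated
0.4 — pedigree heritabilities are noisy in a single cross; the mean over
replicates is unbiased (see the acceptance script).
`conditional_test()` then asks whether a correlated SNP adds signal
beyond the QTL, and `scan_association()` runs per-SNP tests with or
without a genomic relationship term.

A command-line wrapper (`inst/cli/qtlmm`) exposes `simulate`, `kinship`,
`fit`, `scan`, `assoc` and `compare` subcommands over a sectioned
parameter file; see `?parse_parameter_file` for the grammar and
`?qtlmm_cli` for flags.

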