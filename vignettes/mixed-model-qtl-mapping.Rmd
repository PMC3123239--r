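---
title: "Mixed-model QTL mapping and association with qtlmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model QTL mapping and association with qtlmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`qtlmm` fits the general linear mixed model

$$ \mathbf{y} = \mathbf{X b} + \sum_k \mathbf{Z}_k \mathbf{u}_k +
   \mathbf{e}, \qquad
   \mathbf{u}_k \sim N(\mathbf{0}, \mathbf{K}_k \sigma^2_k), \quad
   \mathbf{e} \sim N(\mathbf{0}, \mathbf{I}\sigma^2_e), $$

where $\mathbf{y}$ holds the recorded phenotypes, $\mathbf{b}$ the fixed
effects (environmental effects, covariates and any QTL or SNP regression
coefficients), and each random term $\mathbf{u}_k$ carries its own
covariance structure $\mathbf{K}_k$. Random terms are mutually independent.
Everything the package does — linkage scans in line crosses, per-SNP
association with structure correction, imprinting and epistasis models,
conditional linkage-versus-LD comparisons — is a choice of columns for
$\mathbf{X}$ and of structures $\mathbf{K}_k$ inside this one model, which
is also why a single fitting routine (`qmm()`) serves all analyses.

The supported covariance structures are:

* the **numerator relationship matrix** $\mathbf{A}$ from a pedigree
  (`pedigree_A()`, tabular method), quantifying expected identity by
  descent given the pedigree, with founders taken unrelated and
  non-inbred. Its sparse inverse is assembled directly by Henderson's
  rules (`pedigree_A_inverse()`), which assume non-inbred parents; an
  `exact = TRUE` mode inverts the tabular matrix instead and is exact
  under inbreeding. The polygenic ("infinitesimal") term
  $\mathbf{u} \sim N(\mathbf{0},\mathbf{A}\sigma^2_u)$ absorbs background
  genetic covariance and is the main guard against spurious QTL signals.
* **molecular (genomic) relationship matrices** from a SNP panel:
  the raw allele-sharing form $\mathbf{G} = \mathbf{MM}'/n$ with genotype
  codes $-1,0,1$ for genotypes 11, 12, 22, and the standardized form
  $\mathbf{G}^* = \mathbf{W D}^{-1}\mathbf{W}'/n$ with
  $w_{ij} = m_{ij} - \mu_j$, $\mu_j = 2q_j - 1$ and
  $D_{jj} = 2q_j(1-q_j)$, $q_j$ the frequency of allele 2
  (`raw_G()`, `standardized_G()`). These are what corrects association
  scans for population structure.
* the **identity** (independent levels), or any **user-supplied matrix**
  read from a sparse triplet file (`read_user_matrix()`), e.g. an IBD
  matrix computed elsewhere.

## Line-origin probabilities in crosses

For a cross between two founder lines, the expected QTL genotype of an
individual at an arbitrary map position is driven by the probabilities of
the four *ordered* line-origin states (paternal origin, maternal origin)
$\in \{1,2\}^2$. `origin_posteriors()` computes these with a
forward–backward hidden Markov model:

* transitions between adjacent loci use the Haldane map function
  $r = (1 - e^{-2d})/2$ ($d$ in Morgans), applied independently to the
  paternal and maternal meiosis. Haldane's no-interference assumption is
  what makes the two meioses independent Markov chains; no other map
  function is offered.
* emissions come from per-line marker allele frequencies. By default the
  lines are taken as fixed for alternative alleles (allele 1 in line 1,
  allele 2 in line 2); a `line_freqs` matrix in `cross_data()` generalises
  this to partially informative markers.
* the hidden chain of an individual is the pair of meiosis indicators of
  its two parental gametes; the origin transmitted at a locus is drawn
  from the parent's marginal ordered-origin posterior for the indicated
  gamete. Because F1 gametes have degenerate origins, this is *exact* for
  F2 and backcross individuals. For F3 and later generations it
  conditions on the parents' marginal posteriors per locus and ignores
  residual within-parent linkage information — a deliberate, stated
  approximation that keeps all generations inside one recursive
  algorithm. F2, F3 and backcross data are therefore analysed jointly.
* an individual with no genotyped marker on a chromosome gets its prior
  (¼ per state in an F2), with a warning.

The posteriors convert to regression coefficients
(`qtl_coefficients()`), using the convention that the first index is the
paternal-gamete origin:
$c_\mathrm{add} = p_{11} - p_{22}$,
$c_\mathrm{dom} = p_{12} + p_{21}$,
$c_\mathrm{imp,pat} = (p_{11}+p_{12}) - (p_{21}+p_{22})$ (paternal-allele
contrast, fitted under maternal imprinting) and symmetrically
$c_\mathrm{imp,mat}$. With imprinting, dominance is not defined.
Epistasis enters as elementwise products of coefficient columns of two
loci (`epistasis_columns()`: `aa`, `ad`, `da`, `dd` or user-defined
pairs).

For association, `snp_lambda()` gives the $-1/0/+1$ additive code;
`snp_lambda_imprinted()` determines the parent-of-origin of the child's
alleles from the trio genotypes where this is logically forced and
excludes the individual otherwise, so undetermined genotypes do not
contribute to the likelihood.

## Estimation and testing

Variance components are estimated by EM-REML through Henderson's
mixed-model equations (`reml_em()`): at each iteration the MME are solved,
and $\sigma^2_k \leftarrow (\hat{\mathbf{u}}_k'\mathbf{K}_k^{-1}
\hat{\mathbf{u}}_k + \sigma^2_e\,\mathrm{tr}(\mathbf{K}_k^{-1}
\mathbf{C}^{kk}))/q_k$,
$\sigma^2_e \leftarrow (\mathbf{y}'\mathbf{y} -
\hat{\mathbf{b}}'\mathbf{X}'\mathbf{y} - \sum_k
\hat{\mathbf{u}}_k'\mathbf{Z}_k'\mathbf{y})/(N - \mathrm{rank}\,
\mathbf{X})$. The REML log-likelihood is evaluated through the same
decomposition and is non-decreasing along the iterations, which the code
asserts (warning beyond a $10^{-8}$ relative slack). Because plain EM is
only linearly convergent, each sweep is combined with a safeguarded
Aitken extrapolation of the log variance components: the jump along the
estimated geometric path is accepted only when it does not decrease the
REML log-likelihood (overshooting jumps retry with halved gains, and an
ordinary step that overshoots backtracks the same way), preserving
monotonicity while typically cutting the iteration count by an order of
magnitude; the accelerated fixed point was cross-checked against direct
numerical maximisation of the REML criterion. Near a boundary ($\sigma^2_k \to 0$) convergence remains
slow, so null components are reported as small positive numbers unless a
long iteration budget is given.

Numerical choices:

* convergence when the relative change of the REML log-likelihood falls
  below `tol` ($10^{-8}$ by default, at most 1000 iterations); variances
  are floored at $10^{-10}\times$ the phenotypic variance, which keeps
  the floor scale-equivariant;
* the MME are assembled from sparse incidence blocks; solving and the
  inverse-block traces use dense Cholesky factorisation, which is exact
  and fast up to a few thousand equations — the intended scale of this
  package. A sparse solution path (`solve_mme(..., method = "sparse")`)
  is available and agrees with the dense path to $10^{-8}$;
* a singular covariance matrix (common for $\mathbf{G}^*$) is blended
  with a small ridge ($10^{-6}$ of its mean diagonal) before inversion,
  with a message;
* rank deficiency of the fixed design is an error naming the dependent
  columns; scans instead drop QTL columns that are collinear with the
  null design and reduce the test's degrees of freedom accordingly
  (a QTL coefficient can degenerate at particular positions);
* ties in the scan argmax break toward the lowest cM position.

Hypothesis testing follows two rules. Models differing in *fixed* effects
(QTL coefficients, SNP codes) are compared with Gaussian **ML**
log-likelihoods — REML likelihoods are not comparable across different
$\mathbf{X}$ — evaluated at each model's REML variance components, or at
the null model's components when `fix_vc = TRUE`; for pure fixed-effect
models the profile ML likelihood is used, so those LRTs are the classical
ones. Tests of a *variance component* (the random-SNP mode of
`scan_association()`) compare REML likelihoods and use the boundary null
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (`pvalue_from_lrt(..,
"mixture50")`). No multiple-testing correction is applied; profile
p-values are pointwise, and genome-wide thresholds are the user's
responsibility.

`scan_qtl()` re-estimates variance components at every grid position by
default; `fix_vc = TRUE` reuses the null-model estimates, which is many
times faster and in our simulations indistinguishable in the profile
shape and argmax. The default grid is 1 cM, always including marker
positions, clamped to the marker span. `conditional_test()` fits both
terms jointly and reports each term's LRT conditional on the other — the
device used to ask whether a signal is linkage or linkage disequilibrium:
once one locus is fitted, a second is only declared significant if it
adds signal conditional on the first.

## What the simulator emulates

`simulate_cross()` generates a two-line cross from explicit meioses:
founder lines fixed for alternative marker alleles, Haldane crossovers
(Poisson count, uniform positions, no interference — matching the HMM's
assumption), F2/F3/backcross offspring in any mix, and phenotypes
$y = \mu + \text{sex} + c_\mathrm{add} a + c_\mathrm{dom} d +
(\text{imprinting terms}) + u + e$ with $u \sim
N(0, \mathbf{A}\sigma^2_u)$ built by Mendelian sampling down the
pedigree. Heritability is defined as $\sigma^2_u / (\sigma^2_u +
\sigma^2_e)$, i.e. over the non-QTL variance. The default design — about
500 phenotyped F2s from 30 founder pairs, markers every 5 cM on a 50 cM
chromosome, an additive QTL of one phenotypic standard deviation at
17 cM, $h^2 = 0.4$ — mirrors the scale of a typical pig intercross
chromosome study. The founder number matters more than it may appear:
pedigree-based heritability estimates draw their information from
between-family contrasts, so a design with very few F1 couples gives
noisy and, in small samples, upward-biased $\hat h^2$ no matter how many
offspring are phenotyped; 30 couples for 500 offspring reflects real
resource populations and makes $\hat h^2$ well behaved. A truth file
records the simulated origins, polygenic values and residuals; it is
written for validation and never read by analysis code.
`simulate_snp_panel()` draws Hardy–Weinberg genotypes, optionally in
subpopulations whose frequencies drift following a Balding–Nichols Beta
distribution with parameter $F_{st}$ — the testbed for
structure-corrected association.

What the simulator does *not* emulate — linkage disequilibrium among
panel SNPs, selection, genotyping error, non-Gaussian residuals,
partially informative microsatellites (available in the analysis code via
`line_freqs` but not generated) — bounds what passing tests show: they
validate the algorithms under their own assumptions, not robustness to
every feature of real data.

## Validation performed by the test suite

The tests re-derive expected values from independent oracles rather than
from the implementation: the tabular $\mathbf{A}$ against Monte-Carlo
gene dropping ($10^5$ drops); Henderson's $\mathbf{A}^{-1}$ against the
numerical inverse; $\mathbf{G}$/$\mathbf{G}^*$ against direct formula
evaluation; the HMM against exhaustive enumeration over all ordered
origin configurations on short chromosomes; EM-REML against the
closed-form balanced one-way estimators, a 1-D grid search of the REML
log-likelihood, and `lme4`; and LRTs against textbook regression tests.
Statistical behaviour is checked by simulation at the default study
design: recovery of $a = -1$ and $h^2 = 0.4$ at $n = 500$ over 20
replicates, nominal 5% size of the pointwise test under the null over
200 replicates, reduced null-SNP inflation when the
$\mathbf{G}^*$ term is added under a confounded two-subpopulation design,
and correct attribution in the conditional linkage-vs-LD comparison.
The heavier simulation studies use `fix_vc = TRUE` scans, warm-started
EM and a $10^{-7}$ EM tolerance; these choices change the reported
estimates by far less than their Monte-Carlo spread.

## Known limitations

* Outbred (non-cross) linkage analysis needs an externally computed IBD
  covariance matrix supplied as a user matrix; the package does not
  estimate IBD from markers in general pedigrees.
* Single-trait models only; no sex-chromosome transmission model; no
  interference-aware map functions; no permutation thresholds.
* EM-REML's slow boundary convergence (above); average-information REML
  is out of scope.
* The parameter-file dialect is a documented simplification: section
  names `DATA`, `PEDIGREE`, `MARKERS`, `EFFECT`, `QTL`, `TRAIT`, QTL
  keywords `fix_a`/`fix_d`/`fix_ad`/`fix_ipat`/`fix_imat`/`ran_a`/
  `snp_fix`/`snp_ran`, scopes `global`/`pos`/`snp`, nesting `(column)`.
  Consecutive QTL lines with the same scope and nesting describe one
  locus (so an `fix_a` line followed by an `fix_ad` line yields a single
  additive+dominance term); a blank line starts a new locus.

## A worked example

```{r, eval = FALSE}
library(qtlmm)

sim <- simulate_cross(sim_design(n_f2 = 500, h2 = 0.4,
                                 qtl = list(pos_cM = 17, a = -1, d = 0),
                                 seed = 42))
cr <- sim$cross
rnd <- list(u = list(K_inv = pedigree_A_inverse(cr$ped)))

## genome scan with a polygenic term
sc <- scan_qtl(y ~ sex, cr, random = rnd, effects = "add", fix_vc = TRUE)
plot(sc)
attr(sc, "argmax")

## refit at the optimum, variance components re-estimated
po <- origin_posteriors(cr, "1", attr(sc, "argmax")$pos_cM,
                        individuals = cr$pheno$id)
co <- qtl_coefficients(po[, , 1, drop = FALSE])[, "add", drop = FALSE]
colnames(co) <- "qtl_add"
fit <- qmm(y ~ sex, cr$pheno, random = rnd, qtl_columns = co)
summary(fit)
```
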