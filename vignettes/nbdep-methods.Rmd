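---
title: "Rank-based negative binomial mixed models for shRNA-level dependency screens"
author: "nbdep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based negative binomial mixed models for shRNA-level dependency screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pooled shRNA viability screens report, for every reagent `s` and cell line
`c`, the log fold change (logFC) of the reagent's sequencing count after the
screen relative to its initial library abundance. Strongly negative logFC
means the knockdown depleted the cells. A *self-dependency* is a gene whose
knockdown preferentially kills cell lines carrying an alteration in that same
gene — the kind of signal that nominates driver genes and drug targets.

Two nuisance processes contaminate shRNA-level readouts: technical offsets of
the screening pool a reagent was run in, and microRNA-like off-target
repression driven by the reagent's 7-mer seed (positions 2–8 of the guide),
whose strength tracks the thermodynamic stability of seed pairing. The usual
response is to aggregate each gene's reagents into a single gene-level score
first and test afterwards. nbdep instead keeps every reagent in the model and
handles the nuisance structure explicitly, which preserves power at the small
group sizes typical of cancer-specific analyses.

## The pipeline

**Preprocessing.** Cell lines whose mutation burden exceeds the panel mean by
more than three standard deviations are removed (a single pass; the
threshold is not recomputed). Genes absent from either the mutation or the
copy-number table are removed, as are shRNAs whose initial abundance is
missing or below 50 counts. Replicated readouts of an shRNA are averaged per
cell line. Two readings here were genuinely open and are fixed as follows:
the burden statistic uses the sample (n−1) standard deviation, and
"below 50" is read strictly (`< 50`, so 50 is kept). Replicate averaging is
applied to the viability readouts per cell line — averaging only the
abundance could not yield one row per shRNA. Note a structural limit of any
mean + 3 sd rule: with `k` outliers among `n` lines the largest attainable
z-score is about `sqrt((n-k)(n-1)/(nk))`, so hypermutated lines are only
detectable when they are few relative to the panel; the synthetic generator
respects this when injecting violations.

**Batch correction.** Pool membership and seed stability are attributes of
the shRNA, so the correction regression runs per *cell line* across its
observed shRNAs:

    y_s = alpha_c + delta_c[pool(s)] + gamma_c * stab(s) + eps_s,

with the pool factor coded sum-to-zero and the stability covariate centred
over the fitted shRNAs. The corrected value is
`y_s - delta_c[pool(s)] - gamma_c (stab(s) - mean stab)` — residual plus
intercept — which preserves each cell line's mean; downstream ranks are
invariant to the centring convention, which is why the choice is safe.
Cell lines whose observed shRNAs span a single pool lose the pool term, and
constant stability drops the stability term (the correction degrades
gracefully to the identity). Seeds missing from the stability table are
imputed at the table mean — equivalently zero after centring — rather than
dropping the reagent for the sake of an auxiliary covariate.

**Ranking.** Corrected values are ranked within each cell line across *all*
retained shRNAs of all genes, rank 1 = most depleted. Missing entries stay
missing and observed ranks are contiguous. Ties are broken by shRNA
identifier (C-locale order) so the pipeline is bit-reproducible. Ranks are
computed once, before reagent selection, and never recomputed: the test
consumes the global ranks.

**Concordant reagent selection.** Per gene, each shRNA's rank profile is
correlated (Pearson, pairwise-complete) with the gene's average rank profile
— including the shRNA itself; no leave-one-out — and the top `ceiling(n/2)`
shRNAs are retained. The ceiling means an odd-sized gene keeps its majority
evidence, and a single-reagent gene keeps its reagent. Correlations that are
undefined (fewer than 3 paired observations, zero variance) sort below every
defined one.

**The test.** For gene `g` and alteration class `a` (missense, non-missense,
or amplification), the viability rank `R_ik` of retained shRNA `i` in cell
line `k` is modelled as

    R_ik ~ NB(mu_ik, theta),   mu_ik = exp(beta0 + beta X_k + u_k),
    u_k ~ N(0, sigma^2) independent across cell lines,

where `X_k` is 1 for mutant and 0 for strictly wild-type lines. NB2 is a
two-parameter count family flexible enough for the overdispersed positive
ranks. The intercept is included because ranks have a large baseline mean;
the random intercept absorbs cell-line-wide viability differences. A
covariance more general than `sigma^2 I` is not identifiable from one
intercept per cell line, so independence is assumed. The one-sided Wald test
`p = Phi(beta_hat / se)` targets `H1: beta < 0` — depletion (lower ranks) in
altered lines — for all three classes, amplification included, because
self-dependency predicts depletion in every class. Benjamini–Hochberg
adjustment is applied within each alteration class (and within each
(cancer type, class) stratum in cancer-specific mode), matching how counts
of significant genes are reported per class; the stratification is a design
choice, made once.

Control lines are *strictly* wild-type: no missense, non-missense,
amplification or deep-deletion flag for the gene. Lines carrying only other
alteration classes are excluded from both groups rather than diluting the
controls. Deep deletion itself is never tested — knockdown of an absent gene
is not interpretable as a self-dependency — but it does disqualify a line
from the control group. A (gene, class) pair is testable when at least two
mutant and two wild-type lines each contribute an observed rank; the same
gate applies pan-cancer and per cancer type (the model is not estimable
below it). Cancer types enter the cancer-specific analysis only with at
least four cell lines, evaluated after preprocessing. The non-missense
category covers start/stop-codon deletions and insertions, frameshift and
in-frame indels, nonsense and splice-site events; the category list pairs
start- and stop-codon insertions symmetrically with the deletion pair.
Classification strings are matched case-insensitively with separators
unified, through a small alias table for MAF dialects (e.g.
`Frame_Shift_Del`); unrecognised strings (silent, UTR, ...) create no flag
and are tallied, not errors.

## Likelihood evaluation and fitting

Because the intercepts are independent, the marginal likelihood factorises
over cell lines into one-dimensional integrals

    l = sum_k log INT prod_i f(R_ik; mu_ik, theta) phi(u; 0, sigma^2) du.

`X` is constant within a cell line, so each integrand depends on the data
only through the cluster rank sum and cluster size (plus theta-dependent
gamma-function terms), and the per-cluster posterior mode is a scalar root
found by damped Newton steps on a globally concave objective — the whole
evaluation vectorises over clusters. Each integral is approximated by
adaptive Gauss–Hermite quadrature centred at the mode with curvature
scaling; `n_quad = 1` is exactly the Laplace approximation and is the
default, matching standard mixed-model practice for this family. Higher
node counts are exposed for verification; on the scales used here the
Laplace and 31-node answers agree to several decimals.

Optimisation runs over `(beta0, beta, log theta, log sigma)` with a
box-constrained quasi-Newton method from deterministic moment-based starts.
The `sigma -> 0` boundary is a flat ridge in `log sigma`; rather than
grinding along it, the search floors `sigma` at 1e-3 and a separate
three-parameter `sigma = 0` profile fit covers the boundary — whichever
attains the higher likelihood is reported, with `sigma^2 = 0` when the
profile wins (ties go to the simpler model). The standard error of `beta`
comes from the inverse of a central-difference observed-information matrix
at the chosen optimum. The convergence flag requires a zero optimiser status,
a finite standard error, and a gradient norm below `tol * (1 + |loglik|)`
(default `tol = 1e-6`, i.e. a relative criterion — likelihoods here are in
the hundreds to thousands).

The ablation variants replace the response construction while sharing the
grouping, selection and testing machinery: Gaussian random-intercept models
on raw or corrected logFC (exact marginal likelihood, closed-form GLS for
the fixed effects, profiled variances), and the NB rank model on ranks of
raw logFC. Each variant selects concordant shRNAs from the rank matrix of
its own response, so "selection" means the same operation applied to the
variant's scale; the denoised-rank variant is bit-identical to the main
pipeline.

## The synthetic generator

`generate_synthetic_screen()` emulates the structure the pipeline assumes:

    logFC(s, c) = gene_effect + driver_shift * mutant(gene, c)
                + pool_offset + slope * stability(seed) + cell_effect + noise.

Defaults (chosen once as a plausible desk-scale screen, and stated here
because the simulation results depend on them): 100 genes x 10 shRNAs x 40
cell lines; pool offsets +0.4 / −0.4 / 0 across three pools; stability slope
0.15 on stabilities ~ N(−9, 2) (arbitrary energy units, negative = more
stable pairing); gene-effect sd 0.5; cell-line sd 0.3; residual sd 1 —
reagent-level noise dominates, as in real screens; driver fraction 5% with a
logFC shift of −1 in mutant lines (a strong, canonical-driver-sized effect);
20% of lines mutant per driver; background missense rate 0.1 per gene x
line so null genes form testable groups; initial abundances NB(mean 500,
shape 2) with 2% missing, so a few percent of reagents naturally fall under
the abundance filter. Mutation and GISTIC tables are consistent with the
mutant assignments; a fraction of seeds is withheld from the stability table
to exercise imputation; hypermutated lines, genes without molecular data and
replicated readouts can be injected, and the generator records the realised
identities of every injection so filter accounting can be checked exactly.

What the generator does *not* emulate: correlated off-target structure
beyond the scalar stability trend (no per-seed latent effects as in
gene-level aggregation models), copy-number dosage effects on expression,
non-additive batch structure, and missingness that depends on depletion
(dropout). Passing tests therefore demonstrate correctness of the machinery
and calibration under the assumed structure, not robustness to every
pathology of real screens.

## Simulation protocols

*Type-I error.* For each analysed gene with `m` mutant and `w` wild-type
lines, a replicate draws `n_m ~ Uniform{2..m}` lines from all cell lines
into a pseudo-mutant group and `n_w ~ Uniform{2..w}` from the remainder
(both ends inclusive); labels are random so the null holds by construction.
Replicates are spread evenly over genes with the remainder to the first
genes. *Power.* Settings subsample `n_m` real mutant lines and `n_w = q n_m`
wild-type lines, `n_m` in 2..10 and `q` in {1, 2, 3, 4}. In both protocols
rejection uses the uncorrected `p < 0.05` — these are per-test error rates,
not FDR-adjusted discovery counts — and precomputed ranks and consistent
sets are reused across replicates (denoising is label-free; only the mixed
model is refit), which is statistically identical and orders of magnitude
faster. Every replicate draws its seed from a master seed via one
`sample.int` stream, so reports are exactly reproducible and replicate `j`
is independent of how many replicates run.

Desk-scale problem sizes used by the test-suite and the acceptance script
(the package's own choice of scale): calibration on the model-matched null
uses 500 replicates of 20 cell lines x 10 shRNAs; the pipeline-level
pseudo-group protocol uses 1000 replicates on a 60-gene screen; power runs
200 replicates per setting on a 60-line screen whose driver has 12 mutant
lines; effect recovery uses 200 replicates of 40 lines x 10 shRNAs at a
generating effect of −0.4.

## Numerical choices and degenerate inputs

- Quadrature nodes come from the Golub–Welsch construction
  (`pracma::gaussHermite`), cached per node count; the adaptive transform
  spans the mode ± a curvature-scaled neighbourhood, and `n_quad = 1`
  reproduces Laplace exactly.
- The inner Newton iteration for the posterior mode clamps steps at ±4 and
  stops at increments below 1e-12; the objective is strictly concave so the
  iteration cannot cycle.
- All-equal ranks are rejected as degenerate; a gene whose observations lack
  one of the two groups is an error at the fitting level and a skipped row
  at the pipeline level.
- Ranking ties (possible in principle after correction) break by reagent
  identifier; duplicate readouts must agree on their annotations or loading
  fails.
- Written tables carry 17 significant digits so load–write–load is the
  identity.

## Limitations

The Wald test with a Laplace-approximated likelihood is mildly
anti-conservative at small cluster counts — the model-matched null rejects
at slightly above the nominal 5% — consistent with the general behaviour of
Wald inference in mixed models at these sizes. The method tests
self-dependency only; trans effects (synthetic lethality) are out of scope,
though the denoised rank matrix is a usable starting point for them. Variant-
level filtering (allele frequency, hotspots) is deliberately not performed:
classification strings decide flags, nothing else.
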