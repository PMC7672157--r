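---
title: "Genomic heritability by ridge regression and GCV: models, corrections, and accuracy theory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic heritability by ridge regression and GCV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcvherit)
```

## The model

`gcvherit` works under the standard additive polygenic model for a
quantitative trait measured on $n$ individuals genotyped at $p$ SNPs,

$$ y = \mu \mathbf{1}_n + Z u + X \beta + e, $$

where $Z$ is the column-standardized $n \times p$ genotype matrix, the
SNP effects are homoscedastic random effects $u \sim N(0_p, \tau I_p)$,
$X$ holds optional fixed covariates, and $e \sim N(0_n, \sigma^2 I_n)$.
The genomic heritability is the variance ratio
$h^2_G = p\tau / (p\tau + \sigma^2)$.

The best linear unbiased predictor of $u$ under this model coincides
with the ridge estimator
$\hat u_R = Z^\top (Z Z^\top + \lambda I_n)^{-1} y$ at
$\lambda = \sigma^2/\tau$, which ties the penalty to the heritability
through the one-to-one map

$$ h^2_G = \frac{p}{p + \lambda}, \qquad \lambda = p\,\frac{1 - h^2_G}{h^2_G}. $$

Instead of estimating $(\tau, \sigma^2)$ by REML, the package selects
$\lambda$ by a *predictive* criterion — Generalized Cross-Validation —
on the heritability grid $\{0.01, 0.02, \ldots, 0.99\}$ and reads the
heritability off the selected penalty. The endpoints 0 and 1 are
excluded because they map to infinite and zero penalty. Ties on the
grid break toward the smaller heritability (the more regularized
model), a conservative choice given the degeneracy described next.

## GCV and the high-dimensional centering degeneracy

GCV approximates leave-one-out error from a single fit,

$$ \mathrm{err}_{GCV}(\lambda) =
   \frac{\lVert y - H_\lambda y \rVert^2}
        {\left[\tfrac{1}{n}\,\mathrm{tr}(I_n - H_\lambda)\right]^2},
   \qquad H_\lambda = Z (Z^\top Z + \lambda I_p)^{-1} Z^\top . $$

Every penalty sweep is served by one spectral decomposition: with
$Z = U D V^\top$, both the numerator and the trace are $O(n)$ functions
of the singular values per grid point. Refactorizing per grid point is
never done; that reuse is the entire computational argument for GCV
over $k$-fold CV.

When the columns of $Z$ (and the phenotype) are *empirically* centered
and $p > n$, each row of $Z$ becomes a linear combination of the
others: $Z Z^\top$ acquires a null eigenvalue with a constant
eigenvector, the centered phenotype has no component on it, and
$\mathrm{err}_{GCV} \to 0$ as $\lambda \to 0$. The criterion is then
minimized at the grid boundary and the heritability estimate saturates
at 0.99 regardless of the truth. `estimate_h2(..., method = "gcv_naive")`
implements exactly this uncorrected estimator; it is kept as a negative
control and reproduces the failure on demand.

Two corrections are provided:

* **Projection** (`gcv_projection`, the recommended default). A
  semi-orthogonal contrast $C$ with $C C^\top = I_{n-r-1}$ and
  $C(\mu\mathbf{1} + X\beta) = 0$ maps the system onto the orthogonal
  complement of the fixed-effect span; GCV is evaluated on
  $(C y, C Z)$. With covariates, $C$ comes from the QR decomposition of
  $[\mathbf{1} \mid X]$. Intercept-only, the left singular vectors of
  the centered $Z$ themselves provide a contrast under which
  $(CZ)(CZ)^\top$ is already diagonal, so the whole grid costs one
  eigendecomposition. The criterion is basis-independent: any valid
  contrast of the same span gives identical estimates (this is tested).
  In the contrasted criterion the trace denominator uses the contrast
  dimension $n - r - 1$, since that is the dimension of the system the
  criterion is evaluated on.

* **Two sets** (`gcv_two_set`). Variant means/scales and the fixed
  effects (ordinary least squares of the standardization-set phenotype
  on $[\mathbf{1} \mid X]$) are learned on a disjoint sample and applied
  to the training data, which breaks the dependency without a
  contrast. Only the standardization-set estimates are subtracted from
  the training phenotype; the training-set mean is *not* re-removed,
  since re-centering would reintroduce the dependency the split exists
  to remove. The cost is a smaller effective sample for estimation.

A `kfold_cv` comparator scores the same grid by 10-fold validation MSE.
Folds are contiguous blocks after a seeded shuffle; each fold's
validation data is standardized with the training folds' empirical
statistics (and fixed effects learned on the training folds), i.e. the
no-leakage convention mirroring the two-set logic. The fold-wise
spectral decompositions depend only on the genotypes, so many
phenotypes can be scored for one decomposition.

A `reml_profile_oracle()` provides an independent check: the restricted
log-likelihood of $y \sim N(0, \sigma^2_{tot}(h^2 K + (1-h^2) I))$,
with $K = ZZ^\top/p$, is profiled analytically over the total variance
and evaluated on the same grid via the eigenvalues of the contrasted
$K$. It is deliberately grid-based — a comparator for validating the
GCV estimates, not a replacement for iterative AI-REML software. In
the intercept-only, $p \ge n$ case it reuses the same decomposition as
the projection estimator (the contrasted GRM spectrum is
$d^2_{-n}/p$); otherwise it contrasts the dense GRM. When $p < n$ the
thin SVD does not span the whole contrast space, which is why the
dense route exists.

`estimate_h2()` accepts a *matrix* of phenotypes and returns one fit
per column for a single decomposition — the natural idiom for
simulation studies where many traits share one genotype matrix.

## Prediction-accuracy theory

For a unit-variance trait, independent variants, and the
heritability-matched penalty, the expected out-of-sample squared error
and squared correlation admit closed forms in the ratio $n/p$:

$$ \mathbb{E}\,[(y_{te} - \hat y_{te})^2] \approx
   \begin{cases}
     1 - \frac{n}{p} h^4, & p \ge n \\[4pt]
     (1 - h^2)\,\dfrac{1 + \frac{n}{p} h^2}{1 + h^2(\frac{n}{p} - 1)}, & n > p
   \end{cases}
 \qquad
 \mathrm{corr}^2(y_{te}, \hat y_{te}) \approx
   \begin{cases}
     \frac{n}{p} h^4, & n < p \\[4pt]
     \dfrac{h^4}{\frac{p}{n}(1 - h^2) + h^2}, & n \ge p
   \end{cases} $$

with the training-set error $(1-h^2)^2$ for $p > n$ and
$1 - 2as + a^2 s$ (where $a = n/(n+\lambda)$,
$s = \frac{p}{n}(1-h^2) + h^2$) otherwise. The $n > p$ error branch is
written here in the only algebraic reading that is both continuous at
$n = p$ and converges to the irreducible error $1 - h^2$ as
$n/p \to \infty$; both limits are asserted in the test suite, along
with branch continuity at $n = p$ to $10^{-12}$ across a dense $h^2$
grid. The formulas carry the two qualitative messages the package
exists to quantify: prediction error is bounded below by $1 - h^2$ but
approaches the trait variance 1 whenever $p \gg n$ *regardless of
heritability*, and the squared correlation never exceeds $h^2$,
reaching it only when $n \gg p$.

`exact_decomposition()` gives the exact irreducible / variance /
squared-bias split for a *fixed* training design,
$\sigma^2 + \sigma^2\,\mathrm{tr}(K_\lambda K_\lambda^\top) +
u^\top (K_\lambda Z - I_p)^2 u$ with
$K_\lambda = (Z^\top Z + \lambda I)^{-1} Z^\top$. Since
$(Z^\top Z + \lambda I)^{-1}$ and $Z^\top Z$ commute, $K_\lambda Z$ is
symmetric and the square is the ordinary matrix square. At an
orthogonal design ($ZZ^\top = pI$) with evenly spread effects the
decomposition total reproduces the closed form exactly; this identity
is tested numerically to $10^{-8}$.

For real genomes, linkage disequilibrium reduces the effective number
of independent markers. `effective_snp_fit()` inverts the
high-dimensional branch on observed (normalized) test errors,
$n/p_e = (1 - \mathrm{MSE})/h^4$, and regresses these effective ratios
on the true ratios *through the origin*; the slope estimates $p/p_e$.
An intercept option exists but defaults off. Observations with
normalized MSE $\ge 1$ (implying a nonpositive ratio) are excluded
with a warning. The normalization divides test MSE by the variance of
the phenotype residuals after removal of non-penalized effects.

## The simulator and what it does (not) emulate

The generator implements the classical independent-loci design:
frequencies $f_j \sim U[0.05, 0.5]$, allele counts
$m_{ij} \sim \mathrm{Binomial}(2, f_j)$, a fraction $f_c$ of variants
causal with effects $N(0,\, h^2/(p f_c))$ (the number of causal
variants is $\mathrm{round}(p f_c)$, at least 1 when $h^2 > 0$), and
noise variance $1 - h^2$, so the trait has unit variance in
expectation. Standardization by the *true* frequencies
($z = (m - 2f)/\sqrt{2f(1-f)}$) defines the fully synthetic scenario;
empirical and external-set standardization are what an analysis of
real data would use. Empirical standardization uses the denominator-$n$
(population) standard deviation so columns have exactly unit second
moment; this is the convention the centering-degeneracy algebra
assumes, and it is configurable only by supplying external statistics.

Deliberately *not* simulated: linkage disequilibrium (the accuracy
formulas assume independent variants — on real genomes they hold only
after the effective-marker adjustment), population structure,
relatedness, dichotomous traits, and gene–environment interaction.
Passing tests on this generator therefore validate the estimator's
behavior under its own model assumptions; they do not certify
performance under LD or stratification, where only the real-data
protocol (QC, relatedness pruning, covariate projection) applies.

Seeding: a top-level seed spawns independent per-purpose integer
streams (frequencies, genotypes, effects, noise, standardization set,
test set, folds), so enlarging $p$ or adding a standardization set
does not perturb the noise draws — required by the nested-subset
designs below. All draws go through R's RNG (the genotype sampler
inverts the Binomial(2, f) CDF with one uniform per entry in compiled
code), so everything is bit-reproducible from the seed; the large test
set is accumulated in fixed-width column chunks to keep memory bounded
without changing results.

## Replicated prediction experiments

`replicate_experiment()` implements the nested-subset accuracy design:
one global frequency vector and one global effect vector are drawn at
$p_{max}$; for each $p$ the leading-$p$ effects are rescaled by
$\sqrt{p_{max}/p}$, keeping total genetic variance at $h^2$; one test
set is simulated per $p$ (with its own stream) and many training sets
are fitted at the matched penalty $\lambda = p(1-h^2)/h^2$ (using the
*true* simulated $h^2$ by default; a GCV-estimated penalty is a
caller's choice). Per $p$ the ensemble reports

* `err` — the mean over training replicates of the per-replicate test
  MSE. (The bias–variance identity `err ≈ bias² + var + (1 − h²)` holds
  for this definition and is tested; defining the error against the
  ensemble-mean prediction instead would drop the variance term.)
* `bias2` — squared distance between the known genetic signal
  $Z_{te} u_p$ and the ensemble-mean prediction,
* `var` — mean squared spread of replicate predictions around the
  ensemble mean,
* the per-replicate squared correlations and their mean.

`error_bar_decomposition()` contrasts the two aggregation views of the
error spread: across training replicates (small — the fit is stable)
and across test individuals (large — individual errors are dominated
by the environmental residual). The second exceeding the first is the
quantitative form of "high heritability does not imply accurate
individual prediction".

With few causal variants (e.g. $p = 20$) the single global effect draw
has realized variance $h^2 \chi^2_p / p$, so any one experiment's mean
accuracy tracks the *realized* heritability of that draw; comparisons
against the closed forms at small $p$ must budget for this draw-level
spread, not only for the training-replicate standard error.

## Real-data plumbing

PLINK `.bed/.bim/.fam` (SNP-major v1.00, bit-exact against hand-packed
fixtures in the tests) and tab-separated tables are read and written
natively. The QC filter applies, in a fixed order chosen because order
changes outcomes: variant callrate → sample callrate (both $> 0.99$) →
minor allele frequency ($> 0.01$) → Hardy–Weinberg equilibrium
(1-d.f. goodness-of-fit chi-square, keep if $p > 10^{-7}$; the exact
test is not used because the plain chi-square is deterministic,
closed-form, and adequate at these thresholds) → removal of remaining
monomorphic variants. Every removal is logged with its reason, and the
filter is idempotent. Missing genotypes are mean-imputed after QC and
before standardization. Relatedness pruning on the GRM
($K = ZZ^\top/p$, threshold 0.025) removes, from each offending pair,
the individual in the most offending pairs, ties broken toward the
later sample id — "one individual in all pairs" does not pin down a
unique rule, so this greedy maximum-degree rule is fixed and
documented rather than inferred.

## Numerical choices and problem sizes

* Singular values below $\max(n,p)\,\varepsilon\,d_{max}$ are snapped
  to exact zero; identifying the exact null space created by centering
  is what the intercept-only contrast construction relies on.
* The primal $(Z^\top Z + \lambda I)^{-1} Z^\top y$ and dual
  $Z^\top (ZZ^\top + \lambda I)^{-1} y$ routes are both implemented,
  cross-tested to $10^{-10}$, and selected by $\min(n, p)$.
* `gcv_error` reports `+Inf` with a degeneracy flag (never `NaN`) when
  the trace denominator vanishes; `loo_error` does the same when a
  leverage reaches 1. `loo_error` is a *sum* of scaled residuals,
  paralleling the GCV numerator, and equals the literal
  refit-each-observation leave-one-out to $10^{-8}$ in the tests.
* The default validation suites run the estimator designs at
  $n = 1000$, $p = 10{,}000$ (10–30 replicates) and the accuracy sweep
  at $p$ from 50,000 down to 20 with 50 training replicates — large
  enough for the Monte-Carlo bands to be meaningful on a single
  desktop core, while the full-scale configurations remain available
  through `experiment_config()`.

## Known limitations

No standard errors or confidence intervals are attached to the
heritability estimate (replicate spread is the intended measure); no
LD-aware weighting of markers; no binary traits; the REML comparator
is a grid profile, not a Newton-type maximizer, so its resolution is
the grid step; and the accuracy formulas assume the
heritability-matched penalty — they do not describe ridge at an
arbitrary $\lambda$.
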