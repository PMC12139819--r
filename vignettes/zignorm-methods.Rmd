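---
title: "Modelling growth and mortality reaction norms across common gardens"
author: "zignorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling growth and mortality reaction norms across common gardens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Replicated common-garden (provenance) trials plant clonal genotypes across
many sites and measure performance repeatedly. When the sites span a wide
climatic gradient, the trial identifies each genotype's *reaction norm* —
its expected performance as a continuous function of site climate — and
how those norms vary with the genotype's climate of origin and its genomic
background. `zignorm` implements this analysis for a design measuring
annual height growth increment and survival of clonal tree genotypes in a
network of gardens characterized by their mean coldest month temperature
(MCMT, °C), with genotypes carrying a home-climate MCMT, three genomic
principal components, and a species-ancestry proportion `q` from a
two-species hybrid zone.

## The model

Two fitness components enter one zero-inflated Gaussian (ZIG) mixed model.
For observation $i$ (one tree in one year), let $y_i = \log(\mathrm{growth}_i + 1)$
and let $z_i$ indicate a structural zero (the tree was recorded dead, so
its growth is coded 0). With $p_i$ the structural-zero probability and
$\mu_i$ the conditional mean,

$$
f(y_i) \;=\;
\begin{cases}
p_i + (1-p_i)\,\varphi(0;\mu_i,\sigma^2), & y_i = 0\\[2pt]
(1-p_i)\,\varphi(y_i;\mu_i,\sigma^2), & y_i > 0 .
\end{cases}
$$

Mixing a point mass with the value of a continuous density is the
numerical convention of zero-inflated continuous families in the widely
used mixed-model tools for this model class, which keeps fitted
log-likelihoods directly comparable across software. Zeros recorded on
*live* trees are retained and handled by the same mixture ("sampling"
zeros), while dead trees' zeros are "structural".

Both linear predictors share the same fixed-effect structure. With $g$ the
garden MCMT and $h$ the home MCMT, each divided by its root-mean-square
(`scale(x, center = FALSE)`; divisors stored so predictions for new data
reuse the training scaling), the full variant crosses $g$ and $h$ with
their squares and adds the three genomic PCs and their interactions with
$g$ and $g^2$:

```
(Intercept), g, h, g2, h2, g:h, g2:h2, g2:h, g:h2,
pc1, pc2, pc3, pc1:g, pc2:g, pc3:g, pc1:g2, pc2:g2, pc3:g2
```

(18 columns; squares are formed from the *scaled* values and not rescaled
— the simplest reading consistent with scaling "the numeric variables"
before fitting, and the choice is recorded so predictions invert it
coherently). The `genetics_only` variant drops every home-climate column
(12 remain) and `climate_only` every PC column (9 remain). Random
intercepts enter both parts for genotype, garden, block nested within
garden (block levels are garden-specific), year, and individual tree; the
two parts' random effects are independent vectors. A
`model_spec(zi_random_terms=)` option allows a reduced random-effect
structure in the zero-inflation part, analogous to specifying a separate
zero-inflation formula.

## Estimation

The marginal likelihood integrates the random intercepts out of the joint
density; `zignorm` approximates the integral by a Laplace approximation:

1. **Inner problem.** For fixed parameters, the joint log-density is
   maximized over all random effects by damped Newton iterations with the
   exact sparse negative Hessian $H = B_u^\top W B_u + P$ ($W$ holds
   per-observation 2×2 curvature blocks across the two linear predictors,
   $P$ the prior precisions), factorized by sparse Cholesky. The
   approximate marginal is the joint value at the mode plus
   $\tfrac12(q\log 2\pi - \log\det H)$. The approximation is exact when
   all observations are positive (the Gaussian case), a property the test
   suite exploits against a closed-form multivariate-normal oracle.

2. **Outer problem.** A quasi-Newton optimizer (`nlminb`) maximizes the
   Laplace objective jointly over the fixed effects of both parts,
   $\log\sigma$, and the log random-effect SDs, using an *analytic*
   gradient: the envelope (score) term plus the derivative of the
   log-determinant,
   $\tfrac12\operatorname{tr}(H^{-1}\,\mathrm{d}H/\mathrm{d}\theta)$,
   including the indirect dependence through the mode. The traces contract
   per-observation blocks of $B_u H^{-1} B_u^\top$ — obtained from a
   Takahashi selected inverse of the sparse Cholesky factor (the package's
   single compiled kernel) — against analytic third derivatives of the
   observation log-likelihood. Every derivative formula is validated
   against finite differences in the test suite. Maximizing the exact
   Laplace objective in the fixed effects matters: profiling them at the
   joint mode instead (an h-likelihood-style shortcut) ignores the
   curvature's dependence on the zero-inflation coefficients and
   measurably biases quadratic temperature terms.

3. **Uncertainty.** The joint fixed-effect covariance is the inverse Schur
   complement of the random-effect block in the observed information at
   the optimum (conditional on the variance parameters, the convention of
   comparable mixed-model software). Wald chi-square tests are per
   coefficient with one degree of freedom, since every model term
   contributes one column.

Numerical choices: deterministic initialization (OLS on the positive
responses; logistic regression on the zero indicator, clamped to ±5; all
log-SDs at $\log 0.5$); inner gradient tolerance $10^{-8}$; outer relative
tolerance $10^{-8}$; fixed effects bounded at ±15 so a separated
zero-inflation part (small folds can predict their zeros perfectly) pins
benignly at the boundary instead of diverging; random-effect SDs bounded
in $[10^{-4}, 10]$ on their natural scale, with estimates below $10^{-3}$
flagged as boundary; convergence is declared on optimizer success or on a
stationarity check: the Newton-step bound on the attainable improvement in
the fixed effects, $\tfrac12 g^\top \Sigma g$ with $\Sigma$ the Schur
covariance, must fall below a quarter log-likelihood unit (far beneath
inferential relevance; near separation the bound overstates what is
attainable along likelihood asymptotes) with the variance-parameter scores
small (their profile is flat near small SDs). If the check fails, explicit
Newton polish steps on the fixed effects alternate with further
quasi-Newton passes before the fit is declared unconverged. Degenerate
inputs: no zeros pins the zero-inflation part with a warning; all zeros
returns an unconverged degenerate fit; collinear fixed-effect columns are
an error naming the columns (training designs only — held-out designs
reuse training scaling and may be short).

An independent oracle, `brute_force_marginal_loglik()`, evaluates the same
marginal by adaptive (mode- and curvature-centred) Gauss–Hermite
quadrature with at least 50 nodes per dimension, factorizing over levels
when a single grouping factor is present. It is guarded to tiny instances
and used only in tests; Gauss–Hermite nodes come from the Golub–Welsch
eigenvalue construction.

## Predictions, reaction norms, fitness proxy

`predict_components()` returns the conditional mean of $\log(g+1)$, a
back-transformed growth (default the plug-in $\exp(\eta)-1$; a
lognormal-mean correction $\exp(\eta + \sigma^2/2)-1$ is selectable — the
evaluation functions default to the log scale precisely so no
back-transform choice is forced), the mortality probability, and the
overall fitness proxy $(1-p)\times\mathrm{growth}$. Random effects
contribute their conditional modes for known levels and zero for unseen
levels (the population-level convention for new gardens or genotypes).
`reaction_norm()` evaluates a genotype over an equally spaced MCMT grid —
by default 100 points from −23.9 to 9.8 °C, spanning the home climates and
garden climates of the motivating network — and reports the grid argmax
temperatures for growth and overall fitness, ties breaking toward the
colder temperature for determinism. `transfer_distance_view()` re-indexes
a norm by garden-minus-home MCMT.

## Transferability evaluation

`leave_one_garden_out()` refits the model with each garden excluded,
recomputing covariate scaling on the training gardens only (no leakage),
and predicts the held-out garden with zero deviation for its unseen
garden/block levels. Two Pearson prediction abilities are reported per
garden × year × variant: *conditional* (observed zeros excluded) and
*overall* (dead trees as observed 0, predicted $(1-p)\times$ growth).
Undefined correlations are reported as missing, never zero.
`compare_model_variants()` pairs fold scores by garden × year and applies
an exact two-sided Wilcoxon signed-rank test: zero differences are dropped
and counted, and the null distribution of the positive-rank sum is built
by sign-flip enumeration (dynamic programming over doubled midranks), so
arbitrary tie patterns remain exact; a paired t-test is available by
option.

## Rangewide projection

`project_best_genotype()` reads a single-band MCMT raster (plain-text ESRI
ASCII grid; GeoTIFF input is not supported and is rejected with a clear
message — convert with `gdal_translate -of AAIGrid`), quantizes cell
values to 0.01 °C, predicts every genotype's overall fitness at each
unique temperature (fixed effects only, each genotype keeping its own home
climate and PCs), and maps the argmax genotype and its ancestry
proportion. Cells outside the mask bounds — by default the garden MCMT
range −16.5 to 9.8 °C, i.e. the climates the model was trained on — are
masked; argmax ties break toward the lowest genotype index.
`shift_summary()` compares two scenario maps cell-wise. Output layers
round-trip through the same ASCII format exactly.

## The synthetic trial generator

Because the motivating field data are not published with an accession, the
generator is a first-class module whose defaults *are* the study
conditions the package is tested under: 45 clonal genotypes spanning
ancestry $q\in[0,1]$ (a mixture of near-parental and intermediate
components), home MCMT increasing with the warm-species share over
[−23.9, −3.8] °C, 17 gardens × 2 blocks × 2 years (≈3060 observations)
with garden MCMT quasi-evenly spaced over [−16.5, 9.8] °C so both climatic
extremes stay anchored, plus a small per-year jitter. PC axes are built
from noise orthogonalized against home MCMT so the realized correlations
hit their targets exactly (−0.69 for PC1; −0.22 and −0.40 for PC2/PC3,
matching the observed coupling of genetic structure and climate).
The zero-inflation intercept is calibrated by root finding so the expected
structural-zero fraction equals its target (0.27), with zeros
concentrating at the temperature extremes through a convex zero-inflation
logit.

True fixed effects act on the scaled design. The defaults encode: a
dominant quadratic garden-MCMT response with an interior optimum;
higher growth and a warmer optimum for genotypes with more warm-species
ancestry (negative PC1 main effect and `pc1:g` interaction, since PC1
decreases with ancestry `q`); a truly null `pc2` and `pc2:g2` (used by the
type-I-error experiment); and weak home-climate terms. The conditional
intercept is 4.2 (typical annual increments around 60 cm, realistic for
young poplar); this keeps the mass of the truncation that protects
$\log(\mathrm{growth}+1)\ge 0$ below half a percent, so the generator
matches the fitted likelihood to that order and the score-identity
property (mean score at truth equals zero) holds — survivor growth is
drawn from the truncated normal exactly, by inversion. Variance-component
defaults (0.15–0.4 by factor, zero for the individual zero-inflation term,
which one observation per tree-year cannot identify; $\sigma = 0.5$) are
arbitrary but fixed; nothing in the data motivating the package constrains
them.

What the generator does *not* emulate: spatial or temporal autocorrelation
beyond the intercept hierarchy, herbivory/measurement error (negative
increments), missing data, genotype-by-year interactions, linkage
structure in the genomic covariates, or multivariate climate. Passing
tests therefore demonstrate the estimator's correctness under the model's
own assumptions — not robustness to the field realities the quality
filters exist for.

## Recovery experiments and their statistics

`recovery_experiment()` repeats simulate → fit cycles and summarizes
per-parameter estimates, Wald SEs and 95% CI coverage. Two statistics
deserve explanation:

* **Control-variate bias.** At this design, the garden-MCMT coefficient's
  per-replicate sampling SD is large (garden-level confounding with 17
  gardens), so averaging `estimate − truth` over a feasible number of
  replicates cannot resolve biases of a few percent. The table therefore
  also reports `bias_cv`: the mean difference between the ML estimate and
  a GLS oracle computed on the survivors at the *true* variance
  components. The oracle is linear in the responses and exactly unbiased,
  and it shrinks group effects the way the ML fit does, so the difference
  isolates systematic bias with an order-of-magnitude smaller Monte Carlo
  error.
* **Pooled coverage.** Per-parameter coverage over 30 replicates carries
  binomial noise of ±4–6 points; `pooled_coverage` averages the coverage
  indicator over all fixed effects and replicates, which is the
  statistically stable summary the acceptance checks assert.

The acceptance suite runs 30 replicates of the default design (and 200
reduced-scale replicates — 15 genotypes × 8 gardens, genotype and garden
intercepts — for the type-I-error check of the null `pc2:g2` term); these
sizes balance Monte Carlo precision against the cost of refitting the full
model hundreds of times and are stated here as the package's own choice.

## Known limitations

* The Laplace approximation shares the small-cluster bias of all
  Laplace-based mixed-model tools for the binary part; the quadrature
  oracle quantifies it on small instances (the test suite holds the gap
  below $10^{-3}$ at a six-level instance's ML point).
* Wald intervals condition on the variance parameters; with 17 gardens
  the garden-level effects' intervals run slightly narrow, which the
  pooled-coverage experiments quantify.
* The fitness proxy multiplies survival by growth on the response scale;
  it is a ranking device, not a demographic rate.
* Reaction norms extrapolate outside the garden climate range; the
  projection module masks such cells rather than predicting them, and
  `predict_components()` can attach an extrapolation warning.
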