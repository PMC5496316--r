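---
title: "Evaluating MIMIC-based uniform-DIF detection by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating MIMIC-based uniform-DIF detection by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

When a questionnaire is used to compare two populations — typically a large
reference group and a small clinical (focal) group — an item shows
*differential item functioning* (DIF) if respondents at the same level of
the latent construct answer it differently depending on group membership.
*Uniform* DIF is the simplest and most consequential form: a constant offset
in the item's difficulty across the whole trait range. The MIMIC (multiple
indicators multiple causes) structural equation model is a popular DIF
screen precisely because it needs only one joint covariance matrix and thus
works with modest samples. This package provides a complete Monte-Carlo
laboratory for asking: *how often does the MIMIC Wald test find uniform DIF
that is there (power), and how often does it cry wolf (Type I error), when
the focal group is small and the latent trait may be heavily skewed?*

## Data-generating model

Ordinal responses come from the graded response model (GRM). For item $i$
with discrimination $a_i$ and ascending thresholds $b_{i1} < \dots <
b_{i,J-1}$, the probability of answering in category $j+1$ or above is

$$P(Y_i \ge j + 1 \mid \theta) = \frac{e^{a_i(\theta - b_{ij})}}
{1 + e^{a_i(\theta - b_{ij})}},$$

and category probabilities are adjacent differences of these cumulative
curves. Per replication a fresh item bank is drawn: $a_i \sim
\mathrm{Uniform}(1.5, 2)$ and thresholds as i.i.d. standard normal draws
sorted ascending within item. Sorting alone guarantees a valid GRM; no
minimum threshold separation is imposed.

The latent trait $\theta$ is standard normal or, to emulate skewed
constructs such as symptom scales in general-population samples, a Beta
distribution standardized to mean 0 and variance 1:
Beta(1, 4)/Beta(4, 1) give moderate skewness ($\pm 1.05$) and
Beta(0.5, 4)/Beta(4, 0.5) high skewness ($\pm 1.65$). Standardization uses
the analytic Beta moments, not sample moments, so every replication's
population is exactly centered and scaled; skewness is unaffected by the
affine transformation. Thirteen reference/focal distribution pairings are
indexed by `trait_condition()`: normal/normal (condition 13), normal vs
skewed (1–4), same skew in both groups (5–8) and opposing skews (9–12).

Uniform DIF is injected by adding a constant $\Delta \in \{0.25, 0.5, 1\}$
(small / medium / severe) to *all* thresholds of the studied item — by
convention item 1 — in the focal group only. Raising thresholds makes the
item harder, so the focal group scores lower on it at equal $\theta$.

## The fitted model and the DIF test

The MIMIC model regresses both the latent trait and the studied item on the
group covariate $x$ (0 = reference, 1 = focal):

$$\theta = \gamma x + \zeta, \qquad
y_i = \tau_i + \lambda_i \theta + \beta\, x\,[i = s] + \varepsilon_i .$$

$\gamma$ absorbs a true group difference in the latent mean; $\beta$, the
direct covariate-to-item path on the studied item $s$, captures a group
difference in the item's difficulty beyond what the trait explains — the
signature of uniform DIF. The two-sided Wald test $z = \hat\beta /
\mathrm{se}(\hat\beta)$ at $\alpha = 0.05$ is the detection rule. Because
the injected shift raises focal thresholds, $\hat\beta$ is negative in
expectation under DIF.

Estimation is normal-theory maximum likelihood on the item scores treated
as numeric values $1..J$ — the estimator contrasted in this literature with
categorical-data weighted least squares, and the reason results at 3
response categories differ from those at 7. The fit minimizes

$$F_{\mathrm{ML}} = \log|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - p
+ (\bar m - \mu)^\top \Sigma^{-1} (\bar m - \mu)$$

over the free parameters, where $S, \bar m$ are the sample moments of the
joint vector (items, covariate) and $\Sigma, \mu$ the model-implied ones;
$(N-1)F_{\mathrm{ML}}$ is the model chi-square. The optimizer is written in
the package itself (`fit_mimic()`), with analytic gradients verified
against finite differences in the test suite.

### Identification and numerical choices

* **Identification.** The lowest-indexed non-studied item is the marker:
  its loading is fixed at 1 and the latent residual variance is free; the
  latent intercept is 0. The covariate is exogenous with mean and variance
  fixed at their sample values (the "fixed-x" convention of mainstream SEM
  software). The Wald test of $\beta$ — a coefficient in the observed-item
  metric — is invariant to these conventions; exact chi-square/df values
  are not, and the package counts df over the item mean-and-covariance
  structure conditional on the covariate:
  $k + k(k+1)/2 + k - (3k + 2)$, i.e. 8 for 5 items and 43 for 10.
* **Search scale.** Residual and latent variances are optimized on the log
  scale, so the implied covariance is positive definite at every iterate
  and no hard bounds are needed. Quasi-Newton search (`nlminb`) runs from a
  deterministic start — unit loadings, intercepts at the item means,
  residual variances at half the item variances, $\gamma = \beta = 0$ —
  with an iteration cap of 500 and a gradient sup-norm tolerance of 1e-6
  (with up to two restarts from the incumbent). Identical data therefore
  give bit-identical fits.
* **Improper solutions.** Classical Heywood cases (negative variance
  estimates) appear on the log scale as variances pinned at the zero
  boundary; any variance below 1e-8 flags `heywood`. Such fits, and
  non-converged ones, are never errors — the flags ride along in the
  decision record, and the replication engine redraws the dataset (up to 5
  child seeds) before dropping the replication.
* **Standard errors.** Inverse expected (Fisher) information at the
  optimum, scaled by $N - 1$, with an observed-information fallback if the
  expected information is singular. On correctly specified (linear
  structural) data the reported `se_beta` tracks the empirical sampling
  standard deviation within a few percent; the suite enforces 10%.

## The Monte-Carlo engine

A scenario is one cell of the factorial design: sample-size ratio
(R100/F100 … R500/F100), DIF magnitude, scale length (5 or 10 items),
response categories (3, 5, 7) and distribution condition (1–13); the full
crossing is 780 cells. Each cell's seed is derived by hashing its factor
levels with the base seed, and each replication takes its own child seed
from the cell's stream, so any subset — a single replication, one cell, a
parallel run — reproduces the full run exactly.

Per replication, `run_scenario()` generates a dataset, tests the studied
item (power) and, if requested, every DIF-free item (Type I error), each
time refitting the MIMIC model with that item as studied and the rest as
anchors. Power and Type I error are proportions of rejections over
converged replications.

### Where Type I error comes from

Measuring the false-positive rate requires items that truly satisfy the
null. Testing the DIF-free items *inside* a DIF dataset does not deliver
that: the shifted item then sits among the anchors, its group effect leaks
into $\hat\gamma$ and from there into the other items' direct paths, and
the false-positive rate grows with the DIF magnitude — for a 5-item scale
the inflation at severe DIF is far from mild. That anchor-contamination
effect is worth studying in its own right and stays available as
`alpha_source = "same_dataset"`. Published Type-I-error rates for this
design hover near the nominal level at *both* magnitudes, which is only
consistent with null data. The default `alpha_source = "matched_null"`
therefore tests the DIF-free items in a companion dataset drawn from the
same child seed with the shift set to zero: common random numbers give it
the same item bank and latent traits as the power dataset, and every item
in it genuinely satisfies the null. With 10 items the two conventions
nearly coincide (one contaminated anchor among nine dilutes away).

### Fresh versus fixed item banks

Redrawing the item bank every replication makes each cell's power a
*bank-averaged* quantity — the property of the design, not of one
parameter draw. The alternative (one bank per cell, available via the
`bank` argument of `generate_dataset()`) leaves bank-level noise in every
cell: across random banks the per-bank power of a mid-range cell spreads
over several percentage points. Published per-cell values from any single
simulation run should therefore be read with that extra uncertainty in
mind when comparing against bank-averaged estimates.

## What the generator does and does not emulate

It emulates: polytomous Likert responses driven by one latent construct,
realistic discrimination (1.5–2), random item difficulty, small focal
groups, skewed latent traits, and a single uniform-DIF item. It does not
emulate: nonuniform DIF (group-by-trait interactions), multiple DIF items,
more than two groups, missing data, local dependence between items,
multidimensional constructs, or real-world violations of the GRM itself.
Passing tests certify the statistical machinery under the stated
generating model; they do not certify that any real questionnaire behaves
like that model.

## Problem sizes used in the checks

The package's own acceptance checks rerun selected cells at 500
replications (the aggregate over the 60 normal-trait cells at 150 each)
rather than 1000, with tolerances matched to the Monte-Carlo standard
errors of the reference values: ±0.05 for mid-range rates and ±0.02 for
rates within a couple of points of 0 or 1. The standalone
`scripts/acceptance.R` uses 1000–3000 replications per cell. Convergence
at these sample sizes is essentially complete (the suite requires ≥ 98%).

## Known limitations

* Treating 3-category scores as continuous is a deliberate replication of
  the maximum-likelihood convention under study, not a recommendation;
  with very coarse or very skewed items a categorical estimator is the
  methodologically safer choice.
* The Wald test relies on asymptotic normality of $\hat\beta$; at
  R100/F100 with 3 categories the normal approximation, not only the
  effect size, limits power.
* Fit indices (RMSEA, RMR, TLI, CFI, GFI) are averaged over replications
  of the studied-item fit only, as scenario-level summaries.
* The one-at-a-time testing procedure assumes the anchors are DIF-free;
  iterative anchor purification is out of scope.
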