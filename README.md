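# mimicsim

Monte-Carlo evaluation of the MIMIC (multiple indicators multiple causes)
structural equation model as a detector of **uniform differential item
functioning (DIF)** in polytomous questionnaire items — aimed at
psychometricians and biostatisticians who need to know how far the method
can be trusted when the focal (clinical) group is small and the latent
construct is skewed.

## The model in brief

Ordinal item responses are generated from the graded response model: for
item *i* with discrimination *a<sub>i</sub>* ~ U(1.5, 2) and sorted
standard-normal thresholds *b<sub>ij</sub>*,

> P(Y<sub>i</sub> ≥ j + 1 | θ) = exp(a<sub>i</sub>(θ − b<sub>ij</sub>)) / (1 + exp(a<sub>i</sub>(θ − b<sub>ij</sub>))),

with latent trait θ either N(0, 1) or a Beta distribution standardized to
mean 0 and variance 1 (moderate or high skew). Uniform DIF adds a constant
Δ ∈ {0.25, 0.5, 1} to all thresholds of the studied item in the focal group
only.

The detector is the MIMIC model, fitted by maximum likelihood on the
numeric item scores with the package's own covariance-structure optimizer:

> θ = γx + ζ,  y<sub>i</sub> = τ<sub>i</sub> + λ<sub>i</sub>θ + βx·[i = s] + ε<sub>i</sub>,

where x is the 0/1 group covariate. γ captures a latent mean difference;
the direct path β on the studied item *s* captures uniform DIF, tested with
the two-sided Wald statistic z = β̂/se(β̂) at α = 0.05. Power is the
rejection rate on the DIF item, Type I error the rejection rate on DIF-free
items measured in matched null data, both over replications of a factorial
design (sample-size ratio × DIF magnitude × scale length × response
categories × 13 trait-distribution conditions = 780 cells).

## Worked example

Simulate one design cell — 300 reference vs 100 focal subjects, medium DIF
(Δ = 0.5) on item 1 of a 5-item, 3-category scale, reference trait normal
and focal trait highly skewed (condition 2) — then test every item:

```r
library(mimicsim)
scn <- scenario(n_ref = 300, n_focal = 100, delta = 0.5, n_items = 5,
                n_categories = 3, condition_id = 2, seed = 2026)
d <- generate_dataset(scn)
fit_mimic(d)
#> MIMIC fit (N = 400, studied item 1, marker item 2)
#>   converged: TRUE   heywood: FALSE
#>   beta (DIF path)  =  -0.1738  (se 0.0666)
#>   gamma (trait)    =  -0.0232  (se 0.0310)
#>   chi-square = 6.339 on 8 df (F_ML = 0.01589)
#>   RMSEA 0.000  RMR 0.008  TLI 1.000  CFI 1.000  GFI 0.995

evaluate_dataset(d, alpha = 0.05)
#>   item    beta_hat          z     p_value rejected converged heywood
#> 1    1 -0.17378622 -2.6075516 0.009119233     TRUE      TRUE   FALSE
#> 2    2  0.03572455  0.7809435 0.434835753    FALSE      TRUE   FALSE
#> 3    3 -0.02022052 -0.3026404 0.762163929    FALSE      TRUE   FALSE
#> 4    4  0.18108451  1.9430277 0.052012817    FALSE      TRUE   FALSE
#> 5    5  0.03731024  0.6471140 0.517558149    FALSE      TRUE   FALSE
```

The negative β̂ on item 1 (thresholds were raised for the focal group, so
its scores drop at equal θ) is significant — correctly flagged — while the
four DIF-free items are not. Replicating the cell estimates its operating
characteristics:

```r
run_scenario(scn, n_reps = 200)
#> scenario: R300/F100, delta = 0.5, 5 items, 3 categories, condition 2 (high), seed 2026
#>   replications: 200 requested, 200 converged (1 retries)
#>   power = 0.775   type I error = 0.075
```

So at this sample size the test finds medium DIF about three times in four,
with a false-positive rate a couple of points above the nominal 0.05 —
the price of the opposing-skew trait distributions. Whole factorial grids
run via `run_grid(config_scenarios(load_config("paper_grid")), ...)` or the
CLI, and `aggregate_contrast()` summarizes power and Type I error along any
design factor.

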