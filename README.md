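# coraldemog

Size-structured demography and transient dynamics of coral assemblages.

Coral populations rarely sit at their stationary size structure: storms,
bleaching, and fragmentation keep displacing them, so their short-term
behaviour can differ sharply from what the long-term growth rate suggests.
`coraldemog` is an R package for quantifying both sides of that picture
from tagged-colony survey data. It fits size-dependent vital rates,
assembles fragmentation-inclusive integral projection models (IPMs),
computes long-term and transient demographic metrics with jackknife
uncertainty, characterizes local thermal regimes from monthly sea surface
temperature series, and relates demography to environment across
assemblages.

## The model

A colony's state is its log surface area z. The population projects over
annual steps through a kernel K = P + F discretized by the midpoint rule
(default 200 x 200 cells):

    P(z'|z) = (1 - kappa(z)) sigma(z) gamma(z'|z) + kappa(z) kappa_b(z) kappa_z0(z'|z)
    F(z'|z) = phi(z) phi_s C0(z')

with sigma logistic survival, gamma Gaussian growth/shrinkage, kappa the
fragmentation probability, kappa_b the (zero-truncated) remnant count,
kappa_z0 the remnant-size density, phi larval output, phi_s a scalar
settlement probability, and C0 the recruit-size density.

From the discretized kernel the package computes:

* **lambda** — asymptotic growth rate (dominant eigenvalue);
* **R0, T** — net reproductive rate (spectral radius of `F(I - P)^-1`)
  and generation time `T = log R0 / log lambda`;
* **damping ratio** `rho = lambda1 / |lambda2|` — speed of convergence
  back to the asymptotic trajectory;
* **maximal amplification** — the largest lambda-discounted density
  reachable from any stage-biased initial structure;
* **Kreiss bounds** of amplification and attenuation (resolvent-based),
  whose difference is the **transient envelope (TE)**.

Uncertainty comes from jackknife resampling (95% colony subsamples,
settlement varied within observed yearly limits), with the
normality transforms used downstream (log T, rho^-2, TE^-0.1, and
amplification^-0.5, the demographic stability index DSI). The
comparative layer provides two-block NIPALS PLS regression, ranged major
axis Type 2 regression, and three-way factorial ANOVA (Type II) with
Tukey contrasts. A synthetic-data module generates survey, recruitment,
fecundity, and 1/f^|beta| SST datasets with exactly this statistical
structure, so the entire analysis is testable offline.

## Worked example

```r
library(coraldemog)

pr  <- assemblage_presets(n_colonies = 1000, n_years = 4)[["AT.competitive"]]
sim <- simulate_survey(pr, seed = 42)
fec <- simulate_fecundity(pr, n_records = 300, seed = 43)

vr   <- fit_vital_rates(sim$survey, sim$recruits, fec)
kern <- build_kernel(vr, m = 200)
demographic_metrics(kern)
#> Demographic metrics
#>   lambda              : 1.00946
#>   damping ratio       : 1.4252
#>   R0 / generation time: 1.17339 / 16.9858 years
#>   max amplification   : 165.318
#>   Kreiss bounds       : [0.00212054, 94.8449]  TE = 94.8428
```

Read: this simulated tropical competitive assemblage is essentially
stationary in the long run (lambda ~ 1.01, R0 ~ 1.17, one generation ~
17 years), but a structure-biasing disturbance could leave its density
up to ~95x above — or almost arbitrarily far below — the asymptotic
trajectory before transients dissipate: long-term performance says
little about short-term potential.

A full 12-assemblage study (simulate, fit, kernels, metrics, jackknife,
SST metrics, PLSR/RMA/ANOVA, hashed run manifest) is one call:

```r
run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

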