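# tempburden

Temperature-attributable mortality and its future burden under climate
scenarios, for epidemiologists studying heat- and cold-related deaths
(here motivated by neurodegenerative-disease mortality).

The package implements a two-stage pipeline:

**Stage 1 — association.** The nonlinear, lagged temperature–death
relationship is modelled with a distributed lag non-linear model (DLNM):
a cross-basis pairing a natural cubic spline in daily mean temperature
(knots at the 10th/75th/90th percentiles) with a natural cubic spline
over lags 0–14 days (knots log-spaced), adjusted for holidays and
relative humidity (natural spline, 3 df). The coefficients are estimated
by conditional logistic regression in an individual-level,
time-stratified case-crossover design: each death is compared with the
same weekdays of its own calendar month, so

> ℓ(θ) = Σ_strata [ x_case·θ − log Σ_{j∈stratum} exp(x_j·θ) ]

is maximised by Newton–Raphson. The fitted surface is reduced over the
lag dimension to the overall cumulative exposure–response curve f\*(T),
whose minimum is the minimum-mortality temperature T_mm; relative risks
are reported at the 2.5th/97.5th temperature percentiles versus T_mm.

**Stage 2 — projection.** Daily GCM temperature series per emissions
scenario (SSP126/SSP245/SSP585) are bias-corrected against observations
by monthly additive quantile mapping (trend-preserving). Each projected
day contributes attributable deaths

> D_attr = D · (1 − e^{−(f\*(T) − f\*(T_mm))}),

summed into heat (T > T_mm) and cold (T < T_mm) components by decade and
scenario as GCM-ensemble averages, expressed as attributable fractions
(AF), and compared with the 1980–2009 historical baseline. Uncertainty is
propagated by Monte Carlo: coefficients are redrawn from their sampling
distribution and empirical 95% confidence intervals (eCIs) are taken
from the pooled draw × GCM distribution.

A synthetic-data module generates all inputs — seasonal AR(1) weather,
death records whose daily hazard follows a known exposure–lag–response
surface, and biased, warming GCM ensembles — so the whole pipeline runs
and is validated at desk scale with no external data.

## Worked example

```r
library(tempburden)

cfg <- run_config(out_dir = "demo", seed = 1, baseline_rate = 3,
                  n_sim = 200, n_gcms = 5)
simulate_inputs(cfg)           # writes weather.csv, deaths.csv, scenarios.csv
assoc <- run_association(cfg)  # strata -> conditional logistic fit -> curve
assoc$rr_table
```

```
#>   cause             region  n_deaths  mmt p2.5_temp rr_p2.5 rr_p2.5_low rr_p2.5_high p97.5_temp rr_p97.5 rr_p97.5_low rr_p97.5_high
#> 1 neurodegenerative region1     9652 20.3     0.642    2.34        1.81         3.02       28.2     1.29         1.04          1.60
```

About 9,700 synthetic deaths over 2013–2019 yield a cumulative relative
risk of 2.34 (95% CI 1.81–3.02) at the 2.5th temperature percentile
(0.6 °C) and 1.29 (1.04–1.60) at the 97.5th percentile (28.2 °C),
relative to a minimum-mortality temperature of 20.3 °C — the generator's
truth is RR 2.0 / 1.3 with the reference at the 75th percentile
(21.0 °C), so the fit recovers the built-in surface within its
confidence limits. Then:

```r
proj <- run_projection(cfg, assoc)   # bias correction -> decade burden -> eCIs
subset(proj$differences, decade == "2090s" & scenario == "SSP585")
```

```
#>   scenario decade component  d_an d_af_pct eci_low eci_high af_eci_low af_eci_high
#> 1 SSP585   2090s  cold      -1380   -10.01   -1657    -1007     -12.01       -7.30
#> 2 SSP585   2090s  heat        954     6.92     132     1428       0.95       10.36
#> 3 SSP585   2090s  net        -427    -3.09   -1175      185      -8.52        1.35
```

Under the unrestricted-emission scenario the 2090s heat-related AF rises
by ~6.9 percentage points (eCI 1.0–10.4) while the cold-related AF falls
by ~10; with this cold-dominant synthetic curve the net change stays
negative (the vignette discusses when the net turns positive).
`autoplot(assoc$curve)` draws the exposure–response curve,
`autoplot(proj)` the AF trajectories.

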