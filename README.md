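# gwcommute

Spatially varying regression for active-commuting epidemiology.

Urban health studies routinely ask whether the built environment — density,
cycling infrastructure, transit access, neighbourhood socio-economics —
shapes how much people walk or cycle to work. A single city-wide regression
answers that question *on average*; it cannot show that bikeability matters
in the dense core but not in the periphery. `gwcommute` is for
epidemiologists and health-geography researchers who want to test and map
that **spatial non-stationarity** with a Poisson outcome model, starting
from a participant table with projected residential coordinates.

## The model

Weekly active-commuting hours are rounded to the nearest half hour and
modelled as a count of half-hour units. The core model is a
**semiparametric geographically weighted Poisson regression (GWPR)**:

    log λ_i = Σ_k β_k(u_i, v_i) · x_ik  +  Σ_m γ_m · x_im

where `(u_i, v_i)` are the residential coordinates of subject *i*, the
environmental coefficients `β_k(·)` (and the intercept) vary smoothly over
space, and the individual-level coefficients `γ_m` (age, gender, education,
transit pass, workplace parking, commuting-time tertile, vehicle and bike
counts) are spatially constant. Local coefficients at each location are
estimated by maximising a geographically weighted log-likelihood, with
observation weights from an **adaptive bi-square kernel** (bandwidth = the
distance to the N-th nearest neighbour; Gaussian and fixed-bandwidth
kernels are also available). The fixed and local parts are reconciled by
back-fitting. Model complexity is the **effective number of parameters**
`k = trace(S) + p_global` (S the local hat matrix), the selection criterion
is `AICc = D + 2k` minimised over a descending neighbour-count grid, and
competing models are compared by the MAICE rule (ΔAICc > 2 is substantial).
Per-location significance is a **pseudo-t** (`β/se`, sandwich standard
errors), mapped via inverse-distance-weighted surfaces.

Around the core model the package provides the exposure-construction
toolkit such analyses need — varimax-rotated PCA composites with Kaiser
retention and KMO/Bartlett diagnostics, a perceived-environment index from
Likert items, quartic kernel density rasters, zone-to-grid disaggregation,
500-m buffer means, nearest-station distances — and a synthetic cohort
generator with known true coefficient surfaces, so every stage of the
pipeline is testable without any cohort download.

## Worked example

Simulate a 500-participant cohort whose `env1` coefficient rises linearly
from west (−0.25) to east (+0.35), fit the global model, select the
bandwidth, and compare:

```r
library(gwcommute)
library(dplyr)

coh <- simulate_cohort(scenario_g1(n = 500, seed = 42))
d   <- coh$participants

indiv <- c("age_c10", "gender_female", "educ_high", "parking_work",
           "transit_pass", "commute_tertile", "n_vehicles", "n_bikes")

gpr <- fit_poisson_glm(d, "counts", c("env1", "env2", indiv))
glance(gpr)
#>   deviance deviance_explained  aicc nagelkerke_r2     k     n
#> 1     537.              0.273  559.         0.338    11   500

bs <- bandwidth_search(d, "counts", c("env1", "env2"), indiv,
                       grid = c(100, 200, 400))
bs
#> <bandwidth search> 3 candidates, selected N = 400 (AICc 547.3)

compare_models(gpr, bs$fit, "GPR", "GWPR")
#>   aicc_a aicc_b delta_aicc substantial preferred
#> 1   559.   547.       11.7 TRUE        GWPR

summarize_local(bs$fit)
#>   term        mean_log_odds sd_log_odds mean_or min_or max_or range_or
#> 1 (Intercept)         0.962       0.067    2.62  2.17    2.92    0.745
#> 2 env1                0.048       0.066    1.05  0.918   1.18    0.266
#> 3 env2                0.018       0.047    1.02  0.928   1.18    0.253
```

Read: the global model explains 27% of deviance, but letting the
environmental coefficients vary spatially drops AICc by 11.7 — substantial
under the MAICE rule — and the `env1` odds ratio, 1.05 on average (matching
the global fit), actually ranges from 0.92 to 1.18 across the study region:
the association exists in some neighbourhoods and not in others.
`pseudo_t(bs$fit)` flags where |t| > 1.96, `autoplot(bs$fit, "env1")` maps
the surface, and `run_pipeline()`/`export_results()` run the whole chain
(composites → global fit → bandwidth search → GWPR → MAICE → IDW surfaces)
and write CSV/GeoJSON/ESRI-ASCII/JSON outputs.

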