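# icarsurv

Bayesian spatial survival analysis of under-five child mortality across
administrative areas, in the style of county-level analyses of the Kenya
Demographic and Health Survey: a proportional-hazards model with a
piecewise-constant baseline hazard and intrinsic conditional autoregressive
(ICAR) areal frailties, fitted by Metropolis-within-Gibbs MCMC and compared
against the no-frailty Cox model with DIC, WAIC and LPML.

## Who it is for

Epidemiologists and biostatisticians who want to quantify *where* child
mortality risk clusters after adjusting for child, maternal and household
covariates — and to test whether that spatial structure is worth modelling
at all. The real DHS microdata is registration-gated, so the package also
ships a synthetic-data generator that emulates the survey's child-survival
structure (47 counties, 0–60 month follow-up, heavy right censoring, the
canonical covariate set) with recorded ground truth, making every part of
the pipeline testable offline.

## The model

For child `i` in area `a(i)`, with follow-up `t_i` months and death
indicator `d_i`:

    h_i(t) = h0(t) * exp(x_i' beta + w_{a(i)})

with `h0` piecewise-constant, so each record's log-likelihood contribution
is `d_i (log h0(t_i) + x_i' beta + w_{a(i)}) - H0(t_i) exp(x_i' beta +
w_{a(i)})`. The frailties carry the intrinsic CAR prior

    p(w | s2)  ∝  s2^(-r/2) exp( - Σ_{i~j} (w_i - w_j)^2 / (2 s2) )

over the county adjacency graph (`r` = areas − connected components),
identified by a sum-to-zero constraint; `s2` gets an Inverse-Gamma prior
with a conjugate Gibbs update. DIC/WAIC/LPML compare the spatial model with
the plain no-frailty model; Cox–Snell residuals (cumulative hazard of the
residuals approximately straight with slope one) check fit.

## Worked example

```r
library(icarsurv)

## a synthetic 20-county dataset with true ICAR frailty variance 0.2
ds <- generate_dataset(sim_config(n_areas = 20, children_per_area = 75,
                                  seed = 5))
design <- build_design(ds$records)
cfg <- mcmc_config(n_iterations = 6000, burn_in = 2000, thinning = 4,
                   seed = 99)

spatial    <- sample_posterior(ds$records, design, ds$graph, config = cfg)
no_frailty <- sample_posterior(ds$records, design, NULL,     config = cfg)

compare_models(no_frailty, spatial)
#>                                       model      dic      lpml     waic
#> 1     Cox Proportional Hazards (No Frailty) 1547.409 -775.5605 1550.243
#> 2 Proportional Hazard Spatial Frailty Model 1540.427 -771.9226 1543.389

posterior_summary(spatial, "sigma2")
#>   parameter      mean    median        sd       lower     upper
#> 1    sigma2 0.2253378 0.1689925 0.2061031 0.008415377 0.7863695
```

The spatial model wins on all three criteria (lower DIC and WAIC, higher
LPML), and the frailty-variance posterior centres near the generating value
0.2. Hazard ratios come from exponentiated coefficient summaries — here
applied to the published posterior means of the Kenyan analysis:

```r
hazard_ratio_report(u5cm_reference_summary())[c(1, 3, 14), c(2, 6:9)]
#>                             label hazard_ratio hr_lower hr_upper percent_change
#> 1       Sex of the child (Female)       0.8777   0.7761   0.9921          12.23
#> 3  Sex of household head (Female)       0.8564   0.7548   0.9842          14.36
#> 14   Child is twin (2nd Multiple)       1.5586   1.0998   2.1351          55.86
```

i.e. girls face a 12.23% lower hazard than boys, children in female-headed
households a 14.36% lower hazard, and a second-born twin a 55.86% higher
hazard. Per-county posterior median frailties export with
`frailty_map_export()` (optionally into a GeoJSON choropleth), and
`run_pipeline()` wraps simulate → fit both models → compare → diagnose →
report into one artifact directory.

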