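# fireconn

Fires have become rare in the boreal forests of northern Europe, and the
insects that depend on them — pyrophilic, fire-favoured species — are
increasingly managed with prescribed conservation burns. Placing those
burns well requires knowing *at what distances and time lags* past fires
still feed a local pyrophilic community. `fireconn` is an R package for
answering that question from two routine data sources: a fire-history
register (coordinates, burned area, year for every recorded fire) and
per-site catch tables from insect sampling (how many of the caught
individuals and species belong to the fire-favoured group).

## The statistic and the model

For sampling site *i*, spatiotemporal connectivity to past fires is

```
ST_i = sum_j exp(-d_ij * alpha_s) * FA_j * exp(-T_j * alpha_t)
```

summed over register fires *j* within 20 km of the site, where `d_ij` is
distance in km, `FA_j = ln(burned area in m²)`, and `T_j` is years since
the fire (≥ 1; only fires before sampling count). It is the classical
incidence-function connectivity of metapopulation ecology with an added
exponential discount in time.

The two decay scales are estimated, not assumed: the response — per-site
ln-odds that a random caught individual (or species) is pyrophilic — is
regressed on standardized `ST` in a normal-family GLM, and `(alpha_s,
alpha_t)` are chosen on a grid over `[0, 4]²` by minimum deviance (the
deviance profile). Control groups expected *not* to respond to fire
history (non-pyrophilic and obligate saproxylic beetles) run through the
identical chain. A built-in simulator generates fire landscapes and
binomial–logit catches with known ground truth, so the whole chain is
validated by parameter recovery rather than by faith.

## Worked example

```r
library(fireconn)

# connectivity of one site to two fires, at decay scales 1.7/km and 1.4/yr
trap  <- data.frame(site_id = "t1", x_m = 0, y_m = 0, sampling_year = 2011)
fires <- data.frame(fire_id = c("f1", "f2"),
                    x_m = c(2000, 9000), y_m = c(0, 3000),
                    area_m2 = c(10000, 250000), year = c(2010, 2008))
connectivity(trap, fires, connectivity_params(alpha_s = 1.7, alpha_t = 1.4))
#>   site_id   st_value n_contributing_fires
#> 1      t1 0.07579879                    2
```

Both fires are within the 20 km radius, but the 2008 fire 9.5 km away is
discounted to practically nothing (`exp(-9.5*1.7) * exp(-3*1.4) ≈ 2e-9`);
almost the entire value comes from the 1-year-old fire 2 km away:
`exp(-3.4) * ln(10000) * exp(-1.4) ≈ 0.0758`.

```r
# simulate a landscape with known truth, then recover the scales
cfg  <- synthetic_config(true_alpha_s = 1, true_alpha_t = 1, beta = 2,
                         n_sites = 60, seed = 42)
sim  <- simulate_dataset(cfg)
resp <- build_responses(sim$sites, group = "pyrophilic", level = "individuals")
deviance_profile(sim$sites, sim$fires, resp, grid_step = 0.2)
#> deviance profile on [0, 4]^2, step 0.2 (441 grid points)
#>   selected alpha_s = 0.8, alpha_t = 0.8 (deviance 23.51)
#>   slope 1.576 (SE 0.083), p = 1.35e-26
```

The profile lands one grid step from the true `(1, 1)` with a strongly
positive standardized slope — at 60 sites a single replicate recovers the
scales approximately; the replicated validation below quantifies how well.

## The analysis workflow

The `analysis/` directory holds thin numbered drivers over the package:

```sh
Rscript analysis/01_simulate.R --seed 1   # synthetic register + catches
Rscript analysis/02_connectivity.R        # per-site ST + weight curves
Rscript analysis/03_fit.R                 # 3 groups x 2 levels, optimized scales
Rscript analysis/04_recover.R             # recovery + calibration summaries
```

Each writes CSV/JSON tables under `results/` (estimates table, long-format
deviance surfaces, weight curves, scatter data, replicate summaries) plus a
`run_info.json` recording package version, seed and resolved
configuration.

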