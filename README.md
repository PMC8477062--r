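# dendrocomp

Dendroecology of even-aged plantation forests: how much of a tree's radial
growth is set by climate, how much by its neighbours, and how does crowding
change its ability to weather droughts?

`dendrocomp` is an R package for forest ecologists working with the three
data sources a typical plantation study yields: a spatially explicit stand
inventory (one snapshot of positions and diameters), dated ring-width
series from increment cores, and monthly records from a nearby climate
station. From those it computes:

* **Competition** - the distance-dependent Hegyi index
  `CI_i = sum_j (D_j/D_i) / d_ij` over neighbours within 8 m, the
  low/medium/high classification (`CI < 1`, `1 <= CI < 3`, `CI >= 3`), and a
  retroactive reconstruction of every tree's annual CI from the cored
  trees' growth-rate series (`GR_k = RI_k / RI_total`), closing exactly on
  the observed inventory in the final year.
* **Chronologies** - basal area increments `BAI_t = pi (r_t^2 - r_(t-1)^2)`,
  regional curve standardization (RCS) detrending, AR-prewhitened residual
  chronologies, and the Rbar / EPS / SNR signal statistics
  (`EPS = n rbar / (n rbar + 1 - rbar)`, `EPS = SNR/(1+SNR)`).
* **Climate** - vapour pressure deficit from T and RH, Thornthwaite
  potential evapotranspiration, the standardized
  precipitation-evapotranspiration index (SPEI) at arbitrary monthly
  scales via a probability-weighted-moment log-logistic fit, a one-per-year
  growing-season (April-October) SPEI, and Mann-Kendall / double-mass
  homogeneity screens for station records.
* **Climate-growth correlations** - monthly Pearson screens over the
  previous-October to current-September window, with significance stars
  and a ranked shortlist of factors.
* **Attribution** - an OLS model of 5-year block means of log BAI on
  climate factors, reconstructed CI and site index, decomposed into
  climate / competition / site shares by exact LMG relative importance.
* **Drought resilience** - severe-drought events (growing-season
  SPEI < -1, events separated by more than 3 years), and the Lloret
  indices resistance `Rt = BAI_D/BAI_pre`, recovery `Rc = BAI_post/BAI_D`,
  resilience `Rs = BAI_post/BAI_pre` and relative resilience
  `RRs = (BAI_post - BAI_D)/BAI_pre`, per tree, with CI-class contrasts
  and CI-resilience correlations.

Because studies of this kind rarely release their field data, the package
ships a synthetic-data generator (`sim_config()`, `simulate_stand()`) that
produces stands, climates and ring series with known ground truth - true
annual CI trajectories and true climate/competition effect sizes - so the
whole pipeline is testable end to end. See the methods vignette
(`vignettes/dendrocomp-methods.Rmd`) for the models, assumptions and
design decisions.

## Worked example

Simulate a medium-density stand with droughts imposed in 1996 and 2008,
then run the main stages:

```r
library(dendrocomp)

cfg <- sim_config(density = 550, n_years = 40, seed = 42,
                  drought_years = list(c(1996, 1, 0.65), c(2008, 1, 0.7)))
sim <- simulate_stand(cfg)

# competition classes of the final inventory
ci <- hegyi_ci(sim$stand)
table(ci$class)
#>    low medium   high
#>      7     42      0

# RCS-detrended, AR-prewhitened residual chronology
idx <- rcs_detrend(sim$rings, planting_year = cfg$planting_year)
for (id in unique(idx$core_id)) {
  sel <- idx$core_id == id
  idx$index[sel] <- ar_prewhiten(idx$index[sel])
}
chron <- build_chronology(idx[!is.na(idx$index), ])
chron
#> Tree-ring chronology: 40 years, mean depth 23.7
#>   Rbar = 0.186, EPS = 0.845, SNR = 5.43

# drought events from the growing-season SPEI
gs <- growing_season_spei(sim$climate, cfg$latitude)
events <- select_drought_events(gs)
events[[4]]
#> Drought event 4: years 2008 (min growing-season SPEI -2.70)

# per-tree Lloret indices and their density dependence
bai <- bai_from_rings(sim$rings)
ind <- stand_resilience(bai, events)
ci_resilience_correlation(ci[c("tree_id", "ci")], ind)
#>    event index            r          p  n
#> ...
#> 10     4    rc -0.371204858 0.07411883 24
#> 12     4   rrs -0.401751531 0.05165578 24
```

The chronology statistics say the 24 cores share a common signal (mean
interseries correlation 0.19); both imposed dry years are picked up as
severe drought events below the -1 threshold (1996 merges with the
following year's carried-over deficit); and for the 2008 event the
recovery and relative resilience of individual trees decline with their
competition index - the density dependence the package is built to
detect, here at single-plot sample size (n = 24 cored trees). The
multi-site experiments `recover_known_effects()` and
`drought_density_experiment()` run the same analyses at study scale.

File-based workflows use `run_pipeline()`, which reads the inventory /
rings / climate files (CSV or Tucson `.rwl`), executes the stages in
dependency order, and writes per-stage CSVs plus a JSON manifest to an
output directory; `validate_inputs()` reports schema and unit violations
(DBH outside 1-150 cm, ring widths outside 0.01-20 mm, RH outside
(0,100], orphan core ids) in one pass.

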