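---
title: "Methods: climate, competition and drought resilience in even-aged pine stands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate, competition and drought resilience in even-aged pine stands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrocomp)
```

`dendrocomp` implements a dendroecological analysis chain for even-aged
plantation forests: from stand inventories, dated ring-width series and
monthly climate records to competition indices and their annual
reconstruction, detrended chronologies, climate-growth correlation screens,
a variance-decomposition attribution of growth to climate, competition and
site condition, and drought resistance/recovery/resilience statistics.
This vignette is the package's account of the underlying models, the
parameters that matter, and the design choices made where the methods
leave room.

## Competition: the Hegyi index and its annual reconstruction

Competition intensity around a subject tree $i$ is the distance-dependent
Hegyi index

$$ CI_i = \sum_{j : d_{ij} \le R} \frac{D_j / D_i}{d_{ij}}, $$

with $D$ the stem diameter at breast height (cm), $d_{ij}$ the stem
distance (m), and a neighbourhood radius $R$ of 8 m. Stands are classed as
low ($CI < 1$), medium ($1 \le CI < 3$) or high ($CI \ge 3$) competition;
both cut-points are half-open on the right, so 1.0 is medium and 3.0 is
high.

Because repeated inventories are rarely available, the annual history of
$CI$ is reconstructed retroactively from a single inventory plus the cored
trees' ring series. Each cored tree's increments are converted to a
growth-rate series $GR_k = RI_k / \sum_k RI_k$; the arithmetic mean of the
cored trees' rates, renormalized to sum to one, is the plot growth rate.
A cored tree's past diameter is then its observed DBH minus twice the
radial increment laid down after year $k$; a non-cored tree's is its
observed DBH times the cumulative plot growth rate. Both paths close
exactly on the observed inventory in the final year, which the tests
assert to machine precision. The working assumptions are the usual ones for
even-aged plantations: the over-bark diameter growth *rate* equals the
under-bark radial growth rate, all trees share the planting year, and no
trees died during the reconstructed period (inputs violating the cohort
assumption are refused).

Three choices were genuinely open:

* **Edge effects.** A 30 × 30 m plot cannot hold an 8-m buffer, so by
  default no correction is applied and trees whose neighbourhood disc
  leaves the plot are flagged `edge`. A linear-expansion correction
  (dividing CI by the fraction of the disc inside the plot) is available
  via `edge_correct = TRUE`; it can only inflate CI and never produces
  negative values.
* **Minimum diameter.** DBH is meaningless before a stem reaches breast
  height, so reconstructed CI is undefined (NA) for years in which the
  subject or any competitor is below 1 cm (`min_dbh`, configurable).
* **Cored neighbours.** Cored neighbours enter the competitor set with
  their own (better-known) back-cast histories by default;
  `include_cored_competitors = FALSE` restricts competitors to the
  rate-path trees.

## Rings: BAI, RCS detrending, and chronology statistics

Tree-level basal area increment is the annulus area
$BAI_t = \pi (r_t^2 - r_{t-1}^2)$ in cm², with the radius accumulated from
the mean of a tree's cores (two cores are averaged into one tree-level
series before conversion, but kept separate for interseries statistics).
The pith offset defaults to zero - plantation cores are assumed to reach
the pith - and is configurable.

Detrending uses regional curve standardization: the mean ring width at
each cambial age (age = calendar year − planting year + 1, valid for
even-aged plantations) is smoothed with a cubic smoothing spline whose
equivalent degrees of freedom are `round(stiffness * n_ages)` with
`stiffness = 0.10` by default, and each width is divided by the curve value
at its age. Ratio indices make the chronology scale-free: multiplying all
widths by any constant leaves the chronology unchanged, a property the
suite checks to 1e-10. Residual chronologies are produced by autoregressive
prewhitening per core, with the order chosen by AIC up to order 3 and
residuals re-centred to mean 1; AIC retains a known null overfit rate of
roughly 25%, so about three quarters of white-noise series are returned
untouched. The yearly chronology value is the arithmetic mean of core
indices (a Tukey biweight robust mean is available behind a flag, but with
9-12 cores per plot the biweight is unstable and is not the default).

Chronology quality uses the classical signal statistics: `rbar` is the
mean pairwise Pearson correlation of cores over their common periods, and
with mean sample depth $n$,

$$ EPS = \frac{n\,\bar r}{n\,\bar r + (1 - \bar r)}, \qquad
   SNR = \frac{n\,\bar r}{1 - \bar r}, \qquad EPS = \frac{SNR}{1 + SNR}. $$

The identity on the right links the two reported thresholds: a minimum SNR
of 17.14 implies a minimum EPS of 0.945.

## Climate: VPD, PET, SPEI and homogeneity screens

Vapour pressure deficit comes from temperature and relative humidity via
the Magnus saturation curve, $VPD = 0.6108\,e^{17.27T/(T+237.3)}(1 -
RH/100)$ kPa. Potential evapotranspiration uses the classical Thornthwaite
formulation (temperature and latitude only), with the annual heat index
computed from the record's climatological monthly normals, mid-month day
lengths from the solar declination, zero PET for freezing months, and the
standard high-temperature polynomial above 26.5 °C. Thornthwaite was chosen
because monthly temperature and latitude are guaranteed to be available at
ordinary climate stations; where wind and pressure exist a Penman-type PET
could be substituted upstream by supplying a `pet_mm` column.

SPEI standardizes the climatic water balance $D = P - PET$ aggregated over
$k$-month backward windows. For each calendar month the windowed sums are
fitted with a three-parameter log-logistic distribution estimated by
unbiased probability-weighted moments; cumulative probabilities map to
standard normal deviates through the exact normal quantile function. The
fit uses the generalized-logistic parameterisation of the family, whose
shape sign follows the sample's L-skewness - this matters because records
containing severe imposed droughts are left-skewed, where the classical
right-skew-only parameterisation has no valid solution. The calibration
period is the full record. Start-up windows (the first $k-1$ months) and
degenerate months (constant balance) are NA, never zero-filled. On long
stationary records the fraction of months below −1 is close to
$\Phi(-1) \approx 0.159$ and each calendar month's mean SPEI is close to
zero; the acceptance suite checks both on a 500-year synthetic record.

The growing season is April-October (seven months). The growing-season
SPEI is computed once per year by fitting the distribution to the yearly
April-October sums themselves, so each year contributes exactly one value
and perturbing months outside the window cannot change it.

Two homogeneity screens are provided for station records: a Mann-Kendall
trend test (tie-corrected variance, continuity-corrected normal deviate)
whose null rejection rate the suite calibrates against its nominal 5%
level, and a double-mass screen that fits a two-segment line to the
cumulative candidate-versus-reference curve and flags breaks when the
segment slopes differ by more than 10% (configurable).

## Climate-growth screen

Monthly predictors are lag-aligned to ring years over the standard
dendroclimatic window from the previous October to the current September;
because late-season effects are sometimes reported through the current
October, the window end is configurable (`window_end = "C_Oct"` gives the
13-month table). Each cell is a Pearson correlation with the residual
chronology with an exact t-distribution p-value. **No multiple-testing
correction is applied by default**: the table reproduces the per-cell
starred-heatmap convention, so among null cells about 5% will be starred
by chance. The most significant factors (default: the top 4 by |r| among
cells with p < 0.05, ties broken by window order) feed the attribution
stage.

## Attribution: block-averaged growth model and LMG shares

Because climate fluctuates annually while competition and site quality
evolve slowly, the modelling works on non-overlapping 5-year block means
(a trailing block is kept only if it covers at least 3 years). The model
is ordinary least squares of log BAI on the selected climate factors, the
reconstructed (modelled) CI and the site index - dominant height at a base
age of 40, treated as an input covariate. Tree age is deliberately not a
predictor. "Mixed model" wording in this literature notwithstanding, no
random effects are specified anywhere in the procedure, so the default is
plain OLS on blocks; the design condition number is reported and exact
collinearity raises an error naming the aliased columns.

Relative importance uses the LMG metric: a predictor group's share is its
incremental $R^2$ averaged over all orderings in which the groups can
enter the model. With the three-way grouping (all climate factors as one
group, CI, site index) the enumeration over $2^3$ subsets is exact, and
shares sum to the model $R^2$ to 1e-10. Shares are reported both as
percent of the explained variance (the default display) and as percent of
total variance, because published percentages are ambiguous between the
two. Under an orthogonal design the shares reduce to marginal $r^2$
proportions, which the suite verifies in closed form.

## Drought events and Lloret resilience indices

A year is a severe drought year when its growing-season SPEI is below −1.
Consecutive drought years form runs, and two runs separated by three or
fewer calendar years merge into a single multi-year event - drought legacy
effects last one to two years, so nearby dry years are one physiological
event, and distinct events must be more than 3 years apart. The rule is
exact: the suite checks every boolean drought pattern of length 12 against
an independent transitive-closure grouping.

For an event, with $BAI_D$ the mean BAI over the event years and
$BAI_{pre}$, $BAI_{post}$ the means over the three years immediately
before and after:

$$ Rt = \frac{BAI_D}{BAI_{pre}}, \quad Rc = \frac{BAI_{post}}{BAI_D},
   \quad Rs = \frac{BAI_{post}}{BAI_{pre}}, \quad
   RRs = \frac{BAI_{post} - BAI_D}{BAI_{pre}}, $$

linked by $RRs = Rs - Rt$ and $Rs = Rt \cdot Rc$, asserted to 1e-12 on
every computed record. Indices are computed per tree on raw (unsmoothed)
tree-level BAI; the 3-year moving average (centred, partial 2-year means
flagged at the endpoints) is a display and event-inspection aid, and a
`smoothed = TRUE` switch uses it inside the windows instead. When another
event's years intrude into a pre/post window the window shifts to the
nearest three clean years within five years, otherwise the index is
reported NA rather than silently contaminated. Multi-year events average
all event years in $BAI_D$, not the worst year.

Group contrasts between CI classes use pairwise Welch t-tests, which
stand in for ANOVA-based post-hoc procedures and are labelled as such in
the output metadata. Density dependence is tested by correlating the
per-tree modelled CI with each index per event, pooling trees across
classes.

## The synthetic-data generator

No field data ship with the package, so every stage is exercised against a
generator with known ground truth. It emulates the sampling design the
pipeline targets: 30 × 30 m even-aged plots at three density classes
(roughly 250, 550 and 900 trees/ha), planted around 1975 and grown for
about 40 years, under a continental monsoon climate with a July-August
precipitation peak and annual totals near 400 mm.

* **Climate** (`sim_climate`): monthly temperature is a seasonal sinusoid
  plus optional trend and noise; precipitation is gamma-distributed with
  the summer peak; relative humidity is a bounded seasonal base. Imposed
  droughts scale a year's precipitation down by a severity fraction chosen
  so the growing-season SPEI of that year falls below −1 when computed by
  the climate module (a severity of 0.6-0.7 lands near −2).
* **Stand** (`sim_stand`): `floor(area × density)` trees on a jittered
  lattice (which guarantees distinct positions), a configurable cored
  fraction, and a shared planting year.
* **Growth** (`sim_growth`): ring width follows
  $w_t = A(\text{age}) \exp(\beta z_t - \gamma CI_t - \lambda CI_t
  L_t + \varepsilon)$, with $A$ a negative-exponential age trend
  ($5.5 e^{-\text{age}/15} + 0.8$ mm, giving ~20 cm DBH at age 40),
  $z_t$ the growing-season water-balance z-score computed from the
  generated climate's own climatology, $CI_t$ the true Hegyi index
  evaluated from the simulated diameters year by year (diameters start at
  a 0.5 cm seedling caliper and accumulate two radial widths per year,
  exactly), and $\varepsilon$ lognormal noise. Noise streams are split per
  tree and substage, so adding trees never perturbs existing ones, and the
  tail is winsorized at 2.5 sigma with an 18 mm ceiling so no physically
  impossible rings occur. $L_t$ is a drought-legacy indicator: in the one
  to two years after any year whose moisture z-score fell below −1, growth
  pays an extra penalty proportional to CI. This interaction is the
  generator's mechanism for density-dependent drought vulnerability:
  resistance is unaffected by competition (the event-year response is
  CI-independent in relative terms) while recovery, resilience and
  relative resilience decline with CI. A purely additive log-linear model
  without the interaction makes the Lloret ratios competition-invariant by
  construction, so it cannot express the density dependence the package is
  designed to detect - this is worth remembering when interpreting what
  passing tests show.

Default effect sizes were fixed once from the field picture the pipeline
targets: `sigma_noise = 0.5` gives interseries correlations (Rbar) in the
realistic 0.14-0.23 range; `beta_climate = 0.25` versus
`gamma_competition = 0.05` makes climate the dominant driver, as reported
for shelterbelt pines, while still separating density classes in late-life
BAI; `lambda_legacy = 0.10` over 2 legacy years yields recovery losses of
the order of tens of percent between low- and high-CI stands.

The parameter-recovery experiments (`recover_known_effects`,
`drought_density_experiment`) simulate six sites × three densities
(attribution) and two sites × three densities (resilience), 40 years, with
droughts imposed in 1996, 2008 and 2014. The attribution experiment uses
`beta_climate = 0.30`, `gamma_competition = 0.02` - the climate-dominance
condition $\beta > \gamma\,\mathrm{sd}(CI)$ with a wide margin, because
log BAI integrates the competition penalty through both the ring width and
the accumulated radius, roughly doubling the effective competition
coefficient relative to $\gamma$.

What the generator does **not** emulate: mortality, regeneration or
thinning; height growth beyond a static allometry; spatial autocorrelation
of microsites; measurement error and dating error in cores; multi-decadal
climate oscillations. Passing tests therefore show that the estimators
recover known effects under a well-specified data-generating process, not
that the pipeline is robust to every pathology of real field data.

## Numerical choices and degenerate inputs

* Probability-weighted moments use the unbiased estimators on order
  statistics; tied values contribute identically whatever their sort
  order. Fitted cumulative probabilities are clamped to
  $[10^{-8}, 1 - 10^{-8}]$ so the normal quantile stays finite.
* Coincident tree positions are an input error everywhere (distance zero
  would make the Hegyi sum infinite); ties in competitor distance need no
  tie-break because contributions are summed.
* Zero-variance predictors in the correlation screen are flagged
  `zero_var` with NA correlation rather than dropped silently.
* `ar_prewhiten` falls back to order 0 (series unchanged) when the AR fit
  fails; constant series pass through unchanged.
* The regional curve is floored at a small positive width before division.
* All problem sizes used in the test and acceptance suites (200 random
  stands up to n = 200; a 500-year climate; 50-seed recovery experiments
  on 6 × 3 and 2 × 3 stand designs) were chosen as the smallest sizes at
  which the distributional checks are stable.

## Known limitations

* Cross-dating quality control is out of scope: ring series are trusted as
  dated.
* The site-index model behind the dominant-height covariate is not
  reimplemented; site index is an input column (synthetic fixtures derive
  it from a Richards-type height-age relation).
* The reconstruction shares one growth-rate series per plot; strongly
  heterogeneous growth within a plot degrades non-cored back-casts (the
  simulator experiments put the median CI reconstruction error near 1-2%,
  well under the 10% working tolerance, but real stands with mortality
  would do worse).
* LMG enumeration is exact only up to 10 groups; more groups are refused
  rather than silently sampled.
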