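---
title: "Methods: smoke exposure and lake chlorophyll-a phenology residuals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smoke exposure and lake chlorophyll-a phenology residuals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakesmoke)
```

## The question and the data

Wildfire smoke carries nutrient-rich particles and ash far downwind of the
burned area and can deposit them onto lake surfaces; it also alters the
radiation reaching the water. Either mechanism could stimulate algal growth.
`lakesmoke` asks whether weeks in which a smoke plume sat over a lake show
elevated surface chlorophyll-a — the standard satellite proxy for algal
biomass — once each lake's own seasonal bloom cycle is accounted for, and
whether any elevation scales with smoke density, lake elevation, and trophic
status.

Two remote-sensing products drive the analysis:

* weekly lake-level surface chlorophyll-a composites (µg/L), derived from a
  satellite cyanobacteria index via the power-law calibration
  `chla = scale * CI^exponent` (defaults follow the published CyAN
  calibration, Tomlinson et al. 2016; Coffer et al. 2020). Each weekly value
  is the area-normalized mean over the lake's resolved pixels, and values at
  the method detection limit (MDL) are left-censored;
* daily smoke-plume polygons with low/medium/high density classes
  (5/16/27 µg/m³ by the Hazard Mapping System convention). Overlapping
  plumes resolve to the day's highest density, days composite to weekly
  maxima, and a *smoke event* is any week with a plume over the lake.

Weeks are consecutive 7-day bins from an origin date (default 2018-01-01,
52 bins). Missing smoke records stay `NA` — they are never coerced to
"no smoke" — and lake-weeks without resolved pixels keep `NA` chlorophyll-a.

A lake-year is **smoke-impacted** when its label sequence contains a
no-smoke week, later a smoke week, later again a no-smoke week (`NA`s are
transparent: they neither extend nor break the pattern, since a missing
record says nothing about the sky). A lake with zero smoke weeks and at
least six observed no-smoke weeks is **non-impacted**; anything else is
**indeterminate**. Read literally, "six clear weeks" alone would let a lake
be non-impacted *and* smoke-impacted at once; requiring zero smoke weeks
keeps the classes disjoint. A strict mode (`consecutive = TRUE`) instead
demands a complete smoke run immediately flanked by no-smoke weeks, for
sensitivity analyses.

## The seasonal model

Each lake's seasonal curve is a natural cubic smoothing spline over
week-of-year, minimizing

$$\sum_w (y_w - f(w))^2 \;+\; \lambda \int f''(w)^2\,dw,$$

with the predictor in *week units*, so `lambda` has a fixed,
tool-independent meaning. At the default `lambda = 1` the smoother carries
roughly 19 equivalent degrees of freedom on a 52-week series: it tracks
seasonal bumps a few weeks wide essentially exactly (a noiseless Gaussian
bump of width 4–10 weeks is recovered within a few percent of its
amplitude) while damping week-to-week noise. As `lambda` grows the fit
degenerates smoothly into the least-squares line, the analytic limit of the
roughness penalty. Fitting is delegated to `stats::smooth.spline`, with the
penalty rescaled from week units onto its internal standardized domain; the
test suite checks the fit against an independent dense linear-algebra solver
of the same objective.

### Keeping the response out of the baseline

A flexible smoother fit to *all* observations partially absorbs any
short-lived uplift into the "seasonal" curve: in simulation, a 2-week
+1.5 µg/L event loses about 60% of its magnitude to the fitted curve at
`lambda = 1`, and the no-smoke residuals are dragged negative in
compensation. Stiffening the spline until events survive (hundreds of
equivalent `lambda`) destroys the seasonal fit itself — there is no single
bandwidth that both tracks a 4-week bloom bump and ignores a 2-week event.

The pipeline therefore estimates each lake's baseline from its **no-smoke
weeks only**, additionally excluding the `exclude_after = 1` week that
follows every smoke week (the modal persistence of the response; responses
fade within 1–2 weeks). A longer shadow is available, but widening the
baseline gaps measurably inflates the prediction variance and the
correlation of event-week residuals, degrading calibration of the pooled
tests with no gain in effect recovery. Residuals are still computed at
every observed week; `baseline = "all"` restores the conventional
full-series fit for sensitivity analyses.

Masking creates a second, subtler problem: weeks inside the fitting set are
in-sample (the smoother shrinks their residuals) while event weeks are
out-of-sample predictions with larger error. A pooled ANOVA comparing the
two would be anti-conservative — in null simulations the rejection rate
roughly quadruples. The fix is exact rather than heuristic: from the
penalized-spline linear operators the package computes the variance factor
of every residual — `diag((I-S)(I-S)')` in-sample, `1 + ||w(x_0)||^2`
out-of-sample, where `S` is the smoother matrix and `w(x_0)` the prediction
weights — and rescales *in-sample* residuals to the lake's mean
out-of-sample variance. Event-week residuals are never rescaled, so their
expectation remains the injected uplift (unbiased effect estimates); under
independent noise both groups then share a common variance, and the null
rejection rate in simulation returns to about 6%, within Monte-Carlo error
of nominal (the residual excess comes from correlation between residuals of
weeks sharing a baseline gap, which pooled ANOVA ignores; the
`per_lake_mean` mode is the cluster-robust alternative). Both columns are reported: `residual` (raw; satisfies
`observed = predicted + residual` exactly) and `std_residual` (the
inference variable used by every downstream test).

Lakes with fewer than `min_obs = 10` usable weeks are flagged unfit and
reported with a reason code — never silently dropped. Relative residuals
(`observed / predicted`) clamp the denominator at `prediction_floor`
(default 0.1 µg/L, a typical MDL) so near-zero baselines cannot blow up the
ratio.

### The `trim` option

The spline configuration carries `trim = 0.6`, interpreted as an iterative
robust mode: refit while excluding observations whose absolute residual
exceeds the `trim` quantile of absolute residuals, until the exclusion set
stabilizes (a degenerate spread, e.g. noiseless data, stops the iteration —
nothing is an outlier then). The mode is **off by default**: quantile
trimming always discards a fixed share of the data, which in simulation
biases the baseline under multiplicative noise without reliably isolating
event weeks, and exposure masking addresses the contamination problem
directly. The option exists for sensitivity analyses.

## The statistical battery

All inference runs on `std_residual`.

* **Two one-way ANOVAs** on weekly residuals pooled across lakes: smoke vs
  no-smoke, and by density class (none/low/medium/high). When the ANOVA is
  significant at 0.05, all pairwise Student's t tests (pooled two-sample
  variance) are computed and compact significance letters assigned from the
  maximal cliques of the not-significantly-different graph; no multiplicity
  correction is applied beyond the ANOVA gate, which is the classical
  protected-t procedure. A `per_lake_mean` sensitivity mode first averages
  within lake and group.
* **Seasonal difference CIs** on *observed* chlorophyll-a (bloom magnitude,
  not residuals): per lake and meteorological season (spring = Mar–May,
  summer = Jun–Aug, fall = Sep–Nov; winter excluded), lakes with at least
  one smoke and one no-smoke observed week contribute the difference of
  mean chlorophyll-a; each season reports the across-lake mean difference
  with a t-based 95% CI.
* **Event-aligned composites**: each maximal run of consecutive smoke weeks
  anchors one window at its first week (relative week 0); consecutive smoke
  weeks are relative weeks +1, +2, … of the same window rather than separate
  events, so persistence does not double-count. Lakes with more than 80% of
  observed weeks at the MDL can be filtered out (`mdl_filter = 0.8`) before
  per-relative-week means and medians are computed.
* **Per-lake deltas**: mean residual over smoke weeks minus mean residual
  over no-smoke weeks, binned on right-closed map edges
  (−∞,−10], (−10,−5], …, (10,∞) µg/L.
* **Strata**: trophic status from the lake's mean observed chlorophyll-a
  over no-smoke weeks (so the stratifier is not contaminated by the
  response): oligotrophic < 2, mesotrophic 2–7, eutrophic > 7 µg/L;
  elevation classes lower < 255, medium 255–538, higher > 538 m (the
  lowest / middle-two / highest quartiles of the smoke-impacted population;
  recomputable with `elevation_bounds()`). Boundary values belong to the
  middle class in both schemes, matching the closed printed ranges. For the
  impact stratification, smoke-impacted lakes contribute their delta;
  non-impacted lakes (which have no smoke weeks, hence no delta) contribute
  their mean residual.

## The synthetic lake landscape

Every statistical property of the pipeline is validated against a generator
with known ground truth:

* one Gaussian seasonal bump per lake — peak amplitude uniform on 1–20 µg/L,
  peak week 20–36, width (SD) 4–10 weeks — the simplest unimodal structure
  the spline must track;
* multiplicative lognormal noise, parameterized to mean 1 and CV
  `noise_cv = 0.3` exactly: chlorophyll-a is positive and right-skewed, and
  multiplicative noise keeps censoring meaningful;
* left-censoring at `mdl = 0.1` µg/L, reported at the MDL with an `at_mdl`
  flag (the flag is true iff the pre-censoring value was below the MDL);
* an independent weekly smoke schedule with `smoke_week_prob = 0.1`
  (≈5 smoke weeks per lake-year, a typical active-season exposure) and
  density mix 0.5/0.3/0.2 over low/medium/high;
* additive, density-keyed uplifts (defaults 0.3/1.6/1.2 µg/L) during each
  smoke week and the `persistence_weeks = 1` week after it, overlapping
  events summing; censoring is re-applied after injection and the exact
  per-week uplift is returned as a truth record.

These defaults are stand-ins chosen for realism, not estimates fitted to
any particular survey. The generator deliberately omits spatial
autocorrelation between lakes, radiative (light-attenuation) effects,
pixel-level imagery, and multi-year dynamics — so passing tests demonstrate
the statistical machinery on exchangeable lakes with ephemeral additive
responses, not calibration to any real landscape.

The validation suite runs at fixed problem sizes chosen to make Monte-Carlo
error small relative to the tolerances: 10,000 random label strings for the
classifier, 1,000 random instances for the ANOVA oracle, 500 null
replicates of 100 lakes × 52 weeks for type-I calibration (the nominal-5%
checks use ±2 Monte-Carlo standard errors), one 500-lake landscape for
effect recovery (±15%), and 100 replicates of 500 lakes for the
density-ordering check (the medium/high ordering spans a 0.4 µg/L gap, so
the per-replicate group means need that many lakes to resolve it).

## Numerical choices and degenerate inputs

* Seeds: every stochastic routine takes an explicit integer seed; per-lake
  streams derive from the configuration seed, so identical configurations
  are bitwise reproducible.
* Empty inputs: an empty pixel list yields `NA` (not 0); an empty smoke
  table labels every week no-smoke; an empty window set yields an empty
  composite; a season with fewer than two contributing lakes reports an
  `NA` CI with a warning.
* Ties and boundaries: density compositing breaks ties by the fixed
  ordering low < medium < high; delta bins are right-closed; trophic and
  elevation boundary values go to the middle class.
* Degenerate groups: an ANOVA group with fewer than two observations is an
  explicit error naming the group; the pipeline converts it into a skipped
  analysis with a warning (e.g. a smoke-free landscape).
* The spline needs at least four distinct weeks; below `min_obs` the lake
  is flagged unfit.

## Limitations

The pipeline tests association, not mechanism: smoke presence is correlated
with season and temperature, and nothing here separates nutrient deposition
from radiative effects. Plume polygons describe the whole atmospheric
column, so surface exposure is overstated on some days. The ANOVA treats
lake-weeks as exchangeable after studentization; it does not model spatial
or temporal autocorrelation beyond the per-lake seasonal fit. Residuals of
heavily censored lakes are dominated by the MDL floor — hence the 80%
at-MDL filter in the event-aligned view — and the cyanobacteria-index
conversion is only as good as its published calibration.
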