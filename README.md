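# lakesmoke

Do lakes bloom after wildfire smoke passes overhead? `lakesmoke` is an R
package for aquatic ecologists and water-quality analysts who want to link
weekly satellite-derived surface chlorophyll-a in lakes with daily
smoke-plume exposure and test whether chlorophyll-a is elevated during and
shortly after smoke weeks — overall, by smoke density, and across lake
elevation and trophic strata.

## What it computes

For each lake *i* with weekly surface chlorophyll-a `y_iw` (µg/L,
left-censored at a method detection limit) and weekly smoke exposure
(none / low / medium / high, the weekly maximum of daily plume densities
5/16/27 µg/m³):

1. **Event classification.** A *smoke event* is a week with a plume over
   the lake. A lake-year is *smoke-impacted* if it shows
   no-smoke → smoke → no-smoke in order (NA weeks transparent), and
   *non-impacted* if it has zero smoke weeks and ≥ 6 observed clear weeks.
2. **Seasonal phenology.** A natural cubic smoothing spline
   `f_i = argmin Σ_w (y_iw − f(w))² + λ ∫ f″(w)² dw` (λ = 1 in week units)
   estimates each lake's seasonal baseline from its unexposed weeks
   (smoke weeks and a 2-week post-event shadow are excluded from fitting).
   Residuals `r_iw = y_iw − f_i(w)` are reported raw and
   variance-standardized (`std_residual`, the inference variable), so
   in-sample and out-of-sample weeks are on a common footing.
3. **Statistics.** One-way ANOVAs of weekly residuals (smoke vs no-smoke,
   and by density class) with protected pairwise Student's t tests and
   compact significance letters; per-season 95% CIs of the across-lake mean
   difference in observed chlorophyll-a between smoke and clear weeks;
   event-aligned composites (relative week 0 = event onset) with an
   at-detection-limit lake filter; per-lake response deltas
   `mean(r | smoke) − mean(r | no smoke)` with map binning; and stratified
   summaries by trophic status (oligotrophic < 2, mesotrophic 2–7,
   eutrophic > 7 µg/L) and elevation (< 255, 255–538, > 538 m).

A synthetic lake-landscape generator (`sim_config()`,
`simulate_lakescape()`) produces seasonal bloom curves, lognormal noise,
censoring, stochastic smoke schedules and injected density-keyed responses
with exact ground truth, so the whole pipeline is testable offline.

## Worked example

Simulate a 40-lake landscape with the default smoke response
(0.3 / 1.6 / 1.2 µg/L for low / medium / high density smoke), run the full
pipeline on its CSVs, and render the report:

```r
library(lakesmoke)

sim <- simulate_lakescape(sim_config(n_lakes = 40, seed = 7))
paths <- write_lakescape(sim, "sim_data")

cfg <- run_config(paths[["chla"]], paths[["smoke"]], paths[["meta"]],
                  out_dir = "results_example", seed = 7)
s <- run_pipeline(cfg)

a <- s$anova_smoke
cat(sprintf("smoke vs no smoke: F(%d, %d) = %.1f, p = %.2g\n",
            a$df_between, a$df_within, a$F, a$p))
print(a$groups)
```

```
smoke vs no smoke: F(1, 2078) = 34.1, p = 6e-09
     group    n       mean        se       ci_lo     ci_hi letter
1 no_smoke 1881 0.09623434 0.0495844 -0.00101191 0.1934806      a
2    smoke  199 1.03895192 0.1628201  0.71786782 1.3600360      b
```

Smoke-week residuals average ≈ +1.1 µg/L above each lake's seasonal
baseline (the mixture of injected 0.3/1.6/1.2 µg/L effects) while no-smoke
weeks sit near zero, and the groups differ significantly (letters `a` vs
`b`): the pipeline recovers the injected response. `results_example/` also contains `group_summaries.csv` (density
classes), `season_ci.csv`, `event_aligned.csv`, `lake_deltas.csv`,
`strata_summaries.csv` and a versioned `summary.json`;
`cat(render_report(s))` prints them as one markdown report. A thin CLI
wrapper for shell use ships at `inst/cli/lakesmoke.R`
(`simulate` / `run` / `report` subcommands).

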