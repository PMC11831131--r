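# nutriclinr

Long-term trends in ocean **nutricline depths** from archives of
hydrographic bottle casts.

Nitrate and phosphate are usually below detection limits in the surface
ocean, so changes in nutrient availability are hard to observe directly.
Both nutrients increase with depth, and the depth at which a nutrient first
reaches a well-detected threshold concentration — the *nutricline*
(nitracline Z<sub>NO3</sub> for nitrate, phosphacline Z<sub>PO4</sub> for
phosphate) — proxies upper-ocean nutrient availability: a deepening
nutricline means less nutrient reaching the sunlit layer. `nutriclinr` is
for marine biogeochemists and ecological time-series analysts who want to
estimate these depths and their multi-decadal trends from irregularly
sampled cruise archives (GO-SHIP / GLODAP / WOD-style bottle tables), with
the statistical machinery needed to defend such trends against sampling
artifacts.

## What it computes

* **Nutricline depths per cast.** Scanning each depth-sorted profile from
  the surface, Z is the first depth where the linearly interpolated
  concentration reaches the threshold. The default thresholds are in
  Redfield proportion (N:P = 16:1): [NO₃⁻] = 3 µmol kg⁻¹ paired with
  [PO₄³⁻] = 3/16 µmol kg⁻¹; 1 and 5 µmol kg⁻¹ variants support sensitivity
  analyses.
* **Site trends.** Cast coordinates are rounded to 1° sites, depths are
  averaged per site and calendar year, and annual means deeper than 50 m
  between 45°S and 45°N enter per-site OLS fits of depth on year
  (T<sub>NO3</sub>, T<sub>PO4</sub>, m y⁻¹; sites need ≥ 2 years).
* **Median trends with bootstrap CIs.** The median of site trends, with a
  95% CI from 10,000 bootstrap resamples of sites — globally, per region
  (hemispheres, basins), and for derived quantities: the paired per-cast
  residual Z<sub>NO3</sub> − Z<sub>PO4</sub>, the seawater density at the
  nutricline (σθ), and the residual statistic
  (T<sub>PO4</sub> − T<sub>NO3</sub>)/√2, the signed orthogonal distance
  from the T<sub>PO4</sub> = T<sub>NO3</sub> line.
* **Robustness battery.** Scrambled-year permutation nulls for the median
  trend (MToRP) with two-sided empirical p-values; bottle-level
  measurement-error injection (0.8 / 0.1 µmol kg⁻¹ for nitrate/phosphate);
  climatology-sampling simulations that replay real sampling schedules onto
  a fixed monthly climatology with optional imposed trends;
  trend-distribution matching by grid search; sign and Kruskal–Wallis
  tests; a deep-water (> 1000 m) concentration-anomaly diagnostic for
  measurement bias; seasonal-anomaly correction against a monthly
  climatology.
* **Synthetic cruise archives.** A generator with analytic ground truth
  (per-site baseline depths, seasonal cycle, normally distributed site
  trends, logistic concentration profiles, bottle noise, two-layer T/S)
  so the whole pipeline is testable end to end without downloads.

Everything is data-frame-first: bottle tables, nutricline records, site
series and trends are tibbles that chain with the pipe; fitted summaries
have `tidy()`/`glance()` methods and `autoplot()` views.

## Worked example

```r
library(nutriclinr)

world   <- synthetic_world(n_sites = 60, years = c(1990, 2020), seed = 42)
arc     <- generate_archive(world)
records <- compute_nutriclines(arc$casts, thresholds = redfield_thresholds(3))
records
#> # A tibble: 7,286 × 10
#>   cast_id   nutrient threshold spec_id depth_m status  latitude longitude  year
#>   <chr>     <chr>        <dbl> <chr>     <dbl> <chr>      <dbl>     <dbl> <int>
#> 1 syn000001 nitrate          3 N3         161. crossed     30.3      4.28  1990
#> 2 syn000002 nitrate          3 N3         130. crossed     29.8      3.73  1990
#> 3 syn000003 nitrate          3 N3         148. crossed     30.1      3.97  1991
#> # ℹ 7,283 more rows

series <- records |> annual_average() |> filter_trend_eligible()
trends <- fit_site_trends(series)

med <- median_with_bootstrap_ci(trends[trends$nutrient == "phosphate", ],
                                n_bootstrap = 10000, seed = 1)
med
#> Median trend 0.0805  [-0.0378, 0.444] (95% bootstrap CI, 10000 resamples, n = 60 sites)

scramble_years(series[series$nutrient == "phosphate", ],
               n_randomizations = 2000, seed = 1)
#> MToRP null (site scramble, 2000 randomizations)
#>   observed median 0.0805, two-sided p = 0.08
```

The phosphacline median trend of +0.08 m y⁻¹ says phosphate depths at the
median site deepened slightly over 1990–2020, but the bootstrap CI spans
zero and the scrambled-year null (p = 0.08) shows a trend of this size
arises from sampling-order chance alone about 8% of the time — at 60 sites
this archive cannot distinguish the deepening from none. `tidy(med)`
returns the same summary as a one-row tibble; `autoplot(trends)` and
`autoplot()` on the null object draw the standard histograms.

A single-config pipeline (`run_pipeline()`, stages `simulate` →
`nutricline` → `aggregate` → `trends` → `nulls` → `report`) writes every
stage artifact as CSV/JSON with a run manifest; see `?run_pipeline`.

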