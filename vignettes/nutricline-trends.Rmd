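---
title: "Estimating nutricline depth trends from bottle-cast archives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating nutricline depth trends from bottle-cast archives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriclinr)
```

## The model

Surface-ocean nitrate and phosphate are mostly below detection, but both
increase with depth. The *nutricline* — the depth where a nutrient first
reaches a well-detected threshold concentration — therefore proxies how
far nutrient-replete water sits below the sunlit layer, and its long-term
trend proxies changing nutrient availability. `nutriclinr` estimates, per
cast and nutrient,

$$Z = \min\{z : C(z) \ge C_{\mathrm{thr}}\},$$

with $C(z)$ the piecewise-linear interpolation of the bottle
concentrations, and then models the annual site means $\bar Z_{s,y}$ as
locally linear in time: $\bar Z_{s,y} = a_s + T_s\,y + \varepsilon$. The
scientific quantity is the *median* of the site slopes $T_s$ — robust to
the very heavy site-to-site variability that seasonal aliasing and
measurement error produce — together with a percentile bootstrap CI over
sites.

Key assumptions, and where they matter:

* **Linear interpolation, first crossing.** The threshold crossing uses
  straight lines between the bracketing bottles (missing bottles are
  skipped, so brackets use the nearest non-missing neighbours), and the
  first crossing from the surface wins on non-monotonic profiles: the
  nutricline is the *top* of the nutrient-replete layer. Linearity is the
  minimal reproducible choice; the test suite pins it against a 0.01 m
  dense-grid brute-force scan.
* **Redfield-paired thresholds.** Defaults are [NO₃⁻] = 3 µmol kg⁻¹ and
  [PO₄³⁻] = 3/16 µmol kg⁻¹ (N:P = 16). Because 16 is a power of two,
  a profile with phosphate exactly nitrate/16 yields *bit-identical*
  crossing depths for the two nutrients — a symmetry the tests assert
  exactly, not approximately.
* **Eligibility.** Trends use only annual means strictly deeper than 50 m
  and sites within 45°S–45°N (inclusive): shallow nutriclines are
  entangled with mixed-layer variability, and high latitudes are not
  nutrient-limited in the same sense. A 25 m variant exists as an argument
  (`min_depth`) because the trend conclusions should not hinge on the cut.
* **OLS per site, unweighted.** Sites need ≥ 2 distinct years. Annual
  points are not weighted by cast count; the regression year is centred,
  which conditions the fit without changing slopes.

## Quality-control window

A crossing is only meaningful if the profile resolves it. By default a
cast is eligible for a nutrient when it has ≥ 3 non-missing values in
0–500 m **and** its deepest non-missing sample reaches 200 m
(`nutricline_control()`). Truncated casts otherwise yield spurious shallow
crossings. The window is deliberately configurable — short illustrative
profiles in documentation use `nutricline_control(min_samples = 2,
min_deepest = 0)` — and two non-missing samples is the hard minimum below
which interpolation is undefined (`insufficient_data`). A cast whose
shallowest sample already meets the threshold is `surface_saturated` and
carries that sample's depth rather than 0 m: such casts are excluded by
the 50 m rule anyway but remain usable for mean-depth maps.

## Statistics and their numerical choices

* **Bootstrap CI** (`median_with_bootstrap_ci()`): percentile method,
  resampling *sites* with replacement — the site is the exchangeable unit;
  resampling years would destroy the within-site time structure the trend
  lives in. Default 10,000 resamples, reproducible by seed.
* **Scrambled-year null** (`scramble_years()`): permutes year labels
  within each site, refits all site trends, and records the median per
  randomization ("median trends of random populations"). Within-site
  permutation preserves each site's depth multiset and spatial structure
  and destroys only temporal order — the stricter null; a global scramble
  is available (`scope = "global"`). The two-sided p-value uses the
  add-one correction $p = (1 + \#\{|m^*| \ge |m_{\mathrm{obs}}|\})/(n+1)$,
  so it can never report an impossible zero. The permutation inner loop
  uses closed-form grouped OLS (cross-checked against `lm()` in the
  tests); within-site permutation leaves each site's year variance
  unchanged, so only the covariance term is recomputed per randomization.
* **Sign test**: exact two-sided binomial on positive vs negative slopes,
  zeros dropped. **Kruskal–Wallis**: `stats::kruskal.test` behind the
  module surface, with a hand-rank oracle in the tests. p-values are
  two-sided throughout and deliberately not multiplicity-corrected: each
  robustness analysis is reported per se, and readers should treat the
  battery as converging evidence, not independent discoveries.
* **Seasonal anomalies** (`seasonal_anomaly()`): observed depth minus the
  monthly climatological depth at the record's site and month. The 50 m
  eligibility cut keeps acting on the *raw* depth (carried as
  `depth_raw_m`): anomalies are near zero by construction and filtering
  them at 50 m would be meaningless.
* **Climatology-sampling populations**
  (`simulate_climatology_sampling()`): replays a sampling schedule on a
  climatology with no long-term change. Random populations permute the
  month labels across events, preserving the archive's overall monthly
  sampling distribution while breaking the site–month pairing; a
  deterministic replay (`randomize_months = FALSE`, one population) is the
  degenerate case. An imposed trend $b_s(t - t_0)$ can be zero, fixed, or
  drawn per site from a normal distribution; under the null the
  population medians scatter around zero, and an imposed fixed trend
  shifts the recovered median to match it.
* **Trend-distribution matching** (`match_trend_distribution()`): grid
  search over (mean, sd) minimising squared errors of the simulated median
  and simulated trend variance against observed values, each standardised
  by the *median across cells* of the Monte-Carlo standard errors — a
  common scale, so noisier grid cells are not rewarded. Ties break toward
  smaller sd (the more parsimonious distribution); an optimum on a grid
  edge warns. Grid search rather than gradient methods because the
  objective is itself a noisy simulation output.
* **Density at the nutricline** (`density_at_depth()`): T and S are
  linearly interpolated to the crossing depth, never extrapolated, and
  passed to a pluggable equation-of-state hook. The shipped default is a
  linear EOS $\rho = \rho_0(1 - \alpha(T - T_0) + \beta(S - S_0))$
  returning a surface-referenced density anomaly; any function of
  (temperature, salinity) — e.g. a TEOS-10 σθ implementation — slots in
  unchanged. Trends of density-at-Z distinguish nutriclines moving *with*
  density surfaces (physics) from moving *across* them (biology).
* **Deep-water bias diagnostic** (`deep_anomaly_trend()`): below 1000 m
  concentrations should be climatologically stable, so the pooled trend of
  observed-minus-climatological concentration there should be zero; a
  nonzero slope flags analytical drift masquerading as a nutricline trend.
* **Site assignment**: rounding is half-away-from-zero on each coordinate
  (so 0.5° goes poleward/eastward consistently, unlike banker's rounding),
  longitudes normalised to [−180, 180) with 180 wrapping to −180; every
  valid coordinate maps to exactly one 1° site.

## The synthetic-data generator

`synthetic_world()` / `generate_archive()` emulate the statistical
structure the analysis assumes: $n$ 1° sites with baseline depths
$Z0_s$, a shared seasonal cycle $A\cos(2\pi(m-\varphi)/12)$, per-site
linear trends $b_s$ drawn per nutrient from normal distributions, casts at
Poisson-random dates, and logistic concentration profiles positioned so
the analytic crossing equals $Z_s(t,m)$ exactly (the logistic gives a
closed-form ground truth, emitted as a sidecar table keyed by `cast_id`).
Defaults, chosen once as the study conditions:

* 300 sites in 45°S–45°N, years 1972–2022, Poisson mean 2 casts per
  site-year, uniform months — a five-decade sparse archive.
* Baselines 80–160 m, seasonal amplitude 20 m (subtropical-gyre scale).
* Trend distributions N(−0.63, 1.5) m y⁻¹ for the nitracline and
  N(0.20, 1.0) m y⁻¹ for the phosphacline — the shoaling/deepening
  tendencies that, replayed through seasonal sampling, reproduce
  observed-archive-like medians and variances.
* Logistic width 50 m with 15 m bottle spacing through 30–300 m: the
  piecewise-linear interpolation error of the crossing is then bounded by
  about $h^2(1-2\sigma_0)/(8w) \approx 0.47$ m, which the tests assert
  (≤ 0.5 m at zero noise).
* Bottle noise 0.1 / 0.01 µmol kg⁻¹ (analytical replication scale). The
  larger *literature* uncertainties, 0.8 / 0.1 µmol kg⁻¹, are injected
  separately by `inject_measurement_error()` when studying error
  sensitivity, mirroring how such error propagates through real archives.
* `redfield_coupled = TRUE` makes phosphate exactly nitrate/16 per bottle
  (one shared crossing), for experiments isolating threshold-scale
  effects.

**The measurement-error regime deserves a note.** The injected phosphate
uncertainty (0.1 µmol kg⁻¹) is more than half the phosphate threshold
(0.1875 µmol kg⁻¹), so any bottle above the phosphacline can spuriously
exceed the threshold with probability of a few percent. When profiles are
shallow-nutricline and the imposed trend spread dominates the trend
variance, these spurious first crossings *attenuate* phosphacline trends
rather than widening them. The interquartile-range inflation contrast
(phosphacline spread inflating several-fold more than the nitracline's)
emerges in the regime the error experiment is about: deep-gyre nutriclines
(baselines 120–200 m) with seasonal sampling noise comparable to the
site-trend spread — the same variance decomposition the climatology replay
exhibits, where seasonality explains roughly half the observed trend
variance. The error-sensitivity tests and the acceptance script use that
configuration, stated here as the package's own design choice.

What the generator does **not** emulate — and hence what passing tests do
not show about real archives: spatially correlated trends and ENSO-scale
interannual variability, cruise-track clustering of casts (events are
independent), nutrient-specific profile shapes beyond the scaled logistic,
QC-flag pathologies of heterogeneous archives, and real bathymetry or
land. Conclusions about those features need real data.

## The pipeline

`run_pipeline()` drives the stages `simulate → nutricline → aggregate →
trends → nulls → report` from one YAML/list config, writing flat CSV/JSON
artifacts plus a manifest (config hash, seed, versions, per-stage row
counts and status). Stages validate their upstream artifacts and name the
missing file when run out of order; a failed stage marks downstream stages
skipped in the manifest. Every output is re-parsable by the package's own
readers.

## Problem sizes in the test suite

The suite regenerates all fixtures in code. Crossing-oracle comparisons
use 1,000 random profiles; null-calibration and parameter-recovery checks
use 20 replicate archives of 300 sites × 30 years with 400 scrambles and
1,000 bootstrap resamples per replicate; climatology simulations use
100–200 populations. These sizes are the package's choice of desk-scale
experiments: large enough that the binomial success criteria (e.g. ≥ 90%
of replicates covering truth) are meaningful, small enough to run
routinely. The package defaults (10,000 scrambles and resamples) remain
the recommended analysis settings.

## Known limitations

* The climatology reader supports the long-format CSV dialect only;
  NetCDF grids must be exported to it first.
* The default equation of state is linear; use the hook for TEOS-10
  accuracy.
* `deep_anomaly_trend()` interpolates per cast with a grouped loop and is
  the slowest step on very large archives; restrict it to casts reaching
  below the diagnostic depth.
* Sampling-density subsetting of cruise archives (thinning to a target
  spatial density) is not implemented.
* Pressure-to-depth conversion defaults to 1 dbar = 1 m; supply a hook for
  latitude-dependent conversion.
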