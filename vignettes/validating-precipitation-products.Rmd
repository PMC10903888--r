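---
title: "Validating gridded precipitation products against biological growth records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating gridded precipitation products against biological growth records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gridded monthly precipitation products — interpolated from weather
stations, derived from satellites, or assimilated by reanalysis models —
disagree most exactly where no stations exist to check them. Biological
growth records offer an independent yardstick: annual tree-ring widths
and satellite vegetation-greenness integrals both respond to
precipitation in the months leading up to the end of the growing season.
Holding everything else fixed, the product that explains more
inter-annual variance in growth is, for time-series work, the better
product. This is a *partial* validation: correlative skill says nothing
about absolute bias, so the comparison ranks products for variability
analyses, not for between-site climatologies.

`precipval` implements the full comparison pipeline: chronology
standardization, 8-month lagged regression scoring, moving-window
evaluation, and Condorcet regional ranking — plus a synthetic study
generator with planted noise structure so every stage has a
parameter-recovery test.

## From cores to chronologies

Raw ring widths confound climate signal with the tree's own
age/size trend. The pipeline follows standard dendrochronological
practice:

1. **Detrending.** Each core is smoothed with Friedman's variable-span
   supersmoother (`supersmooth()`, equal case weights, automatic span by
   cross-validation, `bass = 0`), which removes long- and
   medium-frequency variability while retaining year-to-year variation.
   The ring-width index is the **ratio** raw/fitted — the standard
   dimensionless index around 1. (The difference index is the obvious
   alternative; ratio was chosen because widths are strictly positive
   and the noise is multiplicative.) Cores shorter than 10 years cannot
   support the smoother and are detrended by their own mean, with a
   warning. Non-positive fitted values — possible for a flexible
   smoother near a ragged edge — are floored at a small epsilon
   (10^-3 of the median fit) rather than propagating negative indices.
2. **Pre-whitening.** Each detrended core is pre-whitened
   (`prewhiten()`): an AR(p) model fit by Yule–Walker, order selected by
   AIC over 0..min(round(10 log10 n), n − 2), residuals kept with the
   series mean re-added (residuals are recentred so the output mean
   equals the input mean exactly). Pre-whitening per core *before*
   averaging matches the behaviour of the standard chronology-building
   routine; pre-whitening the averaged chronology instead is exposed as
   `prewhiten_chronology = TRUE`. Greenness series are not pre-whitened
   by default.
3. **Robust averaging.** Cores are averaged per calendar year with
   Tukey's biweight mean (`biweight_mean()`, c = 9, MAD scale, start at
   the median, tolerance 1e-8, at most 50 iterations), falling back to
   the median at years with fewer than four cores, where the iteration
   has nothing to resist outliers with.

## Scoring a product at a site

Growth in year *t* is regressed on the 8 monthly precipitation totals
ending at the close of the growing season: January–August of *t* in the
northern hemisphere, July of *t* − 1 through February of *t* in the
southern hemisphere (the growth year is labelled by the calendar year
containing the season's end). The window includes its end month; this
reading of "8 months prior to the end of the growing season" covers the
growing season plus several antecedent months, which is where
precipitation–growth correlations are expected to be strongest.

The score is the **un-adjusted** R² of the ordinary least-squares fit of
the response on an intercept plus the 8 lag columns. No adjustment is
wanted: every product is fit with identical n and p, so the adjustment
would subtract the same penalty everywhere while making values less
comparable with saturated moving-window fits. Years with any missing
window month are dropped, not imputed, and every site's designs are
restricted to the **pairwise-complete** years shared by all products, so
all products face identical data. A site that fails the minimum sample
size (default `min_obs_full = 20`, comfortably above the 10 needed for
8 predictors + intercept + 1) for *any* product is excluded for *all*
products. Collinear predictor columns — possible in degenerate synthetic
configurations — are eliminated by pivoted QR at tolerance 1e-10, with a
warning.

Moving-window evaluation (`validate_windows()`) repeats the fit in
21-year windows stepping by 1 year, anchored to the calendar years of
the evaluation span so midpoints align across sites; each window reports
at its midpoint, `first_year + (W−1)/2`, so a 1901–2000 span yields
midpoints 1911–1990. Windows with any missing year are skipped entirely
(identically across products): with n = 21 and p = 8 the fit is already
saturated, and fewer rows would make R² incomparable across windows.

## Ranking products within a region

Per region, each site's per-product R² vector becomes a ranked ballot
(exact ties share a rank — no jitter, determinism matters more than
breaking meaningless float ties). `condorcet_outcome()` elects the
product that wins every head-to-head majority; the symmetric loser is
reported too. Ranked ballots use the full ordering, so last places count
against a product, not only first places. When a majority cycle leaves
no winner, the report says so explicitly (`used_fallback = TRUE`) and
carries Copeland scores (pairwise wins − losses) for downstream
tie-breaking, rather than silently electing someone. Regions with fewer
than `min_ballots = 5` sites are flagged: one noisy site should not
paint a region. Regional bar summaries default to the arithmetic mean of
R² (`summary_fn = median` is available).

## The synthetic study generator

No generative model exists for the real archives, so the generator is an
explicit stand-in with known structure; its purpose is parameter
recovery, not realism.

- **Truth.** Monthly precipitation is lognormal around a 12-value
  seasonal cycle (defaults: a temperate 45–90 mm cycle) with
  coefficient of variation `seasonal_cv = 0.4` — typical inter-annual
  variability for mid-latitude monthly totals.
- **Products.** Product k multiplies truth by `exp(N(0, sd_k))`,
  independently per site-month. Multiplicative lognormal error keeps
  products positive and scales error with magnitude, as interpolation
  error does. The default planted ordering is sd = (0.25, 0.5, 1.0):
  a good, a mediocre and a poor product. `product_noise_sd` may be a
  product × region matrix to plant regional winner flips.
- **Growth.** The site signal is `g_t = Σ β_j z_jt + η_t` where `z` is
  truth precipitation z-scored per calendar month (so β is scale-free)
  over the site's 8-month window, and η is AR(1)
  (`ar1_coef = 0.3`, innovation sd 0.4). The default β ramps from 0.05
  to 0.30 toward the window's end — late-window months matter most —
  giving full-period R² against truth around 0.5 at chronology level,
  a strong but realistic precipitation-limited site. Each of 5 cores
  multiplies a negative-exponential juvenile trend (2 mm initial level,
  0.02/yr decay in cambial age) by `exp(g_t + N(0, 0.2))`; core start
  years are staggered uniformly over the first third of the span to
  exercise ragged-edge averaging.
- **Greenness.** The same response model without age trend or core
  replication; a fraction `evi_missing_frac = 0.1` of cells is missing
  at random, and a site is retained only if at least half its years are
  present — the same completeness rule applied to vegetation-index
  pixels.
- **Reproducibility.** Each generator stage draws from its own stream
  derived from `config$seed` by a fixed offset (truth = 1, products = 2,
  rings = 3, greenness = 4). Identical configs therefore give
  bit-identical studies, and each stage is reproducible standalone.

What the generator does **not** emulate: spatial autocorrelation among
sites, product error geography, species differences, cross-dating error,
disturbance pulses, or the fat-tailed measurement blunders of real
archives. Passing parameter-recovery tests shows the pipeline's
statistics behave as designed, not that any real product is good.

## Numerical choices and degenerate inputs

- Null calibration uses β = 0 **and** `ar1_coef = 0`: with iid normal
  responses the full-period R² is exactly Beta-distributed with mean
  p/(n − 1), which the test suite checks against 200 signal-free sites.
  With AR(1) noise that closed form would not hold.
- The biweight iteration returns the median when the MAD collapses to
  zero; the OLS scorer reports `NA` for a constant response (R²
  undefined) and clamps tiny negative rounding residue into [0, 1].
- RWL parsing auto-detects the precision dialect from the series
  terminator (999 → 0.01 mm, −9999 → 0.001 mm) and rejects — never
  repairs — malformed lines, overlapping or gapped decades, and missing
  terminators. BCE years are not representable and are refused on
  write.
- Problem sizes in the test suite are chosen for tight Monte-Carlo
  control at desk scale: 200 sites for null calibration, 20 independent
  80-year studies of 100 sites for ordering recovery, 1000-case oracle
  sweeps for the biweight and Condorcet primitives.

## Worked example

```{r, eval = FALSE}
library(precipval)

cfg <- sim_config(seed = 1)        # 100 sites, 80 years, K = 3 products
run <- run_study(cfg)

glance(run)                        # mean R^2 per product
run$report$regions                 # Condorcet winner/loser per region
autoplot(run$report)

wf <- validate_windows(run$growth, run$study$products, run$study$sites,
                       eval_span = c(1921, 2000))
plot_window_skill(wf)
```

With the default planted noise ordering the low-noise product wins the
region and mean R² decreases strictly in product noise; the acceptance
script (`scripts/acceptance.R`) recomputes exactly these quantities from
scratch.

## Limitations

The pipeline deliberately stops at a simple correlative skill score: no
bootstrapped response functions, no significance tests per month, no
spline/negative-exponential detrending alternatives, no EPS/rbar
chronology diagnostics, and no raster or cartographic handling — regions
enter as precomputed labels. Where the real-data workflow needs those,
dedicated dendro and GIS tooling should wrap this package, not replace
it.
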