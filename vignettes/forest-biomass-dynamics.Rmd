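---
title: "Estimating long-term biomass dynamics from forest census plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating long-term biomass dynamics from forest census plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(forestsink)
```

This vignette explains the models and procedures `forestsink` implements,
the assumptions behind them, the numerical and design choices that were
genuinely open, and what the simulated-data validation does and does not
demonstrate.

## From census records to stem biomass

The unit of observation is a stem ≥ 10 cm diameter measured at a painted
point of measurement (POM), re-measured at every census of its plot.
Biomass of a non-monocot stem is
`AGB = 0.0673 (ρ D² H)^0.976` kg, with diameter `D` in cm, height `H` in
m and wood density `ρ` in g cm⁻³; monocots use the diameter-only form
`exp(−3.3488 + 2.7483 ln D)`. Plot totals are expressed in Mg ha⁻¹ by
summing stems and dividing by the topography-corrected area.

Two pre-processing steps protect the diameter series:

* **POM changes.** When buttress growth forces the POM upward, the change
  census records the diameter at both POMs; their ratio (new/old) is the
  taper ratio. We standardize the whole series to the old POM (dividing
  post-change values by the compounded taper) and to the new POM
  (multiplying pre-change values), and take the elementwise mean. The
  mean series corresponds to an invariant POM between the two, avoids the
  step artefact of switching series, and uses tree-level taper
  information. If the old POM was already unusable at the change census,
  the old-POM diameter is estimated by projecting the previous
  measurement forward at the tree's accepted growth rate (records flagged
  `estimated`).
* **Growth anomalies.** Annualized growth outside −0.5 to +4 cm yr⁻¹
  (configurable) is treated as measurement error. The offending value is
  replaced by extrapolation from the previous *corrected* value — the
  tree's own mean accepted growth if any interval is accepted, else the
  plot size-class statistic (mean in the 10–19.9 cm class, where growth
  is right-skewed by many slow small stems; median in the 20–39.9 and
  ≥ 40 cm classes, where samples are small and the median is both robust
  and conservative with respect to net biomass gain). Corrections cascade
  forward: a corrected diameter is the baseline for the next interval,
  so a single bad census does not poison two intervals. A tree with two
  or more growth intervals, all implausible, is excluded. Raw values are
  preserved in a parallel column so the corrected fraction is auditable;
  on the default simulation it is ≈ 2%, matching the scale reported for
  curated field networks.

Heights are rarely measured on every stem, so they are predicted from a
height–diameter model fitted to a measured subsample: a Weibull curve
`H = a(1 − exp(−b D^c))` fitted by ordinary or basal-area-weighted least
squares (the weights, ∝ D², give large trees — which dominate biomass —
more influence), or a log–log regression. Among candidate fits we select
the one minimizing the summed absolute AGB prediction error over the
height sample (error is summed, not averaged; the ranking is identical).
Exact ties fall to the deterministic order Weibull > BA-weighted Weibull
> log–log, preferring the asymptotic forms that cannot extrapolate
unboundedly. Wood density is assigned by taxonomic hierarchy — species
value, else genus mean, else family mean, else the mean over the plot's
identified stems — with the provenance level recorded.

## Interval dynamics and census corrections

For a census interval of length `t` years, above-ground wood productivity
(AGWP) is the annualized biomass gain of surviving and recruiting stems,
and AGB mortality the annualized biomass of stems dying. Both are
corrected for two components unobservable from the censuses themselves:

1. **Unobserved recruits** that enter and die within the interval. The
   "true" recruit count inverts the census-corrected recruitment rate
   (`r_corr = r t^0.0759`, with the survivors as base population):
   `N_true = Ns ((Ns+Nr)/Ns)^(t^0.0759) − Ns`. The excess over the
   observed recruits is assigned a diameter of the plot minimum plus one
   third of the interval's growth at the small-class mean rate, the plot
   mean wood density, and a predicted height. `N_true` is kept
   real-valued (the unobserved count is `max(0, N_true − Nr)`, clamped
   with a log entry if rounding would make it negative) so corrections
   are smooth in `t`; a self-consistent fixed-point inversion differs
   negligibly for `t` < 10 yr.
2. **Growth of known dying trees** after their last measurement, assumed
   to die at mid-interval having grown at the plot's size-class median
   rate.

Both components add equally to gain and loss, so they cancel in the net
flux. Survivor gains count positive AGB increments; the small post-QC
biomass decline of shrinking survivors is carried as an explicit
`survivor_loss` column inside AGB mortality. With that bookkeeping the
package maintains the exact identity
`AGWP − AGB mortality = ΔAGB / t` on every interval (the test suite
enforces 10⁻⁹ Mg ha⁻¹ yr⁻¹ across the full simulated network), which is
the property that makes the flux decomposition auditable.

Stem turnover uses `r = 100 (ln(Ns+Nr) − ln Ns)/t` and its mortality
analogue, multiplied by `t^0.0759` to correct for stems that both enter
and die unobserved. A caveat surfaced by the simulator: the exponent is
an empirical pan-tropical calibration, and because the log-ratio formula
partially self-corrects (the survivor base also shrinks with `t`), at
the simulator's 1.8% yr⁻¹ interior mortality the correction mildly
*over*-corrects long intervals. The tests therefore check the qualitative
property — observed rates decline with `t`, corrected rates do not —
rather than exact constancy.

Plots smaller than 0.4 ha within 1 km of one another are merged into one
sampling unit when their censuses are synchronous. "Synchronous" is taken
as identical census-date sets after rounding to 0.1 yr (the protocols
give no tolerance; 0.1 yr distinguishes genuinely separate field
campaigns). The merged unit sums areas, pools trees (tags prefixed by
source plot), and takes the area-weighted mean edge distance; merging
plots with different minimum diameters is refused.

## Edge effects and the trend model

Each plot's AGB trend is the OLS slope of AGB against calendar time.
Because short monitoring windows produce noisy slopes, analyses weight
plots by the cube root of monitoring length; `weighting_diagnostic()`
verifies on request that this removes the deviation–length relationship
without introducing an area one.

The scale of edge effects is estimated by modelling plot slopes against
edge distance with four forms — hockey-stick (two linear segments joined
continuously, the second flat; the join is the edge-penetration
distance), asymptotic `y = a − b e^(−cx)`, linear, and null — compared by
`AIC = n ln(SSE_w/n) + 2k`. Parameter counts include the residual
variance (k = 4, 4, 3, 2); the comparison is internal so only
consistency matters. The hockey break is profiled over a deterministic
grid of observed distances plus midpoints, restricted to the interior of
the distance range, with ties resolved toward the smaller break; a
perfect-fit floor on the SSE makes degenerate (constant-response) inputs
rank by parsimony instead of producing −∞ AICs. The analysis is
restricted to plots within 2 km of an edge by default, where the
contrast lives. Cube-root weights enter the edge-model SSE by default
(set `weighted = FALSE` to drop them — whether the original analyses
weighted these fits is not documented, so both are available). The
break-point CI resamples plots with replacement (999 by default) and
refits; refits profile over the *full-data* break grid so the bootstrap
measures sampling uncertainty rather than grid coarsening, and the run
errors out if more than 20% of refits fail.

The network-level trend uses the linear mixed-effects model

```
AGB_ij = β0 + β1 time_ij + β2 edge_i + β3 time_ij:edge_i + u0i + u1i time_ij + e_ij
```

with a random intercept and slope per plot, fitted by REML via
`nlme::lme`. Time is centred at the network mean census date (stabilizes
the intercept–slope correlation; β1 and β3 are invariant to centring).
Residual diagnostics on real networks show variance rising with fitted
value and falling with plot area, so the residual variance is modelled as
`(area)^δa (fitted)^δf` through `varComb(varPower(~area),
varPower(~fitted(.)))`, the exponents profiled within the (RE)ML
iterations; the reported `var_exponents` are on the variance scale
(twice nlme's sd-scale powers). CIs use the normal approximation to the
REML estimator distribution. Marginal R² is the fixed-effect prediction
variance over the sum of fixed, random (averaged over observed times)
and mean residual variance. On convergence failure the fitter retries
with `optim`, then falls back — flagged in the result — to an
intercept-only random effect and/or homoscedastic residuals.

Supporting estimators: `weighted_mean_change()` (cube-root-weighted mean
of plot slopes with a hand-constructed BCa bootstrap CI — jackknife
acceleration, normal-scale interpolation between order statistics; the
test suite checks it against the independent `boot::boot.ci`
construction on identical replicates), `threshold_scan()` (interior/edge
trends at 100–1000 m thresholds in 100 m steps, rows with fewer than 3
plots in a class flagged rather than fitted), and `leave_one_out()`
(trend spectrum under plot or site omission).

## Drought windows

For a named El Niño event (default interval 1997.5–1998.5 in decimal
years; the episode bounds are user-declared, not detected from climate
data), each qualifying plot — monitored before, during and after — has
exactly one interval overlapping the event, labelled `during`; earlier
and later intervals are `before`/`after`. If a census date falls inside
the event, the interval containing the event midpoint is `during` and
the plot is flagged. Window means of AGWP, AGB mortality and annualized
AGB change come from an intercept-only mixed model (plot random
intercept) with interval-length weights — longer intervals average more
demographic noise. The annualized interval-level AGB change is used for
all three responses, rather than refitting the time-slope model within
each window, so the three responses are estimated on the same support
and remain identifiable with the 1–3 intervals per plot per window that
drought windows typically contain. Significance is read from
non-overlapping 95% CIs, the convention used for these window contrasts.

## The simulator: what it emulates, and what it does not

`simulate_network()` generates the study conditions end to end: 71 plots
(22 edge, 49 interior; 7 with a 15 cm minimum diameter), areas 0.25–4.4
ha, 2–9 intervals of 2–6 whole years starting 1972–1994, stems ≥ 10 cm
at ≈ 530 ha⁻¹. Demography is annual: lognormal diameter increments with
size-class means (0.17/0.24/0.20 cm yr⁻¹), Bernoulli mortality with a
size-biased hazard ∝ (D/20)^−0.4 renormalized to 1.8% yr⁻¹ of stems
(2.3% in edge plots), and Poisson recruitment at 1.6%/2.3% yr⁻¹ with
edge recruits tilted toward low-wood-density species. The size bias is
the mechanism that makes the stand a biomass sink: deaths concentrate in
small stems, so biomass mortality (≈ 6.1–6.5 Mg ha⁻¹ yr⁻¹) runs below
stem mortality × AGB while AGWP sits near 7.3–7.5 Mg ha⁻¹ yr⁻¹, giving
a realized interior trend near +0.9 and an edge trend near −0.3
Mg ha⁻¹ yr⁻¹ at ≈ 430 Mg ha⁻¹ standing biomass. A 5% edge growth
stimulus (canopy opening from elevated turnover) keeps edge AGWP
slightly above interior, as observed in edge-affected stands. These
values are calibration knobs fixed once against the long-term means the
package is designed to estimate.

The 1997–1998 drought is a one-year hazard multiplier of 4.0 followed by
a 12-year growth stimulus of 1.30. Both were calibrated at the *census
interval* level: diluted over a typical ≈ 4-yr `during` interval the
pulse yields a mortality ratio of ≈ 1.6–1.8 and an after/before AGWP
ratio of ≈ 1.2 with non-overlapping CIs — the before/during/after
pattern the drought-window analysis is meant to detect.

Observation is separate from demography: diameters are measured with 0.1
cm noise; stems enter the record when their *measured* diameter crosses
the plot minimum; large stems (≥ 30 cm) receive a new POM with
probability 0.02 per census, recording dual measurements with a taper
ratio drawn from 0.85–0.97; deaths of recorded stems appear once, at the
next census. Ground truth (annual true AGB, true per-interval fluxes,
per-year death counts, realized trend slopes) is computed from the
complete event stream, never from the censuses — so estimator validation
compares against what actually happened in the simulated stand.

The simulator deliberately omits features of real data: no spatial stem
maps or neighbourhood competition, no gradual edge gradient (the edge
effect is a step at 448 m, so the hockey-stick break has a well-defined
truth), no species-level community assembly beyond the wood-density
shift, no missed censuses or partial plot re-measurement, and no
correlation between growth and mortality at the stem level. Passing
tests therefore demonstrate that the estimators recover known truths
under the stated statistical structure — not that real census data meet
that structure. One consequence worth noting: with a step edge effect of
≈ 1.2 Mg ha⁻¹ yr⁻¹ against plot-slope noise of similar magnitude, the
hockey-stick break is identified with wide bootstrap CIs, much as the
real-data analyses report.

## Numerical choices and problem sizes

Seeds are explicit everywhere; the canonical default is 20171219 (used
by the test suite for the network simulation and bootstraps). RNG
substreams are derived per plot so stands are reproducible individually
and in parallel. Weibull and asymptotic curves are fitted with
`minpack.lm::nlsLM` (Levenberg–Marquardt, up to 500 iterations), with
data-driven starts and a convergence error carrying the best iterate.
The test suite runs the full default network once (71 plots, ≈ 46,000
stems, ≈ 250 intervals) for the conservation identity and the
end-to-end recovery checks; estimator calibration uses 100 replicate
fits at the 71-plot design scale for CI coverage, 150-plot × 15-census
designs for variance-exponent recovery (chosen so the exponent sampling
error is comfortably inside the ±0.1 check), and a 999-resample
bootstrap for the break-point CI. The whole suite completes in about a
minute on one CPU.

## Known limitations

* Heights are modelled, not measured, for most stems; a systematically
  wrong H–D model biases AGB levels (though trends less so). Alternative
  published H–D parameterizations can be supplied as `hd_model` objects.
* The `t^0.0759` turnover correction is an external empirical constant;
  it is not re-estimated from the data at hand.
* The mixed model assumes Gaussian residuals after the power variance
  function; no spatial autocorrelation between plots is modelled.
* Edge distance is an input; the package does not measure it from
  imagery.
* Below-ground carbon, necromass and branch-fall partitioning are out of
  scope; `carbon_from_agb()` converts above-ground live biomass only.
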