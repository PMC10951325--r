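---
title: "Assessing modeled subsurface reef temperatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing modeled subsurface reef temperatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Coral bleaching is driven by the temperature regime corals actually
experience at depth, which satellite skin temperatures and sparse logger
deployments only partly capture. Data-assimilative regional ocean models
offer continuous subsurface coverage, but before their output can feed
heat-stress monitoring it has to be validated against in situ records.
`reefskill` implements that validation pipeline for the common data
situation: fixed subsurface temperature loggers sampling every 5 minutes
(sometimes 30), and a gridded reanalysis archived as instantaneous 3-hourly
snapshots on fixed depth strata (here 5, 10, 20 and 30 m on a ~4-km grid).

```{r, eval = FALSE}
library(reefskill)
```

## Pairing observations with snapshots

Because the model archive stores snapshots rather than interval averages,
the logger series is averaged in a short window centred on each snapshot
time: ±10 min for 5-min cadence and ±1 h for 30-min cadence, both endpoints
inclusive, so a complete window always holds 5 measurements. Windows with
fewer samples (deployment gaps, battery failures) are kept but flagged with
their count; `pair_series(min_window_n = )` (default 3) drops the sparsest
ones while preserving auditability. Matchups are never emitted outside the
overlap of the two series. Logger depths map to the nearest model stratum,
with exact ties resolved to the shallower stratum — an interpolation-free
rule chosen because nearshore vertical gradients over 5 m are small
relative to model error. Reanalyses need an assimilation spin-up period, so
the Taylor-diagram and bias-surface stages exclude samples before a cutoff
(default 2011-01-01 00:00 UTC); the raw overall comparison keeps the full
series, and the stage functions take the cutoff as an argument.

## Agreement statistics

For paired values (obs_i, model_i), `skill_summary()` reports Pearson r,
bias = mean(model − obs) (positive = model warm), mean absolute error and
RMSE; `|bias| ≤ MAE ≤ RMSE` always holds. `taylor_stats()` reports the
Taylor-diagram triple: r, the standard-deviation ratio sd_model/sd_obs, and
the centered RMS difference, which satisfy crmsd² = sd_m² + sd_o² −
2·sd_m·sd_o·r. Sample (n−1) standard deviations are used throughout; the
identity is convention-invariant as long as one convention is used
everywhere. Grouped tables (`grouped_skill()`) normalize by each group's
own observed standard deviation, so every group is directly readable
against the unit "observed" reference point of a normalized Taylor diagram.
Distance-to-shore bands default to data quartiles and are configurable
because no canonical band definition exists.

Because both the logger and the model contain error, the overall linear
relationship model = α·obs + β is estimated by Deming (errors-in-variables)
regression rather than OLS. The error-variance ratio λ is taken from the
coefficients of variation of the two series, λ = (CV_m·mean_m)² /
(CV_o·mean_o)², which reduces to the variance ratio sd_m²/sd_o²; it is
computed once from the full paired dataset, matching the single overall fit
the diagnostic is used for. The slope comes from the closed-form root of
the quadratic in the sample moments — exact, fast, and directly testable
against a brute-force minimization of the generalized perpendicular
objective. With λ = 1 the fit is orthogonal regression; swapping the two
series while replacing λ by 1/λ inverts the fitted line. The slope's
p-value uses a jackknife standard error over pairs: the reference analyses
in this field report significance without naming a method, and the
jackknife is assumption-light; it is a design choice of this package, not a
reproduction of any particular published test.

## The bias surface

`fit_bias_gam()` models per-matchup bias as an additive penalized-spline
regression (Gaussian family, identity link): cubic regression splines in
depth and distance to shore, a cyclic cubic spline in day of year with the
cycle closed between day 1 and day 366 (so leap years are handled and
f(day 1) = f(day 366) by construction), year as a categorical term with the
earliest year — 2011 when present — as baseline, and a lon–lat tensor
product so the two coordinates are weighted evenly. Fitting is delegated to
`mgcv`, the standard engine for this model class; smoothing parameters are
selected by REML, the robust default when the selection criterion is
otherwise unspecified. Basis dimensions default to 10 for univariate
smooths and 25 (5 × 5) for the tensor surface and shrink automatically when
a predictor has fewer unique values — synthetic arrays often have only
three distinct depths, for example. Terms whose predictor is effectively
constant are dropped with a warning rather than failing the fit.
`partial_effect()` returns centered partial contributions with pointwise
95% bands and refuses to extrapolate beyond the observed predictor range
(plus a 5% margin) because spline extrapolation is meaningless for these
diagnostics.

## Heat-stress metrics

Monthly climatologies are calendar-month means over a baseline (default
2010–2017), computed within one source — observed and modeled datasets each
get their own climatology, so anomalies measure departure from each
dataset's own seasonal norm rather than inter-dataset bias. Daily
detrended temperatures are residuals from a cyclic-spline fit of daily
means on day of year; short cold pulses (internal bores, upwelling) appear
as large negative residuals. Daily means pool all sites by default, with a
per-site mode available, since the pooled regional trace is what the
anomaly comparison uses.

Biweekly variability uses consecutive non-overlapping 14-day blocks
anchored at the series start; non-overlapping blocks avoid the strong
autocorrelation that rolling windows would induce in the comparison
regression, and a trailing block with under 7 days of data is dropped as
unrepresentative. The CV is sd/mean on °C — scale-dependent, but the
convention of the bleaching-variability literature this metric comes from.
Observed and model windows computed from a paired dataset share timestamps,
so `compare_metric()` matches them by (site, window start) and reports the
OLS slope, intercept and r². A peak-bleaching subset is available as a
simple month filter (July–October).

## Spectral diagnostics

`periodogram()` removes the mean, applies the FFT, folds to one side
(doubling the density, halving the Nyquist bin for even lengths) and
converts the frequency axis to cycles per hour by dividing the per-sample
frequency by the sampling interval, so the area under the density equals
the series variance (Parseval; exact up to the sample/population variance
factor). The 3-hourly snapshot cadence caps the resolvable band at 6-hour
periods; faster truth components alias away, which the synthetic module
demonstrates directly. `smooth_daniell()` applies iterated modified Daniell
kernels (half-weight endpoints), defaulting to spans (9, 9) — a smoothness
choice, logged in the result, not a published constant — with half-sample
reflection at the ends, which preserves total area exactly for any
symmetric kernel. No taper is applied by default (an optional split-cosine
taper exists) since leakage is minor for these long series and an untapered
estimate keeps the variance bookkeeping exact. Gaps up to 24 h are linearly
interpolated and flagged; longer gaps split the series into segments whose
spectra are averaged, length-weighted, on the longest segment's frequency
grid. `find_peaks()` reports strict local maxima filtered by topographic
prominence, as periods in hours sorted by density.

## The synthetic generator

`generate_true_series()` builds the truth/observation signal as mean +
harmonics + AR(1) red noise + white noise. Defaults, chosen once to mirror
a nearshore Hawaiian reef regime: mean 25.5 °C; harmonic amplitudes 1.2 °C
annual (8766 h, a harmonic rather than a spline so its variance is in
closed form), 0.10 °C diurnal, 0.15 °C at the M2 semidiurnal internal tide
(12.42 h), 0.05 °C at S2 (12.0 h) and 0.04 °C at 25.82 h — the bands where
observed reef spectra concentrate energy; white noise sd 0.05 °C; AR(1)
marginal sd 0.30 °C with coefficient 0.98 at the 5-min cadence
(decorrelation of a few hours, supplying the low-frequency background the
spectral comparison needs). The logger noise floor is far below instrument
accuracy in the real archive, so these noise levels are free parameters of
the emulation, not estimates. Optional negative half-sine pulses emulate
internal-bore cooling events and are off by default; when enabled they
demonstrate that 3-hourly snapshots miss most of them.

`degrade_to_model()` turns truth into the model series the way the archive
is actually produced: instantaneous subsampling on the 3-hourly UTC grid
(snapshots, never window averages), with injectable constant bias, a
day-of-year cosine bias, amplitude attenuation of harmonics faster than a
cutoff (default 30 h, emulating under-resolved sub-daily energy), and extra
noise. Degradation regenerates the harmonic part from the stored
decomposition and reuses the truth's realized noise, so a zero-error
configuration reproduces truth at snapshots bitwise and attenuation is
exact rather than a filter approximation — this is why degradation is
defined on generated series rather than arbitrary ones.

What the generator does *not* emulate: spatial covariance between sites,
instrument drift and biofouling, data-assimilation increments, and
episodic mesoscale structure. Passing parameter-recovery tests therefore
demonstrates the correctness of the statistical machinery under the
generator's assumptions, not the field accuracy of any particular ocean
model.

One empirical subtlety the synthetic experiments surfaced: the
"model-underestimates-biweekly-CV" direction (regression slope < 1 under
harmonic attenuation) holds at the logger's native 5-min cadence, where the
±10-min matchup window barely smooths the observations. At 30-min cadence
the ±1-h window itself attenuates the observed sub-daily bands, and the
slope can exceed 1 even though every model window is less variable than its
observation in absolute terms. The directional tests therefore run at the
5-min study cadence.

## Problem sizes and numerical choices

The package's own validation uses desk-scale archives: 25 sites × 1 year at
5-min cadence (~2.6M truth samples, 73,000 matchups) for injected-error
recovery, 8 sites at 30-min cadence for the seasonal-bias GAM (~23,000
matchups), n = 10,000 for the null deviance check, and series of 1,656–4,096
points for spectral checks — sizes at which every stage runs in seconds
while Monte-Carlo error stays well inside the tested tolerances. Seeds are
explicit arguments everywhere; per-site seeds derive deterministically from
a master seed, so an archive is reproducible from (configs, error config,
seed) alone. Degenerate inputs fail loudly: constant series for λ or Taylor
statistics, zero covariance for the Deming slope, missing months for a
climatology, under 180 distinct days of year for seasonal detrending, and
irregular cadence for the periodogram.

## Known limitations

- `read_model_series()` reads the long-format griddap CSV dialect; NetCDF
  extraction is out of scope for this package and can be done upstream
  with any standard tool.
- The Deming p-value method is a package design choice (jackknife), so
  published p-values obtained with other methods are not bit-comparable.
- The bias GAM fits the single stated formula; model selection across
  alternative structures is deliberately out of scope.
- Spectral peak *locations* are robust to the Daniell span choice; peak
  *heights* are not, so only locations should be compared across analyses
  using different spans.
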