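---
title: "Quantifying tree resilience to extreme drought: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tree resilience to extreme drought: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrores)
```

## The problem

Trees on cold, semi-arid plateaus grow a single ring per year whose width
tracks growing-season moisture. When an extreme drought hits, growth drops;
in the following years it usually rebounds. `dendrores` quantifies this
behaviour for every tree in a multi-site network and asks how the *regional*
pattern of resistance and recovery changes across successive droughts, and
which climatic and stand-internal factors drive it.

The analysis runs on ring-width indices (RWI): each tree's measured widths
divided by a fitted growth-trend curve, so values scatter around 1 and are
comparable between young and old trees. For a drought in year $e$, with
$D$ the tree's index in year $e$ and $\mathrm{Pre}$, $\mathrm{Post}$ the
mean indices over the 4 years before and after, the two Lloret components
of resilience are

$$R_t = D / \mathrm{Pre}, \qquad R_c = \mathrm{Post} / D.$$

A tree is *high resistance* when $R_t > 0.75$ and *high recovery* when
$R_c > 1.25$ (strict inequalities). Site-level responses are the
proportions of trees beyond these thresholds, mapped onto Thiessen
polygons and regressed on candidate drivers.

## Pipeline stages and the choices behind them

### Detrending

Each tree is detrended with a cubic smoothing spline whose 50%
frequency-response cutoff sits at half the series length — stiff enough to
keep interannual (climatic) variance in the indices while absorbing the
age/size trend. Two numerical points deserve record:

* **Penalty mapping.** For the discrete natural smoothing spline on unit
  spacing, the filter symbol gives the closed form
  $\lambda = (1/f - 1)\,(2 + \cos\omega)\,/\,(12\,(1 - \cos\omega)^2)$
  for amplitude response $f$ at angular frequency $\omega = 2\pi/W$
  (wavelength $W$ in years). This is exact for interior points; the test
  suite verifies the realized response by least-squares sinusoid fits.
* **End treatment.** A natural spline is too permissive near the series
  ends: with only two cutoff wavelengths of data the whole-series response
  measured 0.61 rather than 0.50. The series is therefore extended by
  *point reflection* (odd extension) over one cutoff wavelength at each
  end before smoothing. Point reflection continues straight lines exactly,
  so constants and linear ramps are still reproduced to machine precision,
  and the realized response at the cutoff is 0.50–0.51 for lengths 50–400.
* **Missing rings.** A width of 0 is a structural zero, not a growth
  observation: those years get weight 0 in the fit, an interpolated trend
  value, and index exactly 0 by rule. Trend values are floored at
  0.001 mm so indices stay finite.

Site chronologies are Tukey biweight robust means across trees (tuning
constant $c = 9$, centred at the median, scale fixed at the MAD, iterated
to $10^{-8}$). With one or two values the arithmetic mean is used; when
the MAD is zero the biweight window degenerates and the median is
returned — this keeps the estimator robust for samples where more than
half the values coincide.

### Event detection

Extreme droughts are found on the seasonal (May–June) mean of scPDSI,
averaged over all grid points in the study window: first differences
$d_t = x_t - x_{t-1}$ are computed over the analysis interval, and years
with $d_t < \mu - k\sigma$ (sample SD, $k = 1.5$) are flagged. $\mu$ and
$\sigma$ come from *all* differences of the interval — a single global
threshold, not a moving window. An event is stamped with the later year of
the differenced pair, i.e. the year the drop occurs. Note that for
Gaussian-like differences roughly $\Phi(-1.5) \approx 7\%$ of years sit
below the threshold by construction; the rule isolates *planted* drops
cleanly only when they are large enough to dominate the variance they
themselves add to $\sigma$ (see the generator notes below).

### Resistance, recovery and aggregation

Records lacking a complete 4-year pre- or post-window are flagged
`window_complete = FALSE` and excluded from aggregation rather than
truncated — fixed-window comparability across trees matters more than
keeping edge cases. A missing event-year ring gives $R_t = 0$ exactly; for
$R_c$ the denominator is floored at 0.01 index units, producing large
finite recoveries that are flagged (`dr_floored`), counted in the
high-recovery proportions but excluded from mean recovery, which is
otherwise dominated by a handful of near-zero denominators. The
cross-event comparison of per-tree $R_t$ and $R_c$ distributions uses the
tie-corrected Kruskal–Wallis rank test.

### Growth coherence

Gleichläufigkeit (GLK) between two trees is the mean score over the
year-to-year intervals of an 11-year window centred on the event (5 years
each side): 1 for same-sign changes, 0 for opposite signs, and 0.5 when
either change is exactly zero — the classical tie convention, which
matters for quantized (0.001 mm) widths. Site GLK is the mean over all
unordered pairs fully covering the window; partially covering pairs are
dropped. Mean tree age is ring count to the event year — cores rarely
reach the pith, so this is a relative, not absolute, age.

### Driver regression

One design row per site × event pools all events
($n = \mathrm{sites} \times \mathrm{events}$). The named predictors are
$\Delta\mathrm{PDSI}$ (May–June scPDSI, event year minus preceding year)
and $\Delta\mathrm{DTR}$ (May–July diurnal temperature range, following
year minus event year), alongside event-year seasonal levels of
temperature, precipitation, scPDSI and DTR, plus GLK, mean age and the SD
of indices. The default pool is deliberately seasonal aggregates — about a
dozen candidates against 84 rows; the full 12-month × 6-variable menu is
available behind `full_monthly = TRUE` with a warning.

Selection is the classical threshold-driven forward–backward procedure:
enter the candidate with the smallest partial-F p-value if below 0.1, then
iteratively drop any retained term whose p-value exceeds 0.15. Ties break
by term name so runs are bit-reproducible; selection stops when nothing
qualifies, when degrees of freedom run out, or when the fit is numerically
perfect (p-values on zero residuals are noise). With both thresholds at 1
the procedure reduces to full-model OLS, which the tests verify.
Proportions are regressed untransformed, as the linear response equations
imply; predicted values outside [0, 1] are possible at extreme predictor
values and are not clipped.

### Thiessen mapping

Voronoi cells are built by half-plane intersection in plate-carrée
(longitude/latitude treated as planar) — the usual GIS practice at a
~10° × 11° extent — and clipped to the analysis box. The nearest-site
property is therefore exact in the same planar metric, which keeps the
tiling invariant well defined; cell areas use a local equal-area scaling
(meridian degree length, and parallel degree length at the box's
mid-latitude), so cell areas sum exactly to the box area. "High" area
fractions use a configurable cut (default 0.5) on the site proportions.

## The synthetic region generator

No tree-level measurements are released with the source study, so the
package ships a generator whose defaults *are* the study conditions: 28
sites, 849 trees, juniper-like stands between 28–37.4°N and
90.4–100.8°E, three region-wide droughts (1969, 1979, 1995), chronologies
correlating ≈ 0.47 with May–June scPDSI, and regional high-resistance
proportions falling (71.9 → 55.2 → 39.7%) while high-recovery proportions
rise (28.3 → 52.2 → 64.2%) with a north–south gradient, so the
high-resistance area contracts and the high-recovery area expands.

Design points, each fixed once:

* **Growth model.** Widths are multiplicative-lognormal around a modified
  negative-exponential age curve — the standard generative assumption
  compatible with ratio detrending. Per-tree log-growth mixes a site
  common signal (weight $w$, drawn per site from 0.45–0.75, which drives
  the spread of site GLK) with tree-level noise (total log-SD 0.3).
* **Climate coupling.** The site common signal mixes standardized May–June
  scPDSI with non-climatic site variability. The mixing weight is set from
  the target correlation with two corrections: a closed-form term for
  tree-noise averaging ($\sqrt{w^2 + (1-w^2)/n}/w$) and an empirical
  factor 1.37 for the attenuation caused by the exponential transform and
  by event-window overwrites decoupling part of the correlation interval.
  The factor was fixed by a one-off calibration sweep (50 seeds) and not
  revisited; realized site correlations are 0.48 ± 0.10.
* **Drought magnitudes.** The three events drop May–June scPDSI by 7, 8
  and 9 SDs of the regional first differences. The size is dictated by the
  detection rule itself: planted dips inflate the very $\sigma$ that sets
  the threshold, and below ≈ 6 SD a 44-year series no longer yields the
  three planted years (and nothing else) near-surely. Real scPDSI extremes
  are nowhere near this separable — a stated limitation, not an accident.
  Distinct magnitudes also give the events distinct $\Delta$PDSI levels,
  as real droughts differ in severity. The planted post-drought May–July
  DTR rises (1.0, 0.4, 1.2 °C) are deliberately *not* ordered like the
  drought severities: cloud-cover recovery, not moisture, sets the DTR
  response, and making the two planted signals collinear would confound
  the driver regression by construction.
* **Controlled resistance/recovery.** Event-year suppression and the
  4-year post-event ramp are imposed on the *index* scale: each tree's
  event index is set to $R_t^\* \times$ its realized pre-window mean, and
  the post-window is rescaled to $R_c^\* \times$ the event index, with
  $R_t^\*, R_c^\*$ drawn from high/low uniform groups whose per-event
  means are solved from the target regional means. Group membership is an
  exact count $\mathrm{round}(p \times n)$ per site, so planted
  proportions are recoverable without binomial sampling error; spline
  re-estimation jitters realized $R_t$ by ~1–3%, which the group margins
  (≥ 0.08 index units from the 0.75/1.25 thresholds) absorb.
* **Missing rings.** Base probability 0.002 per year, inflated 15× at
  event years *for low-resistance trees only* — a missing ring is itself
  the extreme low-resistance outcome, and letting it strike planted
  high-resistance trees would silently bias the planted proportions.
* **Seeding.** One master seed feeds a counter-based hierarchy
  (region → site → tree), so adding a site never perturbs other sites'
  draws, and identical configs give byte-identical bundles.
* **Equation response mode.** For regression-recovery studies the per-site
  target proportions can instead be computed from the published-form driver
  equations applied to each site's realized $\Delta$PDSI / $\Delta$DTR and
  expected GLK ($0.5 + \arcsin(w^2)/\pi$), plus Gaussian noise scaled to a
  target $R^2$. This mode pairs naturally with moderate drought magnitudes
  (2–4 SD): at the published coefficients, the 7–9 SD swings needed for
  near-certain detection push predicted proportions outside [0, 1].

### What the generator does *not* emulate

Spatially continuous climate fields (each site has an independent local
deviation), age-dependent drought sensitivity, core-to-tree averaging,
crossdating error, autocorrelated recovery trajectories beyond the 4-year
ramp, and realistic scPDSI tail behaviour (see drought magnitudes above).
Passing tests therefore demonstrate that the *method* recovers known
structure under its own assumptions — not that real juniper networks meet
those assumptions.

## Problem sizes in the test suite

The suite exercises the full 849-tree region once (proportion recovery)
and otherwise uses 3–6-site configurations; selection-recovery and type-I
studies run 100–1000 replicates at the design-matrix level ($n = 84$
rows), where the regression operates. These sizes were chosen as the
smallest at which the respective statistical claims are sharp (binomial
99% CI of ±0.045 at n = 849; selection rates over 100 seeds).

## Known limitations

* The stepwise procedure inherits the usual caveats of threshold-driven
  selection (biased coefficients post-selection, inflated $R^2$); it is
  implemented because it is the method under study, not as a
  recommendation.
* Proportion responses are modelled by untransformed least squares, so
  fitted values are not guaranteed to lie in [0, 1].
* Voronoi geometry is planar in degree space; at 28–38°N a degree of
  longitude shrinks by ~11% across the box, which slightly distorts
  relative cell areas compared with a true equal-area tessellation.
* GLK significance is not assessed, and resilience variants beyond
  resistance/recovery (e.g. the Post/Pre ratio) are intentionally out of
  scope.
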