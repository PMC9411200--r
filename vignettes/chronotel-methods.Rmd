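---
title: "Models and methods behind chronotel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chronotel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chronotel` implements the standard rodent circadian analysis battery on
home-cage telemetry — locomotor activity (LMA) counts and core body
temperature (T_b) in 1-min bins — together with a synthetic telemetry
generator whose presets encode published group phenotypes of germ-free
(GF) versus conventionally raised (SPF) mice. This vignette documents
the models, every tunable parameter with its default and rationale, the
numerical conventions, and the limits of what the validation shows.

## Data model and time conventions

A `TelemetrySeries` holds one subject's uniformly sampled counts and
temperature with a per-bin missing-data mask. Masked bins are excluded
from every downstream mean and sum and are never interpolated: telemetry
dropouts are short and irregular, and imputation would bias the robust
percentiles the episode detector relies on. The per-day usability
threshold of `qualityMask()` defaults to 5% missing, a conservative cap
that keeps daily means essentially unbiased.

Zeitgeber time follows the standard convention: ZT0 = lights-on,
ZT12 = lights-off in a 12L:12D cycle. In constant darkness (DD),
projected ZT (pZT) extrapolates at exactly 24.0 h per cycle from the
last lights-off. A τ-corrected projection is deliberately not used:
pulse times in the underlying protocols are named relative to the prior
photocycle, and after only two cycles of free run the accumulated τ
error (a few minutes) is far below the pulse-timing resolution.
Circadian "days" for daily statistics (FAA, quality flags, phase
summaries) are 24-h blocks anchored at the first ZT0 at or after
recording start.

The file dialect is a UTF-8 CSV `timestamp,lma,tb` with ISO-8601
timestamps and literal `NA` for missing temperature, one file per
subject; lighting and feeding protocols load from a small YAML schema
(see `readScheduleConfig()`). Proprietary binary logger formats are out
of scope.

## The synthetic telemetry model

The generator is the package's validation instrument: it produces data
with exactly the statistical structure the analyses assume, plus ground
truth for recovery tests.

**Phase track.** One true onset per circadian cycle. Under LD, onsets
lock to lights-off + `onsetDelay`. Under DD they drift at `tau` hours
per cycle. After an abrupt shift of the photocycle the onset relaxes
toward the new steady state by `min(reentrainRate, remaining)` per day —
the simplest relaxation consistent with the day-counting re-entrainment
metric. A light pulse at projected ZT p applies the configured phase
shift `prc(p)` once (advance positive), after which drift resumes at
`tau`. Day-to-day Gaussian onset jitter (`onsetJitterSd`) models the
biological imprecision that the onset-variability statistic measures.

**Activity.** Counts per bin are Poisson with rate
`envelope * rateActive + (1 - envelope) * rateRest`, where the envelope
is a square wave of width `alphaTrue` with logistic edges whose 10–90%
width is `rampMin`. Under restricted feeding, a rectangular
food-anticipation component over the 3 h before food onset carries an
expected fraction `faaAsymptote * (1 - exp(-d / faaTauDays))` of the
day's expected total on training day d — a saturating build-up, since
FAA is known to emerge over several days — and re-emerges at the trained
level on deprivation (retention) days.

**Temperature.**
`tb = tbBase + tbCircAmp * envelope + tbActCoupling * MA30(lma) + N(0, tbNoiseSd)`,
with `MA30` a centred 30-min moving average: T_b in rodents combines a
clock-driven circadian component with an acute activity-coupled
component.

**Defaults and their anchoring.** Parameters printed in the source
literature are used directly as preset values: α 12.5 h (SPF) vs 11.5 h
(GF) entrained, 12.7 vs 11.9 h free-running; GF onset delayed a further
10 min; the GF−SPF τ difference +0.04 h (2.4 min/day, inside the
reported 2–3 min/day); a two-fold GF/SPF FAA contrast (asymptotes
0.30 vs 0.15); high-fat-diet variants with τ shortened 0.05 h, baseline
T_b raised 0.45 °C and FAA halved; ex-GF equal to SPF except retained GF
hypothermia. The SPF free-running period defaults to 23.7 h, typical for
C57BL/6 mice. The 24-h mean T_b contrast decomposes as
`Δbase + tbCircAmp·Δα/24` plus an activity-coupling term that cancels
because expected total daily activity is matched across groups
(`rateActive` of the shorter-α group is scaled up); the GF baseline is
therefore *derived* so that the designed contrast equals the reported
0.25 °C rather than set directly.

Magnitudes the literature does not constrain are single realism choices,
fixed once: `rateActive` 20 and `rateRest` 2 counts per 6-min bin
(telemetry units are device-specific, so every analysis is validated to
be scale-invariant); `rampMin` 12 min (nocturnal activity onsets are
sharp); `tbCircAmp` 1.2 °C and `tbNoiseSd` 0.15 °C (typical mouse
telemetry); `tbActCoupling` 0.01 °C per smoothed count; `faaTauDays` 3;
`reentrainRate` 1.0 h/day; PRC {pZT15 → −1.0 h, pZT22 → +0.5 h},
matching the delay/advance geometry of the early- versus late-night
pulse protocol; between-subject Gaussian jitter SDs τ 0.03 h, α 0.15 h,
baseline T_b 0.05 °C; onset jitter 0.05 h (SPF) and 0.03 h (GF, whose
onsets are reported as less variable).

**What the simulator does not emulate** — and hence what recovery tests
cannot show: ultradian bout structure (activity is Poisson within the
envelope), masking by light, cage-change arousal artifacts, seasonal or
ageing trends, and any mechanistic oscillator network. Passing recovery
tests demonstrates that the analysis code measures what it claims on
data satisfying its assumptions; performance on real telemetry with
fragmented rhythms still requires the flagged-cycle reports the detector
emits.

## Episode detection

Detection operates on 6-min re-binned data (the conventional waveform
resolution) smoothed with a 3-bin centred moving average. Per cycle, the
threshold is `thresholdFrac` of the robust amplitude (90th − 10th
percentile of that cycle's smoothed series) above the 10th percentile.
The onset is the first bin inside a ±6 h search window — centred on
lights-off in LD, or the previous onset plus the expected period in
DD — that is supra-threshold, with at least `runOn` (6) of the following
`2·runOn` bins supra-threshold and all `runOff` (4) preceding bins
sub-threshold; the offset is the mirror image in reversed time. The
onset is reported as the start of its bin and the offset as the end of
its bin, so the two edges are treated symmetrically. Cycles with no
qualifying bin — including cycles whose confirmation window would cross
the data edge — return `detected = FALSE` and are excluded with counts
reported; there is no manual-correction step.

`thresholdFrac` defaults to 0.35, calibrated on simulator fixtures and
frozen. A lower threshold (e.g. 0.2) crosses the sigmoid envelope edge
well before its midpoint, inflating α by roughly twice the edge-scale
(~0.25 h at a 12-min ramp) and violating the package's own recovery
requirement (mean absolute α error < 0.15 h over α ∈ 10–13 h); 0.35
keeps the crossing near the edge midpoint while staying robust to
rest-phase Poisson noise. T_b elevation episodes use the same state
machine with the threshold at the midpoint of the cycle's 10th/90th T_b
percentiles.

Onset clock times are unwrapped around their circular mean before the
entrained onset-SD statistic, so rhythms straddling midnight are not
inflated. The free-running onset error is the RMS deviation from the τ
regression line (mean squared residual, not the n−2 variance estimate,
matching the "square-root averaged squared distance" definition).

## Rhythm metrics

**Lomb–Scargle.** Classical Scargle normalization: at each trial
frequency the least-squares sinusoid is fit to the mean-subtracted
unmasked samples via the time-offset form, and its explained sum of
squares is divided by twice the sample variance. This is exactly the
least-squares "goodness of fit" reading of periodogram power, and the
test suite asserts equivalence to an independent `lm()` sinusoid fit at
1e-6 relative tolerance. The scanned band defaults to 20–28 h with 4×
frequency oversampling; the reported statistic is the peak PN in the
band (the conventional single-number reduction). The significance level
maps the false-alarm probability through the independent-frequencies
approximation, `PN_sig = ln(M/fap)` with M the number of independent
frequencies in the band (bandwidth × record length); `fap` defaults to
0.001. A permutation-based threshold was considered and rejected as a
default on cost grounds — the approximation is standard for this
band-limited use.

**Non-parametric amplitude.** The analyzed days are folded into a mean
24-h profile; the M window (default 10 h) maximizes and the L window
(default 5 h) minimizes the circular window mean — the M10/L5
convention, window lengths overridable. Relative amplitude
(M − L)/(M + L) is scale-free; the absolute difference M − L is also
reported since count units are device-specific.

**Profiles and phase summaries.** `dailyProfile()` folds at 24.0 h in LD
or the fitted τ in DD and reports per-bin across-cycle mean ± SEM.
`phaseSummary()` totals counts and averages T_b by photophase/scotophase
(LD, over complete circadian days) or by subjective day/night bounded by
detected episodes (DD), and reports the 24-h mean T_b.

## Phase analysis

**τ** is the OLS slope of detected onset times (absolute hours, hence
already unwrapped) on cycle index; fits outside (20, 28) h are flagged
rather than silently accepted.

**Type II phase shifts.** The pre-pulse regression is extrapolated to
the cycle of the pulse — the pulse night's own onset may be suppressed
by the light pulse, so the projection stands in for it. The post-pulse
rhythm is fit on up to 7 onsets after omitting 3 transient cycles
(at least 6 required) and extrapolated back to the pulse day; the shift
is pre-projection minus post-extrapolation, advances positive, with
whole-cycle ambiguity resolved to the nearest cycle.

**Jet lag.** Daily phase is measured against the mean pre-shift onset
clock time — a clock-time displacement, not a τ-corrected projection,
because the animals are entrained (τ ≈ 24) and the criterion is defined
as a clock displacement. The criterion is a shift of at least
6 − 0.3 h = 95% of the imposed 6-h advance, confirmed on the next
observed day (two-day stability guard) because single-day sporadic
advances occur; the raw first crossing is available by flag. If the
criterion is never met the result is a sentinel ("not re-entrained"
with days observed), not an error. The midpoint basis uses the
centre of mass of activity between onset and offset.

**FAA** is the fraction of a circadian day's counts in the `window`
(default 3 h) before food time: the actual food time on training days,
the expected time (default ZT8) on ad-lib and retention days. The
restricted-feeding generator reproduces the adaptation ramp — day 1
ZT8–16, day 2 ZT8–14, thereafter ZT8–12 — followed by 2 ad-lib days and
a 48-h deprivation; the headline retention statistic is deprivation
day 2. Days with zero counts yield missing values rather than 0/0.

## Statistics

The outlier rule removes values beyond ±3 sample SDs of the measure's
mean in a single pass, pooled across groups — the most conservative
reading of exclusion "from the sample mean" (per-group or iterative
variants would remove more). On Gaussian data this removes ≈ 0.27% of
points. Two-sample comparisons default to the pooled-variance t test
(matching the era of the original analyses; Welch by flag) with Hedges'
g = d·(1 − 3/(4·df − 1)). The two-factor ANOVA uses Type II sums of
squares so unbalanced group sizes do not contaminate main effects
through the interaction. No multiple-testing correction is applied, by
design. The factor layout for FAA across protocol days is reported as
group × day; the original layout is ambiguous and this is the
documented choice.

## Numerical choices and degenerate inputs

Re-binning requires widths that divide 24 h and truncates a trailing
partial window; a window of entirely masked bins stays masked. Constant
series yield no detected episodes (no supra-threshold bin exists under a
strict `>` comparison) and zero periodogram power. Zero-SD samples
exclude no outliers; zero pooled variance with unequal means yields a
flagged infinite t. Folding indices carry a 1e-9 guard against binary
representation error at bin boundaries. All cohort-level randomness
derives from a single base seed through per-subject seeds drawn once,
so outputs are bit-identical across runs and platforms for a fixed
configuration.

## Validation problem sizes

The shipped test-suite checks run at the scale of the study design they
emulate: 12-day LD and 11–12-day DD records at 1-min resolution, 8
subjects per group for recovery of α, α_Tb, τ and the T_b contrast; 10
seeded replicates per pulse phase for PRC recovery; 20 seeded cohorts
(n = 4 per group) for the FAA contrast; 10^6 samples for the Gaussian
behaviour of the outlier rule. These sizes make the whole suite run in
well under a minute while keeping Monte-Carlo error small relative to
each assertion's tolerance.

## Known limitations

ClockLab's proprietary onset operator is undocumented, so numerical
equality with ClockLab output is not claimed — only recovery of
simulator ground truth. The detector's state machine has no
template-matching or change-point alternative. Only the two pulse
phases used by the protocol (pZT15, pZT22) are modelled, not a full
phase-response curve. There is no mixed-effects or repeated-measures
modelling beyond the factorial ANOVA, and no chi-square or
Sokolove–Bushell periodogram or cosinor fit.
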