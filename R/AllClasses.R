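#' @import methods
#' @importFrom stats coef lm median plogis pnorm pt qnorm quantile rnorm rpois
#'   sd setNames t.test var residuals anova
#' @importFrom utils read.csv write.csv head tail modifyList packageVersion
#' @importFrom graphics plot
NULL

#' TelemetrySeries: uniformly sampled telemetry for one subject
#'
#' Container for home-cage telemetry recorded on a uniform grid: locomotor
#' activity (LMA) counts per bin and core body temperature (Tb, degrees
#' Celsius), with a per-bin missing-data mask.  Masked bins are excluded
#' from every downstream mean or sum; they are never interpolated.
#'
#' @slot startTime POSIXct time of the first bin.
#' @slot binWidth bin width in minutes (default 1).
#' @slot lma non-negative activity counts per bin.
#' @slot tb body temperature per bin; NA where unavailable.
#' @slot mask logical per bin, TRUE = masked (excluded downstream).
#' @slot subjectId opaque subject label.
#' @slot groupLabel opaque group label (e.g. "SPF-NC").
#'
#' @name TelemetrySeries-class
#' @rdname TelemetrySeries-class
#' @exportClass TelemetrySeries
setClass("TelemetrySeries",
  representation(
    startTime  = "POSIXct",
    binWidth   = "numeric",
    lma        = "numeric",
    tb         = "numeric",
    mask       = "logical",
    subjectId  = "character",
    groupLabel = "character"
  ),
  prototype(
    binWidth = 1, subjectId = "subject", groupLabel = "group"
  )
)

setValidity("TelemetrySeries", function(object) {
  n <- length(object@lma)
  if (length(object@tb) != n || length(object@mask) != n)
    return("lma, tb and mask must have identical length")
  if (length(object@binWidth) != 1 || object@binWidth <= 0)
    return("binWidth must be a single positive number of minutes")
  ok <- !object@mask & !is.na(object@lma)
  if (any(object@lma[ok] < 0))
    return("lma counts must be non-negative")
  TRUE
})

#' Construct a TelemetrySeries
#'
#' @param lma numeric activity counts per bin.
#' @param tb numeric body temperature per bin (NA allowed).
#' @param binWidth bin width in minutes.
#' @param startTime POSIXct start of the first bin.
#' @param mask logical mask per bin (TRUE = exclude); defaults to masking
#'   bins whose tb is NA only when tb is supplied, otherwise all FALSE.
#' @param subjectId,groupLabel labels.
#' @return A [TelemetrySeries-class] object.
#' @export
TelemetrySeries <- function(lma, tb = rep(NA_real_, length(lma)),
                            binWidth = 1,
                            startTime = as.POSIXct("2020-01-01 00:00:00",
                                                   tz = "UTC"),
                            mask = NULL,
                            subjectId = "subject", groupLabel = "group") {
  if (is.null(mask)) mask <- rep(FALSE, length(lma))
  new("TelemetrySeries", startTime = startTime, binWidth = binWidth,
      lma = as.numeric(lma), tb = as.numeric(tb), mask = as.logical(mask),
      subjectId = subjectId, groupLabel = groupLabel)
}

#' LightSchedule: the lighting protocol of an experiment
#'
#' Ordered segments (LD, DD or LL) tiling the experimental span without gaps,
#' plus discrete light pulses.  Provides the Zeitgeber-time frame: under LD,
#' ZT0 is lights-on and ZT12 lights-off; under DD, projected ZT (pZT)
#' extrapolates at exactly 24 h per cycle from the last lights-off.
#'
#' @slot segments data.frame with columns type ("LD","DD","LL"), start_h,
#'   end_h (hours from schedule start), on_clock, off_clock (clock hours,
#'   NA outside LD).
#' @slot pulses data.frame with columns start_h, duration_min, label.
#' @slot originClock clock hour-of-day at schedule time zero.
#' @slot referenceLightsOff hours-from-start of the lights-off event
#'   anchoring pZT when the schedule begins in DD/LL (NA when the schedule
#'   begins with an LD segment).
#'
#' @name LightSchedule-class
#' @rdname LightSchedule-class
#' @exportClass LightSchedule
setClass("LightSchedule",
  representation(
    segments = "data.frame",
    pulses   = "data.frame",
    originClock = "numeric",
    referenceLightsOff = "numeric"
  )
)

setValidity("LightSchedule", function(object) {
  seg <- object@segments
  need <- c("type", "start_h", "end_h", "on_clock", "off_clock")
  if (!all(need %in% names(seg))) return("segments missing required columns")
  if (nrow(seg) == 0) return("schedule needs at least one segment")
  if (any(seg$end_h <= seg$start_h)) return("segments must have positive span")
  if (nrow(seg) > 1 &&
      any(abs(seg$start_h[-1] - seg$end_h[-nrow(seg)]) > 1e-9))
    return("segments must tile time without gaps or overlap")
  if (nrow(object@pulses) > 0 && any(object@pulses$duration_min <= 0))
    return("pulse duration must be positive")
  TRUE
})

#' FeedingSchedule: daily food availability in Zeitgeber time
#'
#' Day-indexed food-availability windows expressed in ZT hours, with
#' day types distinguishing restricted-feeding training days, ad libitum
#' days and food-deprivation (retention probe) days.
#'
#' @slot days data.frame with columns day (0-based circadian day index),
#'   type ("training","adlib","deprivation"), food_start_zt, food_end_zt
#'   (NA outside training days).
#' @slot expectedFoodZT ZT hour of expected food delivery, used on
#'   retention-trial days.
#'
#' @name FeedingSchedule-class
#' @rdname FeedingSchedule-class
#' @exportClass FeedingSchedule
setClass("FeedingSchedule",
  representation(days = "data.frame", expectedFoodZT = "numeric")
)

setValidity("FeedingSchedule", function(object) {
  d <- object@days
  if (!all(c("day", "type", "food_start_zt", "food_end_zt") %in% names(d)))
    return("days missing required columns")
  tr <- d$type == "training"
  if (any(tr) && (any(d$food_start_zt[tr] < 0 | d$food_start_zt[tr] >= 24)))
    return("feeding windows must lie within [0, 24)")
  if (any(d$type == "deprivation" & !is.na(d$food_start_zt)))
    return("deprivation days must have no feeding window")
  TRUE
})

#' SimConfig: parameterization of the synthetic telemetry model
#'
#' Full parameter set of the simulator: an entrainable phase track drives a
#' square activity envelope (width alphaTrue, sigmoid edges) modulating
#' Poisson counts, and body temperature follows the envelope plus an
#' activity-coupled term with Gaussian noise.  Named presets encode the
#' group-level phenotypes the analysis battery is validated against.
#'
#' @slot label preset name, or "" for hand-built configurations.
#' @slot tau free-running period, hours.
#' @slot onsetDelay hours after lights-off at which activity begins.
#' @slot alphaTrue active-phase duration, hours.
#' @slot rateActive,rateRest expected counts per 6-min bin.
#' @slot rampMin 10-90 percent width of the sigmoid envelope edge, minutes.
#' @slot prc named numeric mapping pulse pZT (hours, names) to phase shift
#'   (hours, advance positive).
#' @slot reentrainRate hours of phase adjustment per day after a shift of
#'   the photocycle.
#' @slot faaAsymptote steady-state fraction of expected daily activity
#'   carried by the food-anticipation component.
#' @slot faaTauDays e-folding build-up constant of FAA over RF days.
#' @slot tbBase,tbCircAmp baseline and envelope-driven Tb, degrees C.
#' @slot tbActCoupling degrees C per smoothed activity count.
#' @slot tbNoiseSd Gaussian Tb noise SD, degrees C.
#' @slot onsetJitterSd day-to-day Gaussian jitter of the realized onset
#'   around the phase track, hours (0 = deterministic track).
#' @slot jitterTauSd,jitterAlphaSd,jitterTbBaseSd between-subject SDs used
#'   by [simulateCohort()].
#'
#' @name SimConfig-class
#' @rdname SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    label = "character",
    tau = "numeric", onsetDelay = "numeric", alphaTrue = "numeric",
    rateActive = "numeric", rateRest = "numeric", rampMin = "numeric",
    prc = "numeric", reentrainRate = "numeric",
    faaAsymptote = "numeric", faaTauDays = "numeric",
    tbBase = "numeric", tbCircAmp = "numeric",
    tbActCoupling = "numeric", tbNoiseSd = "numeric",
    onsetJitterSd = "numeric",
    jitterTauSd = "numeric", jitterAlphaSd = "numeric",
    jitterTbBaseSd = "numeric"
  ),
  prototype(
    label = "", tau = 23.7, onsetDelay = 0.1, alphaTrue = 12.5,
    rateActive = 20, rateRest = 2, rampMin = 12,
    prc = c("15" = -1.0, "22" = 0.5), reentrainRate = 1.0,
    faaAsymptote = 0, faaTauDays = 3,
    tbBase = 36.2, tbCircAmp = 1.2, tbActCoupling = 0.01, tbNoiseSd = 0.15,
    onsetJitterSd = 0,
    jitterTauSd = 0.03, jitterAlphaSd = 0.15, jitterTbBaseSd = 0.05
  )
)

setValidity("SimConfig", function(object) {
  if (object@tau <= 20 || object@tau >= 28)
    return("tau must lie in (20, 28) hours")
  if (object@alphaTrue <= 0 || object@alphaTrue >= 24)
    return("alphaTrue must lie in (0, 24) hours")
  if (object@rateActive < 0 || object@rateRest < 0)
    return("activity rates must be non-negative")
  if (object@faaAsymptote < 0 || object@faaAsymptote > 1)
    return("faaAsymptote must lie in [0, 1]")
  if (object@tbNoiseSd < 0) return("tbNoiseSd must be non-negative")
  TRUE
})

#' DetectionParams: tuning of the onset/offset state machine
#'
#' Detection operates on re-binned, moving-average-smoothed data.  The
#' per-cycle threshold is thresholdFrac of the robust daily amplitude
#' (90th minus 10th percentile) above the 10th percentile; an onset needs
#' sustained supra-threshold activity ahead and quiescence behind.
#'
#' @slot binWidth working bin width in minutes (default 6).
#' @slot smoothBins width of the centred moving average, bins.
#' @slot thresholdFrac fraction of the robust amplitude, in (0, 1).
#' @slot runOn bins of sustained supra-threshold activity required.
#' @slot runOff bins of sub-threshold quiescence required on the far side.
#' @slot searchWindowH half-width of the search window around the expected
#'   onset, hours.
#'
#' @name DetectionParams-class
#' @rdname DetectionParams-class
#' @exportClass DetectionParams
setClass("DetectionParams",
  representation(
    binWidth = "numeric", smoothBins = "numeric", thresholdFrac = "numeric",
    runOn = "numeric", runOff = "numeric", searchWindowH = "numeric"
  ),
  prototype(binWidth = 6, smoothBins = 3, thresholdFrac = 0.35,
            runOn = 6, runOff = 4, searchWindowH = 6)
)

setValidity("DetectionParams", function(object) {
  v <- c(object@binWidth, object@smoothBins, object@runOn, object@runOff,
         object@searchWindowH)
  if (any(v <= 0)) return("all detection parameters must be positive")
  if (object@thresholdFrac <= 0 || object@thresholdFrac >= 1)
    return("thresholdFrac must lie in (0, 1)")
  TRUE
})

#' @rdname DetectionParams-class
#' @param binWidth,smoothBins,thresholdFrac,runOn,runOff,searchWindowH see
#'   slot documentation.
#' @export
DetectionParams <- function(binWidth = 6, smoothBins = 3, thresholdFrac = 0.35,
                            runOn = 6, runOff = 4, searchWindowH = 6) {
  new("DetectionParams", binWidth = binWidth, smoothBins = smoothBins,
      thresholdFrac = thresholdFrac, runOn = runOn, runOff = runOff,
      searchWindowH = searchWindowH)
}

#' PeriodogramResult: Lomb-Scargle periodogram of one series
#'
#' Normalized spectral power (PN) over a period grid, the peak in the
#' scanned band, and the power threshold corresponding to the configured
#' false-alarm probability.
#'
#' @slot periods period grid, hours, strictly increasing.
#' @slot pn normalized power per period (dimensionless, >= 0).
#' @slot peakPeriod,peakPn location and height of the band maximum.
#' @slot significancePn power threshold at the false-alarm probability.
#' @slot fap configured false-alarm probability.
#'
#' @name PeriodogramResult-class
#' @rdname PeriodogramResult-class
#' @exportClass PeriodogramResult
setClass("PeriodogramResult",
  representation(periods = "numeric", pn = "numeric",
                 peakPeriod = "numeric", peakPn = "numeric",
                 significancePn = "numeric", fap = "numeric")
)

setValidity("PeriodogramResult", function(object) {
  if (any(diff(object@periods) <= 0)) return("period grid must increase")
  if (any(object@pn < -1e-12)) return("pn must be non-negative")
  if (abs(object@peakPn - max(object@pn)) > 1e-9)
    return("peakPn must equal max(pn)")
  TRUE
})

#' AmplitudeResult: non-parametric circadian amplitude (M/L windows)
#'
#' Mean activity over the most-active and least-active contiguous windows
#' of the folded 24-h profile, and the relative amplitude
#' (M - L) / (M + L).
#'
#' @slot mMean,lMean counts per bin over the most-/least-active window.
#' @slot mWindowStart,lWindowStart window start, hours into the folded day.
#' @slot relativeAmplitude (M - L)/(M + L), in [0, 1] (NA if M + L = 0).
#' @slot absoluteAmplitude M - L in counts per bin (device-unit free
#'   comparisons should use relativeAmplitude).
#'
#' @name AmplitudeResult-class
#' @rdname AmplitudeResult-class
#' @exportClass AmplitudeResult
setClass("AmplitudeResult",
  representation(mMean = "numeric", lMean = "numeric",
                 mWindowStart = "numeric", lWindowStart = "numeric",
                 relativeAmplitude = "numeric", absoluteAmplitude = "numeric")
)

setValidity("AmplitudeResult", function(object) {
  if (!is.na(object@mMean) && !is.na(object@lMean) &&
      (object@mMean < object@lMean - 1e-9 || object@lMean < -1e-9))
    return("must satisfy mMean >= lMean >= 0")
  TRUE
})

#' PhaseSummary: phase-specific activity and temperature totals
#'
#' Totals of activity counts and mean body temperature split by photocycle
#' phase (photophase/scotophase in LD) or by subjective phase (rest rho /
#' active alpha in DD, bounded by detected episodes).
#'
#' @slot darkCounts,lightCounts total counts in the dark/active and
#'   light/rest phase over the analyzed days.
#' @slot darkTb,lightTb mean Tb per phase, degrees C.
#' @slot meanTb 24-h mean Tb over the analyzed span, degrees C.
#' @slot labels character of length 2 naming the two phases.
#' @slot nDays number of analyzed days/cycles.
#'
#' @name PhaseSummary-class
#' @rdname PhaseSummary-class
#' @exportClass PhaseSummary
setClass("PhaseSummary",
  representation(darkCounts = "numeric", lightCounts = "numeric",
                 darkTb = "numeric", lightTb = "numeric", meanTb = "numeric",
                 labels = "character", nDays = "numeric")
)

#' RegressionFit: free-running period from an onset regression
#'
#' Ordinary least-squares fit of successive onset times (hours, unwrapped)
#' against cycle index; the slope is the free-running period tau.
#'
#' @slot tau slope, hours per cycle.
#' @slot intercept fitted onset at cycle 0, hours.
#' @slot nOnsets number of onsets entering the fit.
#' @slot rmsError root-mean-square onset deviation from the line, hours.
#' @slot accepted FALSE when tau falls outside (20, 28) h.
#' @slot cycles,residuals per-onset cycle indices and residuals.
#'
#' @name RegressionFit-class
#' @rdname RegressionFit-class
#' @exportClass RegressionFit
setClass("RegressionFit",
  representation(tau = "numeric", intercept = "numeric", nOnsets = "numeric",
                 rmsError = "numeric", accepted = "logical",
                 cycles = "numeric", residuals = "numeric")
)

#' PhaseShiftResult: Aschoff Type II light-pulse phase shift
#'
#' @slot shift hours; advances positive, delays negative.
#' @slot pulsePzt projected ZT of the pulse, hours.
#' @slot nPostOnsets onsets entering the post-pulse regression.
#' @slot transientsOmitted post-pulse transient cycles discarded.
#'
#' @name PhaseShiftResult-class
#' @rdname PhaseShiftResult-class
#' @exportClass PhaseShiftResult
setClass("PhaseShiftResult",
  representation(shift = "numeric", pulsePzt = "numeric",
                 nPostOnsets = "numeric", transientsOmitted = "numeric")
)

#' ReentrainmentResult: days to re-entrain after a photocycle shift
#'
#' The criterion is a cumulative phase shift of criterionShift - tolerance
#' hours (6 - 0.3 h, i.e. 95 percent of a 6-h shift, by default), held for
#' two consecutive days unless the stability guard is disabled.
#'
#' @slot daysToCriterion first post-shift day meeting the criterion
#'   (NA when never met within the observed track).
#' @slot criterionShift,tolerance hours.
#' @slot basis "onset" or "midpoint".
#' @slot dailyShifts achieved shift per post-shift day, hours.
#' @slot reentrained logical.
#'
#' @name ReentrainmentResult-class
#' @rdname ReentrainmentResult-class
#' @exportClass ReentrainmentResult
setClass("ReentrainmentResult",
  representation(daysToCriterion = "numeric", criterionShift = "numeric",
                 tolerance = "numeric", basis = "character",
                 dailyShifts = "numeric", reentrained = "logical")
)
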