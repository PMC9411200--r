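#' @describeIn TelemetrySeries-class activity counts per bin.
#' @param x a TelemetrySeries.
#' @export
setMethod("lma", "TelemetrySeries", function(x) x@lma)

#' @describeIn TelemetrySeries-class body temperature per bin.
#' @export
setMethod("tb", "TelemetrySeries", function(x) x@tb)

#' @describeIn TelemetrySeries-class logical mask (TRUE = excluded).
#' @export
setMethod("seriesMask", "TelemetrySeries", function(x) x@mask)

#' @describeIn TelemetrySeries-class bin width in minutes.
#' @export
setMethod("binWidth", "TelemetrySeries", function(x) x@binWidth)

#' @describeIn TelemetrySeries-class number of bins.
#' @export
setMethod("nBins", "TelemetrySeries", function(x) length(x@lma))

#' @describeIn TelemetrySeries-class covered duration in hours
#'   (bin count times bin width, exactly).
#' @export
setMethod("spanHours", "TelemetrySeries",
          function(x) length(x@lma) * x@binWidth / 60)

#' @describeIn TelemetrySeries-class bin start times in hours from
#'   series start.
#' @export
setMethod("timeHours", "TelemetrySeries",
          function(x) (seq_along(x@lma) - 1) * x@binWidth / 60)

#' @describeIn TelemetrySeries-class subject label.
#' @export
setMethod("subjectId", "TelemetrySeries", function(x) x@subjectId)

#' @describeIn TelemetrySeries-class group label.
#' @export
setMethod("groupLabel", "TelemetrySeries", function(x) x@groupLabel)

setMethod("show", "TelemetrySeries", function(object) {
  cat(sprintf(
    "TelemetrySeries '%s' (%s): %d bins of %g min (%.1f h), %d masked\n",
    object@subjectId, object@groupLabel, length(object@lma),
    object@binWidth, length(object@lma) * object@binWidth / 60,
    sum(object@mask)))
  cat(sprintf("  lma total %.0f; tb %s\n", sum(object@lma[!object@mask]),
              if (all(is.na(object@tb))) "absent" else
                sprintf("mean %.2f degC",
                        mean(object@tb[!object@mask], na.rm = TRUE))))
})

setMethod("show", "LightSchedule", function(object) {
  cat("LightSchedule:\n")
  for (i in seq_len(nrow(object@segments))) {
    s <- object@segments[i, ]
    cat(sprintf("  [%6.1f, %6.1f) h  %s%s\n", s$start_h, s$end_h, s$type,
                if (s$type == "LD")
                  sprintf(" (on %02.0f:00, off %02.0f:00)",
                          s$on_clock, s$off_clock) else ""))
  }
  if (nrow(object@pulses) > 0)
    cat(sprintf("  %d light pulse(s)\n", nrow(object@pulses)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig '%s': tau %.2f h, alpha %.2f h, onset delay %.2f h\n",
    "  rates %.2f/%.2f per 6-min bin, ramp %g min\n",
    "  tb base %.2f, amp %.2f, coupling %.3f, noise %.2f degC\n",
    "  FAA asymptote %.2f (tau %g d), reentrain %.1f h/d\n"),
    object@label, object@tau, object@alphaTrue, object@onsetDelay,
    object@rateActive, object@rateRest, object@rampMin,
    object@tbBase, object@tbCircAmp, object@tbActCoupling, object@tbNoiseSd,
    object@faaAsymptote, object@faaTauDays, object@reentrainRate))
})

setMethod("show", "PeriodogramResult", function(object) {
  cat(sprintf(
    "Lomb-Scargle periodogram: peak PN %.2f at %.2f h (threshold %.2f, FAP %g)\n",
    object@peakPn, object@peakPeriod, object@significancePn, object@fap))
})

#' @describeIn PeriodogramResult-class peak normalized power in the band.
#' @param x a PeriodogramResult.
#' @export
setMethod("peakPower", "PeriodogramResult", function(x) x@peakPn)

#' @describeIn AmplitudeResult-class the relative amplitude (M-L)/(M+L).
#' @param x an AmplitudeResult.
#' @export
setMethod("relativeAmplitude", "AmplitudeResult",
          function(x) x@relativeAmplitude)

setMethod("show", "AmplitudeResult", function(object) {
  cat(sprintf(
    "NPCRA amplitude: M %.2f (start %.1f h), L %.2f (start %.1f h), RA %.3f\n",
    object@mMean, object@mWindowStart, object@lMean, object@lWindowStart,
    object@relativeAmplitude))
})

#' @describeIn RegressionFit-class the fitted free-running period, hours.
#' @param x a RegressionFit.
#' @export
setMethod("tauHours", "RegressionFit", function(x) x@tau)

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf(
    "Onset regression: tau %.3f h over %d onsets, RMS error %.3f h%s\n",
    object@tau, object@nOnsets, object@rmsError,
    if (object@accepted) "" else " [flagged: tau outside (20,28) h]"))
})

setMethod("show", "PhaseShiftResult", function(object) {
  cat(sprintf(
    "Type II phase shift at pZT%.0f: %+.2f h (%s) from %d post onsets, %d transients omitted\n",
    object@pulsePzt, object@shift,
    if (object@shift >= 0) "advance" else "delay",
    object@nPostOnsets, object@transientsOmitted))
})

setMethod("show", "ReentrainmentResult", function(object) {
  cat(sprintf(
    "Re-entrainment (%s basis): %s (criterion %.1f - %.1f h)\n",
    object@basis,
    if (object@reentrained) sprintf("%d days", object@daysToCriterion)
    else sprintf("not re-entrained in %d days", length(object@dailyShifts)),
    object@criterionShift, object@tolerance))
})

setMethod("show", "PhaseSummary", function(object) {
  cat(sprintf(
    "PhaseSummary over %g cycles (%s / %s):\n  counts %  .0f / %.0f; tb %.2f / %.2f degC; 24-h mean tb %.2f degC\n",
    object@nDays, object@labels[1], object@labels[2],
    object@darkCounts, object@lightCounts,
    object@darkTb, object@lightTb, object@meanTb))
})
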