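# Per-cycle onset/offset detection.  The detector works on re-binned,
# smoothed data with a per-cycle robust threshold; an onset needs sustained
# supra-threshold activity ahead and quiescence behind, an offset is the
# mirror image in reversed time.

movingAverageNA <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xs)); cn <- c(0, cumsum(ok))
  half <- (k - 1) / 2
  lo <- pmax(1, seq_len(n) - floor(half))
  hi <- pmin(n, seq_len(n) + ceiling(half))
  num <- cs[hi + 1] - cs[lo]; den <- cn[hi + 1] - cn[lo]
  ifelse(den > 0, num / den, NA_real_)
}

# counts of TRUE in the k elements ending at i (inclusive) / starting at i
runCountBack <- function(b, k) {
  cs <- c(0, cumsum(b))
  n <- length(b)
  i <- seq_len(n)
  cs[i + 1] - cs[pmax(0, i - k) + 1]
}
runCountFwd <- function(b, k) {
  cs <- c(0, cumsum(b))
  n <- length(b)
  i <- seq_len(n)
  cs[pmin(n, i + k - 1) + 1] - cs[i]
}

# Expected-onset search centers, one per cycle.  In LD the center is
# lights-off; in DD it is the previous cycle's (detected or expected)
# onset plus the expected period (chained in detectCore from detected
# onsets).  Returns a data.frame(center, ld).
cycleCenters <- function(schedule, spanH, expectedPeriod) {
  ev <- lightsOffEvents(schedule)
  seg <- schedule@segments
  inLD <- function(t) {
    i <- segmentIndexAt(schedule, min(t, spanH - 1e-9))
    !is.na(i) && seg$type[i] == "LD"
  }
  anchor <- if (seg$type[1] == "LD") {
    ev[ev >= 0][1]
  } else {
    r <- schedule@referenceLightsOff
    r + 24 * ceiling((0 - r) / 24)
  }
  centers <- anchor; ld <- inLD(anchor)
  repeat {
    prev <- tail(centers, 1)
    nxt <- ev[ev > prev + 12 & ev <= prev + 36]
    fromLD <- length(nxt) > 0 && inLD(nxt[1])
    cand <- if (fromLD) nxt[1] else prev + expectedPeriod
    if (cand >= spanH) break
    centers <- c(centers, cand); ld <- c(ld, fromLD)
  }
  data.frame(center = centers, ld = ld)
}

detectCore <- function(values, timesH, centers, params, thresholdFun,
                       channel, expectedPeriod = 24) {
  W <- params@searchWindowH
  runOn <- params@runOn; runOff <- params@runOff
  out <- data.frame(cycle = seq_len(nrow(centers)) - 1,
                    onset_h = NA_real_, offset_h = NA_real_,
                    alpha_h = NA_real_, channel = channel, detected = FALSE)
  center <- centers$center[1]
  for (ci in seq_len(nrow(centers))) {
    if (ci > 1) {
      # LD cycles re-anchor on lights-off; DD cycles chain from the
      # previous detected onset when available
      if (centers$ld[ci]) {
        center <- centers$center[ci]
      } else {
        prev <- if (out$detected[ci - 1]) out$onset_h[ci - 1] else center
        center <- prev + expectedPeriod
      }
    }
    win <- timesH >= center - 12 & timesH < center + 12
    v <- values[win]
    if (sum(!is.na(v)) < length(v) / 2) next
    thr <- thresholdFun(v[!is.na(v)])
    supra <- !is.na(values) & values > thr
    sub <- !is.na(values) & values <= thr
    fwdOn <- runCountFwd(supra, 2 * runOn)
    # quiescence behind excludes the candidate bin itself; the full
    # runOff window must exist, so a cycle truncated by the data edge is
    # flagged undetected rather than mis-timed
    backOffExcl <- c(0, runCountBack(sub, runOff)[-length(sub)])
    candOn <- supra & fwdOn >= runOn & backOffExcl >= runOff
    sWin <- which(timesH >= center - W & timesH <= center + W & candOn)
    if (length(sWin) == 0) next
    i <- sWin[1]
    onset <- timesH[i]
    # offset: mirror image in reversed time, searched ahead of the onset
    backOn <- runCountBack(supra, 2 * runOn)
    fwdOffExcl <- c(runCountFwd(sub, runOff)[-1], 0)
    candOff <- supra & backOn >= runOn & fwdOffExcl >= runOff
    oWin <- which(timesH > onset + 1 & timesH <= onset + 20 & candOff)
    if (length(oWin) == 0) next
    j <- tail(oWin, 1)
    # onset marks the start of the first supra bin, offset the end of the
    # last supra bin, so the two edges are treated symmetrically
    offset <- timesH[j] + params@binWidth / 60
    if (offset <= onset) next
    out$onset_h[ci] <- onset
    out$offset_h[ci] <- offset
    out$alpha_h[ci] <- offset - onset
    out$detected[ci] <- TRUE
  }
  out
}

#' Detect daily activity episodes (onset, offset, alpha)
#'
#' The series is re-binned to the working resolution (default 6 min) and
#' smoothed with a centred moving average.  Per cycle, the threshold is
#' thresholdFrac of that cycle's robust amplitude (90th minus 10th
#' percentile of the smoothed series) above the 10th percentile.  The
#' onset is the first bin inside the search window (centred on lights-off
#' in LD, or the previous onset plus the expected period in DD) with at
#' least runOn of the following 2 runOn bins supra-threshold and all
#' preceding runOff bins sub-threshold; the offset is symmetric in
#' reversed time.  Cycles with no qualifying bin return detected = FALSE.
#'
#' @param series a [TelemetrySeries-class].
#' @param schedule a [LightSchedule-class].
#' @param params a [DetectionParams-class].
#' @param expectedPeriod expected cycle length, hours (default 24).
#' @return data.frame with columns cycle, onset_h, offset_h, alpha_h
#'   (hours from series start), channel, detected.
#' @export
detectEpisodes <- function(series, schedule, params = DetectionParams(),
                           expectedPeriod = 24) {
  span <- spanHours(series)
  if (span < 3 * expectedPeriod) stop("need at least 3 cycles of data")
  work <- if (abs(binWidth(series) - params@binWidth) > 1e-9)
    rebin(series, params@binWidth) else series
  v <- ifelse(seriesMask(work), NA_real_, lma(work))
  sm <- movingAverageNA(v, params@smoothBins)
  t <- timeHours(work)
  centers <- cycleCenters(schedule, span, expectedPeriod)
  frac <- params@thresholdFrac
  thrFun <- function(x) {
    q <- quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
    frac * (q[2] - q[1]) + q[1]
  }
  detectCore(sm, t, centers, params, thrFun, channel = "LMA",
             expectedPeriod = expectedPeriod)
}

#' Detect the nightly elevated body-temperature episode (alpha_Tb)
#'
#' Same state machine as [detectEpisodes()] applied to the smoothed Tb
#' channel, with the per-cycle threshold at the midpoint of that cycle's
#' 10th and 90th Tb percentiles.
#'
#' @inheritParams detectEpisodes
#' @return data.frame of episodes with channel = "TB".
#' @export
detectTbElevation <- function(series, schedule, params = DetectionParams(),
                              expectedPeriod = 24) {
  span <- spanHours(series)
  if (span < 3 * expectedPeriod) stop("need at least 3 cycles of data")
  if (all(is.na(tb(series)) | seriesMask(series)))
    stop("tb channel entirely masked or missing")
  work <- if (abs(binWidth(series) - params@binWidth) > 1e-9)
    rebin(series, params@binWidth) else series
  v <- ifelse(seriesMask(work), NA_real_, tb(work))
  sm <- movingAverageNA(v, params@smoothBins)
  t <- timeHours(work)
  centers <- cycleCenters(schedule, span, expectedPeriod)
  thrFun <- function(x) mean(quantile(x, c(0.1, 0.9), names = FALSE))
  detectCore(sm, t, centers, params, thrFun, channel = "TB",
             expectedPeriod = expectedPeriod)
}

#' Summary of alpha over detected episodes
#'
#' @param episodes data.frame from [detectEpisodes()] or
#'   [detectTbElevation()].
#' @return list with n, mean_h, sd_h, sem_h over detected cycles only.
#' @export
alphaSummary <- function(episodes) {
  a <- episodes$alpha_h[episodes$detected]
  if (length(a) == 0) stop("no detected episodes")
  list(n = length(a), mean_h = mean(a),
       sd_h = if (length(a) > 1) sd(a) else 0,
       sem_h = if (length(a) > 1) sd(a) / sqrt(length(a)) else 0)
}

# clock-time deviations from the circular mean, hours in (-12, 12]
clockDeviations <- function(onsetH) {
  ang <- onsetH / 24 * 2 * pi
  m <- atan2(mean(sin(ang)), mean(cos(ang))) * 24 / (2 * pi)
  ((onsetH - m + 12) %% 24) - 12
}

#' Onset variability under entrainment (SD of onset clock times)
#'
#' Sample SD of the detected onset clock times in hours, after unwrapping
#' across midnight (deviations are taken from the circular mean of the
#' onsets so that a rhythm straddling 00:00 is not inflated).
#'
#' @param episodes data.frame of episodes from an entrained (LD) span.
#' @return SD in hours.
#' @export
onsetVariabilityLD <- function(episodes) {
  on <- episodes$onset_h[episodes$detected]
  if (length(on) < 3) stop("need at least 3 detected onsets")
  sd(clockDeviations(on %% 24))
}

#' Onset error in free run (RMS deviation from the tau regression)
#'
#' Root-mean-square distance of the detected onsets from the fitted
#' free-running regression line, in hours.
#'
#' @param episodes data.frame of episodes the fit was produced from.
#' @param fit a [RegressionFit-class] from [fitTau()].
#' @return RMS error in hours.
#' @export
onsetErrorDD <- function(episodes, fit) {
  det <- episodes[episodes$detected, ]
  if (!setequal(det$cycle, fit@cycles))
    stop("episodes do not match the cycles of the fit")
  res <- det$onset_h - (fit@intercept + fit@tau * det$cycle)
  sqrt(mean(res^2))
}
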