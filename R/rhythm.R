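# Rhythm strength and waveform statistics: Lomb-Scargle periodogram power,
# non-parametric amplitude (M/L windows), folded daily profiles and
# phase-specific summaries.

#' Lomb-Scargle periodogram over a circadian period band
#'
#' Classical Scargle-normalized power: at each trial frequency the
#' least-squares sinusoid is fit to the mean-subtracted unmasked samples
#' (using the time-offset form, so uneven sampling from masking is handled
#' by construction) and its explained sum of squares is normalized by
#' twice the sample variance.  The significance threshold maps the
#' false-alarm probability through the independent-frequencies
#' approximation, PN_sig = ln(M / fap), with M the number of independent
#' frequencies in the scanned band.
#'
#' @param series a [TelemetrySeries-class].
#' @param periodRange scanned band in hours (default c(20, 28)).
#' @param oversample frequency oversampling factor (default 4).
#' @param fap false-alarm probability for the threshold (default 0.001).
#' @param channel "LMA" or "TB".
#' @return A [PeriodogramResult-class].
#' @export
lombScargle <- function(series, periodRange = c(20, 28), oversample = 4,
                        fap = 0.001, channel = c("LMA", "TB")) {
  channel <- match.arg(channel)
  span <- spanHours(series)
  binH <- binWidth(series) / 60
  if (length(periodRange) != 2 || periodRange[1] >= periodRange[2])
    stop("periodRange must be an increasing pair of hours")
  if (periodRange[1] <= 2 * binH || periodRange[2] >= span / 3)
    stop("periodRange must lie inside (2 bins, span/3); need >= 3 cycles")
  x <- if (channel == "LMA") lma(series) else tb(series)
  keep <- !seriesMask(series) & !is.na(x)
  t <- timeHours(series)[keep] + binH / 2
  x <- x[keep]
  xc <- x - mean(x)
  s2 <- var(x)
  f1 <- 1 / periodRange[2]; f2 <- 1 / periodRange[1]
  df <- 1 / (span * oversample)
  freqs <- seq(f1, f2, by = df)
  pn <- vapply(freqs, function(f) {
    if (s2 == 0) return(0)
    w <- 2 * pi * f
    tauOff <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tauOff)); st <- sin(w * (t - tauOff))
    (sum(xc * ct)^2 / sum(ct^2) + sum(xc * st)^2 / sum(st^2)) / (2 * s2)
  }, numeric(1))
  periods <- rev(1 / freqs)
  pn <- rev(pn)
  m <- max(1, round(span * (f2 - f1)))
  new("PeriodogramResult", periods = periods, pn = pn,
      peakPeriod = periods[which.max(pn)], peakPn = max(pn),
      significancePn = log(m / fap), fap = fap)
}

#' Non-parametric circadian amplitude (most/least active windows)
#'
#' The analyzed days are folded into a mean 24-h profile at the series'
#' bin width.  The M window mean is the maximum mean over all contiguous,
#' circularly wrapped windows of `mHours`; the L window mean is the
#' minimum over windows of `lHours` (the M10/L5 convention at the
#' defaults).  Relative amplitude is (M - L)/(M + L).
#'
#' @param series a [TelemetrySeries-class] covering >= 1 full day.
#' @param mHours,lHours window lengths in hours (defaults 10 and 5).
#' @return An [AmplitudeResult-class].
#' @export
npcraAmplitude <- function(series, mHours = 10, lHours = 5) {
  if (mHours > 24 || lHours > 24) stop("windows cannot exceed 24 h")
  bw <- binWidth(series)
  perDay <- as.integer(round(1440 / bw))
  if (nBins(series) < perDay) stop("need at least one full day")
  v <- ifelse(seriesMask(series), NA_real_, lma(series))
  idx <- ((seq_len(nBins(series)) - 1) %% perDay) + 1
  prof <- as.numeric(tapply(v, idx, mean, na.rm = TRUE))
  prof[is.nan(prof)] <- NA_real_
  windowMeans <- function(p, w) {
    nb <- as.integer(round(w * 60 / bw))
    ext <- c(p, p[seq_len(nb - 1)])
    cs <- c(0, cumsum(ext))
    (cs[seq_along(p) + nb] - cs[seq_along(p)]) / nb
  }
  mm <- windowMeans(prof, mHours)
  ll <- windowMeans(prof, lHours)
  iM <- which.max(mm); iL <- which.min(ll)
  mMean <- mm[iM]; lMean <- ll[iL]
  ra <- if (isTRUE(mMean + lMean > 0)) (mMean - lMean) / (mMean + lMean)
        else NA_real_
  new("AmplitudeResult", mMean = mMean, lMean = lMean,
      mWindowStart = (iM - 1) * bw / 60, lWindowStart = (iL - 1) * bw / 60,
      relativeAmplitude = ra, absoluteAmplitude = mMean - lMean)
}

#' Folded daily activity profile (mean and SEM per bin)
#'
#' Folds the series at `foldPeriod` (24.0 h under LD; the fitted tau in
#' DD) and returns the across-cycle mean and SEM per folded bin, masked
#' bins excluded per bin.
#'
#' @param series a [TelemetrySeries-class] covering >= 2 cycles.
#' @param foldPeriod folding period, hours, in (20, 28).
#' @param channel "LMA" or "TB".
#' @return data.frame with columns bin_start_h, mean, sem, n.
#' @export
dailyProfile <- function(series, foldPeriod = 24, channel = c("LMA", "TB")) {
  channel <- match.arg(channel)
  if (foldPeriod <= 20 || foldPeriod >= 28)
    stop("foldPeriod must lie in (20, 28) hours")
  if (spanHours(series) < 2 * foldPeriod) stop("need >= 2 folded cycles")
  bw <- binWidth(series) / 60
  x <- if (channel == "LMA") lma(series) else tb(series)
  x <- ifelse(seriesMask(series), NA_real_, x)
  t <- timeHours(series)
  nb <- as.integer(round(foldPeriod / bw))
  width <- foldPeriod / nb
  bin <- pmin(floor(((t %% foldPeriod) + 1e-9) / width), nb - 1)
  cyc <- floor((t + 1e-9) / foldPeriod)
  # one value per (cycle, folded bin), then mean/SEM across cycles
  key <- interaction(cyc, bin, drop = TRUE)
  perCycle <- tapply(x, key, mean, na.rm = TRUE)
  kb <- as.integer(sub(".*\\.", "", names(perCycle)))
  means <- tapply(perCycle, kb, mean, na.rm = TRUE)
  sems <- tapply(perCycle, kb, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  })
  ns <- tapply(perCycle, kb, function(v) sum(!is.na(v)))
  ob <- as.integer(names(means))
  data.frame(bin_start_h = ob * width, mean = as.numeric(means),
             sem = as.numeric(sems), n = as.integer(ns))[order(ob), ]
}

#' Phase-specific activity totals and temperature means
#'
#' Under LD the two phases are the scotophase (ZT12-24) and photophase
#' (ZT0-12) over complete circadian days.  Under DD the subjective night
#' is each detected onset-to-offset episode and the subjective day the
#' interval from offset to the next onset, so episodes must be supplied.
#' Also reports the 24-h mean Tb over the analyzed span.
#'
#' @param series a [TelemetrySeries-class].
#' @param schedule a [LightSchedule-class].
#' @param episodes episode data.frame; required when the analyzed span is
#'   in DD.
#' @return A [PhaseSummary-class].
#' @export
phaseSummary <- function(series, schedule, episodes = NULL) {
  t <- timeHours(series) + binWidth(series) / 120
  counts <- ifelse(seriesMask(series), 0, lma(series))
  tbv <- ifelse(seriesMask(series), NA_real_, tb(series))
  seg <- schedule@segments
  idx <- segmentIndexAt(schedule, pmin(t, max(seg$end_h) - 1e-9))
  anyDD <- any(seg$type[idx] != "LD", na.rm = TRUE)
  if (!anyDD) {
    day0 <- circadianDayStart(schedule, 0)
    nDays <- floor((spanHours(series) - day0) / 24)
    keep <- t >= day0 & t < day0 + 24 * nDays
    z <- ztOf(t[keep], schedule)$zt
    dark <- z >= 12
    labels <- c("scotophase", "photophase")
    nightSel <- restSel <- rep(FALSE, length(t))
    nightSel[which(keep)[dark]] <- TRUE
    restSel[which(keep)[!dark]] <- TRUE
  } else {
    if (is.null(episodes)) stop("DD phase summary requires episodes")
    det <- episodes[episodes$detected, ]
    det <- det[order(det$onset_h), ]
    if (nrow(det) < 2) stop("need >= 2 detected episodes in DD")
    nightSel <- restSel <- rep(FALSE, length(t))
    nDays <- 0
    for (i in seq_len(nrow(det) - 1)) {
      nightSel <- nightSel | (t >= det$onset_h[i] & t < det$offset_h[i])
      restSel <- restSel | (t >= det$offset_h[i] & t < det$onset_h[i + 1])
      nDays <- nDays + 1
    }
    labels <- c("subjective night", "subjective day")
    keep <- nightSel | restSel
  }
  meanOf <- function(v, sel) {
    v <- v[sel]; v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  new("PhaseSummary",
      darkCounts = sum(counts[nightSel]),
      lightCounts = sum(counts[restSel]),
      darkTb = meanOf(tbv, nightSel),
      lightTb = meanOf(tbv, restSel),
      meanTb = meanOf(tbv, keep),
      labels = labels, nDays = nDays)
}
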