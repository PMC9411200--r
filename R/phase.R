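# Free-running period, light-pulse phase shifts (Aschoff Type II), jet-lag
# re-entrainment, activity midpoints and food-anticipatory activity.
# All functions take the episode tables of detectEpisodes()/
# detectTbElevation(); series times are hours from the schedule start.

#' Free-running period from an onset regression
#'
#' Ordinary least squares of detected onset times (hours, absolute, hence
#' already unwrapped across day boundaries) against cycle index; the slope
#' is the free-running period tau.  The RMS of the residuals is the
#' free-running onset error.
#'
#' @param episodes episode data.frame (detected rows are used).
#' @return A [RegressionFit-class]; `accepted` is FALSE when tau falls
#'   outside (20, 28) h.
#' @export
fitTau <- function(episodes) {
  det <- episodes[episodes$detected, ]
  if (nrow(det) < 3) stop("need at least 3 detected onsets")
  fit <- lm(onset_h ~ cycle, data = det)
  res <- unname(residuals(fit))
  tau <- unname(coef(fit)[2])
  new("RegressionFit", tau = tau, intercept = unname(coef(fit)[1]),
      nOnsets = nrow(det), rmsError = sqrt(mean(res^2)),
      accepted = tau > 20 && tau < 28,
      cycles = det$cycle, residuals = res)
}

#' Aschoff Type II light-pulse phase shift
#'
#' The pre-pulse onset regression is extrapolated to the cycle of the
#' pulse; the post-pulse rhythm is fit on 6-7 onsets after omitting the
#' transient cycles, and extrapolated back to the pulse day.  The shift is
#' the pulse-day onset projected from the pre-pulse track minus the
#' extrapolated post-pulse line (advance positive).  Whole-cycle
#' ambiguity is resolved by matching the post line to the nearest cycle.
#'
#' @param preEpisodes episodes preceding the pulse (>= 3 detected).
#' @param postEpisodes episodes following the pulse.
#' @param pulseTimeH pulse time, hours from series start.
#' @param schedule optional [LightSchedule-class] used to report the pulse
#'   pZT.
#' @param transients post-pulse transient cycles to omit (default 3).
#' @param maxPostOnsets onsets kept after the transients (default 7).
#' @return A [PhaseShiftResult-class].
#' @export
phaseShiftType2 <- function(preEpisodes, postEpisodes, pulseTimeH,
                            schedule = NULL, transients = 3,
                            maxPostOnsets = 7) {
  preFit <- fitTau(preEpisodes)
  post <- postEpisodes[postEpisodes$detected &
                         postEpisodes$onset_h > pulseTimeH, ]
  post <- post[order(post$onset_h), ]
  if (nrow(post) <= transients + 5)
    stop("need at least 6 post-pulse onsets after omitting ", transients,
         " transient cycles")
  post <- post[(transients + 1):min(nrow(post), transients + maxPostOnsets), ]
  pfit <- lm(onset_h ~ cycle, data = post)
  tauPost <- unname(coef(pfit)[2])
  # pulse-day onset projected from the pre-pulse track (the pulse night's
  # own onset may be suppressed by the pulse, so the projection is used)
  kPulse <- floor((pulseTimeH - preFit@intercept) / preFit@tau)
  preOnset <- preFit@intercept + preFit@tau * kPulse
  kStar <- round((preOnset - unname(coef(pfit)[1])) / tauPost)
  postAtPulse <- unname(coef(pfit)[1]) + tauPost * kStar
  pzt <- if (!is.null(schedule)) ztOf(pulseTimeH, schedule)$zt else NA_real_
  new("PhaseShiftResult", shift = preOnset - postAtPulse,
      pulsePzt = pzt, nPostOnsets = nrow(post),
      transientsOmitted = transients)
}

#' Days to re-entrain after a shift of the photocycle
#'
#' The reference phase is the mean pre-shift onset (or midpoint) clock
#' time.  Each post-shift day's achieved shift is the clock-time
#' displacement from that reference (advance positive).  The criterion is
#' a shift of at least criterionShift - tolerance hours (6 - 0.3 h = 95
#' percent of a 6-h shift by default), by default confirmed on the
#' following observed day (stability guard against sporadically advanced
#' single-day onsets).
#'
#' @param episodes episode data.frame; for basis = "midpoint" it must
#'   carry a `midpoint_h` column (see [activityMidpoint()]).
#' @param shiftTimeH hour (from series start) at which the new photocycle
#'   begins.
#' @param shiftImposed imposed shift, hours (default 6, advance).
#' @param tolerance criterion tolerance, hours (default 0.3).
#' @param basis "onset" or "midpoint".
#' @param stabilityGuard require the criterion to hold on the next
#'   observed day as well (default TRUE).
#' @return A [ReentrainmentResult-class]; `daysToCriterion` is NA with
#'   `reentrained = FALSE` when the criterion is never met.
#' @export
reentrainmentDays <- function(episodes, shiftTimeH, shiftImposed = 6,
                              tolerance = 0.3,
                              basis = c("onset", "midpoint"),
                              stabilityGuard = TRUE) {
  basis <- match.arg(basis)
  col <- if (basis == "onset") "onset_h" else "midpoint_h"
  if (!col %in% names(episodes))
    stop("episodes lack the ", col, " column required for basis ", basis)
  det <- episodes[episodes$detected & !is.na(episodes[[col]]), ]
  pre <- det[[col]][det[[col]] < shiftTimeH]
  if (length(pre) < 3) stop("need >= 3 pre-shift cycles for the baseline")
  ang <- pre / 24 * 2 * pi
  m <- atan2(mean(sin(ang)), mean(cos(ang))) * 24 / (2 * pi)
  ref <- (m + mean(((pre %% 24 - m + 12) %% 24) - 12)) %% 24
  postT <- det[[col]][det[[col]] >= shiftTimeH]
  day <- floor((postT - shiftTimeH) / 24) + 1
  # advance positive: phase marker moves to an earlier clock time
  shift <- ((ref - postT %% 24 + 12) %% 24) - 12
  dailyShifts <- rep(NA_real_, max(day, 0))
  dailyShifts[day] <- shift
  crit <- shiftImposed - tolerance
  okDays <- which(!is.na(dailyShifts) & dailyShifts >= crit)
  hit <- NA_real_
  for (d in okDays) {
    nxt <- which(!is.na(dailyShifts) & seq_along(dailyShifts) > d)
    if (!stabilityGuard || length(nxt) == 0 ||
        dailyShifts[nxt[1]] >= crit) { hit <- d; break }
  }
  new("ReentrainmentResult", daysToCriterion = hit,
      criterionShift = shiftImposed, tolerance = tolerance, basis = basis,
      dailyShifts = dailyShifts, reentrained = !is.na(hit))
}

#' Per-cycle midpoint of locomotor activity
#'
#' Centre of mass of the activity between each detected onset and offset,
#' in hours from series start.
#'
#' @param series a [TelemetrySeries-class].
#' @param episodes episode data.frame for the same series.
#' @return the episodes data.frame with a `midpoint_h` column added
#'   (NA for undetected cycles).
#' @export
activityMidpoint <- function(series, episodes) {
  t <- timeHours(series) + binWidth(series) / 120  # bin centres
  counts <- ifelse(seriesMask(series), 0, lma(series))
  episodes$midpoint_h <- NA_real_
  for (i in which(episodes$detected)) {
    sel <- t >= episodes$onset_h[i] & t < episodes$offset_h[i]
    w <- counts[sel]
    if (sum(w) > 0)
      episodes$midpoint_h[i] <- sum(t[sel] * w) / sum(w)
  }
  episodes
}

#' Food-anticipatory activity per protocol day
#'
#' FAA is the proportion of the day's activity occurring during the
#' `window` hours immediately before the actual (training days) or
#' expected (ad-lib and retention days) time of food delivery.
#'
#' @param series a [TelemetrySeries-class] starting at schedule time zero.
#' @param light the [LightSchedule-class] anchoring circadian days.
#' @param feeding a [FeedingSchedule-class].
#' @param window hours before food counted as anticipatory (default 3).
#' @return data.frame with columns day, day_type ("training", "adlib",
#'   "retention"), food_zt, faa_fraction (NA for days without counts).
#' @export
faa <- function(series, light, feeding, window = 3) {
  t <- timeHours(series) + binWidth(series) / 120
  counts <- ifelse(seriesMask(series), 0, lma(series))
  d <- feeding@days
  out <- data.frame(day = d$day,
                    day_type = ifelse(d$type == "deprivation", "retention",
                                      d$type),
                    food_zt = ifelse(d$type == "training", d$food_start_zt,
                                     feeding@expectedFoodZT),
                    faa_fraction = NA_real_)
  for (i in seq_len(nrow(d))) {
    dayStart <- circadianDayStart(light, d$day[i])
    inDay <- t >= dayStart & t < dayStart + 24
    if (!any(inDay)) next
    tot <- sum(counts[inDay])
    if (tot <= 0) next
    f0 <- dayStart + out$food_zt[i]
    inWin <- t >= f0 - window & t < f0
    out$faa_fraction[i] <- sum(counts[inWin]) / tot
  }
  out
}
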