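# Synthetic telemetry generator: an entrainable phase track (one onset per
# circadian cycle) drives a square activity envelope with sigmoid edges;
# activity is Poisson per bin and body temperature follows the envelope
# plus an activity-coupled term with Gaussian noise.

# Logistic scale so that rampMin is the 10-90 percent width of the edge.
rampScaleH <- function(rampMin) (rampMin / 60) / (2 * log(9))

# Activity envelope in [0, 1] at times t (hours) for a set of cycle onsets.
envelopeAt <- function(t, onsets, alpha, rampMin) {
  env <- numeric(length(t))
  if (rampMin <= 0) {
    for (o in onsets) env <- env + as.numeric(t >= o & t < o + alpha)
  } else {
    s <- rampScaleH(rampMin)
    for (o in onsets)
      env <- env + (plogis((t - o) / s) - plogis((t - o - alpha) / s))
  }
  pmin(env, 1)
}

prcShift <- function(cfg, pzt) {
  keys <- as.numeric(names(cfg@prc))
  if (length(keys) == 0) return(0)
  d <- abs((pzt - keys + 12) %% 24 - 12)
  if (min(d) > 1.0) return(0)
  unname(cfg@prc[which.min(d)])
}

#' Simulate the circadian phase track
#'
#' Produces one true activity onset per circadian cycle.  Under LD, onsets
#' lock to lights-off + onsetDelay.  After a shift of the photocycle the
#' onset relaxes toward the new steady state by min(reentrainRate,
#' remaining discrepancy) per day.  Under DD, onsets drift at tau hours
#' per cycle; a light pulse at projected ZT p applies the programmed phase
#' shift prc(p) once (advance positive, i.e. subsequent onsets earlier),
#' after which drift resumes at tau.
#'
#' @param cfg a [SimConfig-class].
#' @param light a [LightSchedule-class]; its pulses drive PRC resetting.
#' @return list with `onsets` (hours from schedule start, including one
#'   pre-recording cycle so the first day is in steady state), `truth`
#'   (data.frame cycle, onset, offset, alpha), `pulseShifts` (data.frame
#'   start_h, pzt, shift), and `light`.
#' @export
simulatePhaseTrack <- function(cfg, light) {
  stopifnot(is(cfg, "SimConfig"), is(light, "LightSchedule"))
  span <- max(light@segments$end_h)
  ev <- lightsOffEvents(light)
  # steady state from the start: begin one cycle before recording
  if (length(ev) > 0 && ev[1] >= 0 && ev[1] < 24) {
    o <- ev[1] - 24 + cfg@onsetDelay
  } else if (length(ev) > 0) {
    o <- ev[1] + cfg@onsetDelay       # reference lights-off (DD start)
  } else stop("schedule provides no lights-off anchor")
  onsets <- o
  while (tail(onsets, 1) < span) {
    o <- tail(onsets, 1)
    cand <- ev[ev > o + 12 & ev < span - 1e-9]
    if (length(cand) > 0) {
      target <- cand[1] + cfg@onsetDelay
      natural <- o + 24
      disc <- target - natural
      step <- if (abs(disc) < 1e-9) disc else
        sign(disc) * min(cfg@reentrainRate, abs(disc))
      onsets <- c(onsets, natural + step)
    } else {
      onsets <- c(onsets, o + cfg@tau)
    }
  }
  if (cfg@onsetJitterSd > 0)
    onsets <- onsets + rnorm(length(onsets), 0, cfg@onsetJitterSd)
  pulseShifts <- data.frame(start_h = numeric(0), pzt = numeric(0),
                            shift = numeric(0))
  if (nrow(light@pulses) > 0) {
    for (i in seq_len(nrow(light@pulses))) {
      tp <- light@pulses$start_h[i]
      z <- ztOf(tp, light)
      shift <- prcShift(cfg, z$zt)
      # advance positive: subsequent onsets occur earlier by `shift`
      onsets[onsets > tp] <- onsets[onsets > tp] - shift
      pulseShifts <- rbind(pulseShifts,
                           data.frame(start_h = tp, pzt = z$zt,
                                      shift = shift))
    }
  }
  truth <- data.frame(cycle = seq_along(onsets) - 2,
                      onset = onsets,
                      offset = onsets + cfg@alphaTrue,
                      alpha = cfg@alphaTrue)
  list(onsets = onsets, truth = truth, pulseShifts = pulseShifts,
       light = light, spanH = span)
}

# Expected FAA fraction of the day's total on feeding-protocol day d.
faaFractionOnDay <- function(cfg, feeding) {
  d <- feeding@days
  out <- rep(0, nrow(d))
  trainIdx <- 0
  trained <- 0
  for (i in seq_len(nrow(d))) {
    if (d$type[i] == "training") {
      trainIdx <- trainIdx + 1
      trained <- cfg@faaAsymptote * (1 - exp(-trainIdx / cfg@faaTauDays))
      out[i] <- trained
    } else if (d$type[i] == "deprivation") {
      out[i] <- trained    # retention probe: FAA re-emerges at trained level
    }                      # ad-lib days: food freely available, no FAA drive
  }
  out
}

#' Simulate Poisson activity counts from a phase track
#'
#' Per-bin counts are Poisson with rate envelope * rateActive +
#' (1 - envelope) * rateRest (rates per 6-min bin, scaled to the working
#' bin width).  Under a feeding schedule, a rectangular food-anticipation
#' component over the `window` hours before food availability carries an
#' expected fraction faaAsymptote * (1 - exp(-d / faaTauDays)) of that
#' day's expected total on training day d, re-emerging at the trained
#' level on deprivation (retention) days.
#'
#' @param cfg a [SimConfig-class].
#' @param track result of [simulatePhaseTrack()].
#' @param feeding optional [FeedingSchedule-class].
#' @param binWidth minutes per bin (default 1).
#' @param window FAA window, hours before food (default 3).
#' @return list with `lma` (integer counts), `lambda` (expected counts per
#'   bin) and `faaTruth` (data.frame day, type, faa_true; NULL without a
#'   feeding schedule).  Uses the current RNG stream.
#' @export
simulateActivity <- function(cfg, track, feeding = NULL, binWidth = 1,
                             window = 3) {
  span <- track$spanH
  n <- as.integer(round(span * 60 / binWidth))
  t <- (seq_len(n) - 0.5) * binWidth / 60
  env <- envelopeAt(t, track$onsets, cfg@alphaTrue, cfg@rampMin)
  lam <- (env * cfg@rateActive + (1 - env) * cfg@rateRest) * binWidth / 6
  faaTruth <- NULL
  if (!is.null(feeding)) {
    fr <- faaFractionOnDay(cfg, feeding)
    d <- feeding@days
    for (i in seq_len(nrow(d))) {
      f <- fr[i]
      dayStart <- circadianDayStart(track$light, d$day[i])
      if (dayStart + 24 > span + 1e-9)
        stop("feeding day ", d$day[i], " extends beyond the schedule span")
      if (f <= 0) next
      foodZT <- if (d$type[i] == "training") d$food_start_zt[i] else
        feeding@expectedFoodZT
      inDay <- t >= dayStart & t < dayStart + 24
      inWin <- t >= dayStart + foodZT - window & t < dayStart + foodZT
      base <- sum(lam[inDay])
      extra <- base * f / (1 - f)
      lam[inWin] <- lam[inWin] + extra / sum(inWin)
    }
    faaTruth <- data.frame(day = d$day, type = d$type, faa_true = fr)
  }
  list(lma = rpois(n, lam), lambda = lam, faaTruth = faaTruth)
}

# Centred moving average with shrinking windows at the edges.
movingAverage <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  half <- (k - 1) / 2
  lo <- pmax(1, seq_len(n) - floor(half))
  hi <- pmin(n, seq_len(n) + ceiling(half))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Simulate core body temperature from a phase track and activity
#'
#' tb = tbBase + tbCircAmp * envelope + tbActCoupling * (30-min moving
#' average of activity) + Gaussian(0, tbNoiseSd).
#'
#' @param cfg a [SimConfig-class].
#' @param track result of [simulatePhaseTrack()].
#' @param lma activity counts on the same grid.
#' @param binWidth minutes per bin.
#' @return numeric temperature per bin.  Uses the current RNG stream.
#' @export
simulateTb <- function(cfg, track, lma, binWidth = 1) {
  n <- length(lma)
  t <- (seq_len(n) - 0.5) * binWidth / 60
  env <- envelopeAt(t, track$onsets, cfg@alphaTrue, cfg@rampMin)
  k <- max(1L, as.integer(round(30 / binWidth)))
  ma <- movingAverage(lma, k)
  cfg@tbBase + cfg@tbCircAmp * env + cfg@tbActCoupling * ma +
    rnorm(n, 0, cfg@tbNoiseSd)
}

#' Simulate a cohort of subjects under named presets
#'
#' Subject-level seeds are derived deterministically from `baseSeed`;
#' between-subject variability is Gaussian jitter (SDs carried by the
#' config) on tau, alphaTrue and tbBase only.
#'
#' @param presets character vector of preset names (see [makePreset()]) or
#'   a named list of [SimConfig-class] objects.
#' @param nPerGroup subjects per preset (>= 1).
#' @param baseSeed integer master seed.
#' @param light a [LightSchedule-class] shared by the cohort.
#' @param feeding optional [FeedingSchedule-class].
#' @param binWidth minutes per bin of the emitted series (default 1).
#' @return list of subjects; each element carries `series`
#'   ([TelemetrySeries-class]), `truth` (episode ground truth, pulse
#'   shifts, FAA truth, jittered parameters) and `config`.
#' @export
simulateCohort <- function(presets, nPerGroup, baseSeed, light,
                           feeding = NULL, binWidth = 1) {
  if (nPerGroup < 1) stop("nPerGroup must be >= 1")
  if (is.character(presets))
    presets <- setNames(lapply(presets, makePreset), presets)
  nTotal <- length(presets) * nPerGroup
  set.seed(baseSeed)
  seeds <- sample.int(.Machine$integer.max - 1L, nTotal)
  out <- vector("list", nTotal)
  k <- 0
  for (g in seq_along(presets)) {
    cfg <- presets[[g]]
    gname <- if (!is.null(names(presets))) names(presets)[g] else cfg@label
    for (i in seq_len(nPerGroup)) {
      k <- k + 1
      set.seed(seeds[k])
      cfgi <- cfg
      cfgi@tau <- min(27.9, max(20.1,
        cfg@tau + rnorm(1, 0, cfg@jitterTauSd)))
      cfgi@alphaTrue <- min(23.9, max(0.1,
        cfg@alphaTrue + rnorm(1, 0, cfg@jitterAlphaSd)))
      cfgi@tbBase <- cfg@tbBase + rnorm(1, 0, cfg@jitterTbBaseSd)
      track <- simulatePhaseTrack(cfgi, light)
      act <- simulateActivity(cfgi, track, feeding, binWidth = binWidth)
      tbv <- simulateTb(cfgi, track, act$lma, binWidth = binWidth)
      series <- TelemetrySeries(
        lma = act$lma, tb = tbv, binWidth = binWidth,
        subjectId = sprintf("%s_s%02d", gname, i), groupLabel = gname)
      out[[k]] <- list(
        series = series,
        truth = list(episodes = track$truth,
                     pulseShifts = track$pulseShifts,
                     faa = act$faaTruth,
                     tau = cfgi@tau, alphaTrue = cfgi@alphaTrue,
                     tbBase = cfgi@tbBase),
        config = cfgi)
    }
  }
  out
}
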