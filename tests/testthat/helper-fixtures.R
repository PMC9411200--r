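# Shared fixtures: canonical schedules and hand-built series.

ldSched <- function(days = 12, on = 6, off = 18)
  lightSchedule(list(list(type = "LD", on = on, off = off, days = days)))

ddSched <- function(days = 12, referenceLightsOff = -6, pulses = NULL)
  lightSchedule(list(list(type = "DD", days = days)), pulses = pulses,
                referenceLightsOff = referenceLightsOff)

# Deterministic square-wave activity: `high` counts per bin while active
# (onClock to onClock + alpha each day), `low` otherwise.
squareSeries <- function(days = 5, onClock = 18, alpha = 12, high = 30,
                         low = 0, bw = 6, tbHigh = NA, tbLow = NA) {
  n <- days * as.integer(1440 / bw)
  t <- (seq_len(n) - 0.5) * bw / 60
  active <- (t %% 24) >= onClock | (t %% 24) < (onClock + alpha - 24)
  if (onClock + alpha <= 24)
    active <- (t %% 24) >= onClock & (t %% 24) < onClock + alpha
  tbv <- if (is.na(tbHigh)) rep(NA_real_, n) else
    ifelse(active, tbHigh, tbLow)
  TelemetrySeries(lma = ifelse(active, high, low), tb = tbv, binWidth = bw)
}

# One simulated subject under a preset, returning series plus ground truth.
simSubject <- function(preset, light, feeding = NULL, seed = 1,
                       tweak = identity) {
  cfg <- tweak(makePreset(preset))
  set.seed(seed)
  tr <- simulatePhaseTrack(cfg, light)
  act <- simulateActivity(cfg, tr, feeding)
  tbv <- simulateTb(cfg, tr, act$lma)
  list(series = TelemetrySeries(act$lma, tbv), track = tr, cfg = cfg,
       faaTruth = act$faaTruth)
}

noJitter <- function(cfg) {
  cfg@onsetJitterSd <- 0
  cfg@jitterTauSd <- 0; cfg@jitterAlphaSd <- 0; cfg@jitterTbBaseSd <- 0
  cfg
}
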