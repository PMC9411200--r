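# Generator: phase track, Poisson activity, Tb model, presets, cohorts.

test_that("phase track drifts at tau in DD and relaxes linearly after a shift", {
  cfg <- noJitter(makePreset("SPF-DD")); cfg@tau <- 24.1; cfg@onsetDelay <- 0
  tr <- simulatePhaseTrack(cfg, ddSched(10))
  expect_equal(diff(tr$onsets), rep(24.1, length(tr$onsets) - 1))

  # 6-h advance, relaxation 1.5 h/day: cumulative shift 1.5, 3, 4.5, 6
  jl <- lightSchedule(list(list(type = "LD", on = 6, off = 18, days = 4),
                           list(type = "LD", on = 0, off = 12, days = 8)))
  cfg2 <- noJitter(makePreset("SPF-LD")); cfg2@reentrainRate <- 1.5
  tr2 <- simulatePhaseTrack(cfg2, jl)
  base <- 18 + cfg2@onsetDelay
  post <- tr2$onsets[tr2$onsets > 96]
  achieved <- (base - post %% 24) %% 24
  expect_equal(achieved[1:5], c(1.5, 3.0, 4.5, 6.0, 6.0))
})

test_that("a light pulse applies the programmed PRC shift once", {
  # prc(15) = -1: all post-pulse onsets 1 h later than the projection
  tp <- -6 + 24 * 4 + 3          # pZT15 on DD cycle 4
  sch <- ddSched(10, pulses = list(list(start_h = tp, duration_min = 15,
                                        label = "p15")))
  cfg <- noJitter(makePreset("SPF-DD"))
  tr <- simulatePhaseTrack(cfg, sch)
  un <- simulatePhaseTrack(cfg, ddSched(10))
  expect_equal(tr$pulseShifts$shift, -1.0)
  expect_equal(round(tr$pulseShifts$pzt, 6), 15)
  d <- tr$onsets - un$onsets[seq_along(tr$onsets)]
  expect_equal(unique(round(d[un$onsets < tp], 9)), 0)
  expect_equal(unique(round(d[un$onsets > tp], 9)), 1.0)
})

test_that("expected daily activity matches the closed-form rate integral", {
  cfg <- noJitter(makePreset("SPF-LD"))
  cfg@rateActive <- 20; cfg@rateRest <- 1; cfg@alphaTrue <- 12
  cfg@rampMin <- 0; cfg@onsetDelay <- 0
  sch <- ldSched(days = 100)
  set.seed(11)
  tr <- simulatePhaseTrack(cfg, sch)
  act <- simulateActivity(cfg, tr, binWidth = 6)
  # 120 active bins at 20 + 120 rest bins at 1 per day
  expected <- 100 * (20 * 120 + 1 * 120)
  total <- sum(act$lma)
  expect_lt(abs(total - expected), 3 * sqrt(expected))

  # a mid-rest bin has rate exactly rest
  cfg@rateRest <- 0
  act0 <- simulateActivity(cfg, simulatePhaseTrack(cfg, ldSched(3)),
                           binWidth = 6)
  midRest <- which(abs(((seq_along(act0$lambda) - 0.5) * 0.1) %% 24 - 12)
                   < 1)  # around clock noon, far from edges
  expect_equal(unique(act0$lambda[midRest]), 0)
})

test_that("FAA component carries the programmed fraction of daily counts", {
  cfg <- noJitter(makePreset("SPF-RF"))
  cfg@faaAsymptote <- 0.2
  nd <- 200
  feed <- rfSchedule(nTrainingDays = nd - 1, adlibDays = 0,
                     deprivationDays = 1)
  sch <- ldSched(days = nd + 1)
  set.seed(13)
  tr <- simulatePhaseTrack(cfg, sch)
  act <- simulateActivity(cfg, tr, feed)
  t <- (seq_along(act$lma) - 0.5) / 60
  # closed-form expected fraction on late days vs realized counts
  fracs <- vapply(150:190, function(day) {
    d0 <- 6 + 24 * day
    inDay <- t >= d0 & t < d0 + 24
    inWin <- t >= d0 + 5 & t < d0 + 8
    sum(act$lma[inWin]) / sum(act$lma[inDay])
  }, numeric(1))
  lamFrac <- vapply(150:190, function(day) {
    d0 <- 6 + 24 * day
    inDay <- t >= d0 & t < d0 + 24
    inWin <- t >= d0 + 5 & t < d0 + 8
    sum(act$lambda[inWin]) / sum(act$lambda[inDay])
  }, numeric(1))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - mean(lamFrac)), 3 * se)
  # programmed component: window rate minus baseline equals f/(1-f) of base
  expect_gt(mean(lamFrac), 0.2)          # asymptote + rest-phase baseline
  expect_lt(mean(lamFrac), 0.25)
  expect_equal(act$faaTruth$faa_true[nd - 2],
               0.2 * (1 - exp(-(nd - 2) / cfg@faaTauDays)))
})

test_that("Tb decomposes into base, envelope amplitude, and noise", {
  cfg <- noJitter(makePreset("SPF-LD"))
  cfg@tbNoiseSd <- 0; cfg@tbActCoupling <- 0; cfg@rampMin <- 0
  sch <- ldSched(3)
  set.seed(3)
  tr <- simulatePhaseTrack(cfg, sch)
  act <- simulateActivity(cfg, tr)
  tbv <- simulateTb(cfg, tr, act$lma)
  t <- (seq_along(tbv) - 0.5) / 60
  act_mid <- abs((t - 18.1) %% 24 - 6) < 4     # inside active phase
  rest_mid <- abs((t - 18.1) %% 24 - 18) < 4   # inside rest phase
  expect_equal(mean(tbv[act_mid]) - mean(tbv[rest_mid]), cfg@tbCircAmp)

  # baseline shifts pass through linearly (noise-free)
  cfg2 <- cfg; cfg2@tbBase <- cfg@tbBase - 0.25
  tb2 <- simulateTb(cfg2, tr, act$lma)
  expect_equal(mean(tbv) - mean(tb2), 0.25)

  # noise SD is recovered on a flat envelope
  cfg3 <- cfg; cfg3@tbCircAmp <- 0; cfg3@tbNoiseSd <- 0.1
  set.seed(5)
  tb3 <- simulateTb(cfg3, tr, act$lma)
  expect_lt(abs(sd(tb3) - 0.1), 0.005)
})

test_that("presets encode the study group parameters", {
  expect_equal(makePreset("SPF-LD")@alphaTrue, 12.5)
  expect_equal(makePreset("GF-LD")@alphaTrue, 11.5)
  expect_equal(makePreset("GF-DD")@alphaTrue, 11.9)
  expect_equal(makePreset("SPF-DD")@alphaTrue, 12.7)
  expect_equal(makePreset("GF-LD")@onsetDelay - makePreset("SPF-LD")@onsetDelay,
               10 / 60)
  expect_equal(makePreset("GF-RF")@faaAsymptote /
                 makePreset("SPF-RF")@faaAsymptote, 2.0)
  expect_equal(makePreset("GF-LD")@tau - makePreset("SPF-LD")@tau, 0.04)
  expect_error(makePreset("SPF-XX"), "registered presets")

  # expected total daily activity is matched across LD groups
  tot <- function(cfg) cfg@rateActive * cfg@alphaTrue +
    cfg@rateRest * (24 - cfg@alphaTrue)
  expect_equal(tot(makePreset("GF-LD")), tot(makePreset("SPF-LD")))

  # designed 24-h mean Tb contrast is 0.25 degC (base + envelope share)
  spf <- makePreset("SPF-LD"); gf <- makePreset("GF-LD")
  designed <- (spf@tbBase - gf@tbBase) +
    spf@tbCircAmp * (spf@alphaTrue - gf@alphaTrue) / 24
  expect_equal(designed, 0.25)
})

test_that("cohorts are seed-deterministic with documented jitter", {
  sch <- ldSched(4)
  a <- simulateCohort("SPF-LD", 2, baseSeed = 99, light = sch)
  b <- simulateCohort("SPF-LD", 2, baseSeed = 99, light = sch)
  expect_identical(lma(a[[1]]$series), lma(b[[1]]$series))
  expect_identical(tb(a[[2]]$series), tb(b[[2]]$series))
  expect_error(simulateCohort("SPF-LD", 0, 1, sch), "nPerGroup")

  cfg <- noJitter(makePreset("SPF-LD"))
  c0 <- simulateCohort(list("SPF-LD" = cfg), 3, baseSeed = 5, light = sch)
  expect_true(all(vapply(c0, function(s) s$truth$tau == cfg@tau,
                         logical(1))))
  expect_true(all(vapply(c0, function(s) s$truth$alphaTrue == cfg@alphaTrue,
                         logical(1))))
})

test_that("noiseless envelope edges give alpha equal to truth exactly", {
  cfg <- noJitter(makePreset("SPF-LD")); cfg@rampMin <- 0
  tr <- simulatePhaseTrack(cfg, ldSched(3))
  expect_equal(tr$truth$alpha, tr$truth$offset - tr$truth$onset)
  expect_equal(unique(tr$truth$alpha), cfg@alphaTrue)
})
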