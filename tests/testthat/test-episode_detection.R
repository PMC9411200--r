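# Onset/offset state machine, alpha, and the two onset-variability
# statistics.

test_that("a noiseless square wave is timed to within one working bin", {
  s <- squareSeries(days = 6, onClock = 18 + 10 / 60, alpha = 12.5,
                    high = 30, low = 0, bw = 6)
  ep <- detectEpisodes(s, ldSched(6))
  det <- ep[ep$detected, ]
  expect_gte(nrow(det), 4)
  expect_true(all(abs(det$onset_h %% 24 - (18 + 10 / 60)) <= 0.1 + 1e-9))
  offClock <- (18 + 10 / 60 + 12.5) %% 24
  expect_true(all(abs(det$offset_h %% 24 - offClock) <= 0.1 + 1e-9))
})

test_that("constant series yield no detected episodes on either channel", {
  s <- TelemetrySeries(lma = rep(5, 4 * 1440), tb = rep(36.5, 4 * 1440))
  epl <- detectEpisodes(s, ldSched(4))
  expect_false(any(epl$detected))
  eptb <- detectTbElevation(s, ldSched(4))
  expect_false(any(eptb$detected))
  expect_error(alphaSummary(epl), "no detected")
})

test_that("fewer than 3 cycles is an error; all-masked tb is an error", {
  short <- TelemetrySeries(lma = rpois(2 * 1440, 3))
  expect_error(detectEpisodes(short, ldSched(2)), "3 cycles")
  s <- squareSeries(days = 4)
  expect_error(detectTbElevation(s, ldSched(4)), "masked or missing")
})

test_that("alpha summary uses detected cycles only", {
  ep <- data.frame(cycle = 0:3, onset_h = c(0, 24, 48, 72),
                   offset_h = c(11, 36, 61, 80),
                   alpha_h = c(11, 12, 13, 8), channel = "LMA",
                   detected = c(TRUE, TRUE, TRUE, FALSE))
  s <- alphaSummary(ep)
  expect_equal(s$n, 3)
  expect_equal(s$mean_h, 12)
  expect_equal(s$sd_h, 1)
  expect_equal(s$sem_h, 1 / sqrt(3))
})

test_that("onset variability is the SD of unwrapped onset clock times", {
  mk <- function(on) data.frame(cycle = seq_along(on) - 1, onset_h = on,
                                offset_h = on + 12, alpha_h = 12,
                                channel = "LMA", detected = TRUE)
  expect_equal(onsetVariabilityLD(mk(c(18.0, 42.2, 66.4))), 0.2)
  expect_equal(onsetVariabilityLD(mk(c(18, 42, 66, 90))), 0)
  # a rhythm straddling midnight is not inflated by the wrap
  near <- c(23.9, 24.1 + 24, 23.95 + 48) # clock 23.9, 0.1, 23.95
  expect_lt(onsetVariabilityLD(mk(near)), 0.2)
  expect_error(onsetVariabilityLD(mk(c(18, 42))), "at least 3")
})

test_that("simulated onset jitter is recovered by the LD onset SD", {
  sch <- ldSched(12)
  ests <- vapply(1:20, function(i) {
    sub <- simSubject("SPF-LD", sch, seed = 400 + i, tweak = function(cfg) {
      cfg <- noJitter(cfg); cfg@onsetJitterSd <- 0.1; cfg
    })
    onsetVariabilityLD(detectEpisodes(sub$series, sch))
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.1), 0.03)
})

test_that("onset error in DD is the RMS residual from the tau line", {
  on <- c(0, 24.1, 48.2, 72.3) + c(0.1, -0.1, 0.1, -0.1)
  ep <- data.frame(cycle = 0:3, onset_h = on, offset_h = on + 12,
                   alpha_h = 12, channel = "LMA", detected = TRUE)
  fit <- fitTau(ep)
  # independent brute-force RMS
  brute <- 0
  for (i in 1:4) {
    r <- on[i] - (fit@intercept + fit@tau * (i - 1))
    brute <- brute + r^2
  }
  brute <- sqrt(brute / 4)
  expect_equal(onsetErrorDD(ep, fit), brute)
  expect_equal(fit@rmsError, brute)

  exact <- data.frame(cycle = 0:3, onset_h = c(0, 24.1, 48.2, 72.3),
                      offset_h = c(12, 36, 60, 84), alpha_h = 12,
                      channel = "LMA", detected = TRUE)
  expect_equal(onsetErrorDD(exact, fitTau(exact)), 0)
  expect_error(onsetErrorDD(exact[1:3, ], fit), "match")
})

test_that("Tb elevation detection recovers a noiseless 12-h plateau", {
  s <- squareSeries(days = 5, onClock = 18, alpha = 12, high = 30,
                    tbHigh = 37.4, tbLow = 36.2)
  ep <- detectTbElevation(s, ldSched(5))
  det <- ep[ep$detected, ]
  expect_gte(nrow(det), 3)
  expect_true(all(abs(det$alpha_h - 12) <= 0.2 + 1e-9))
})

test_that("detection is invariant to count rescaling", {
  sub <- simSubject("GF-LD", ldSched(6), seed = 21)
  ep1 <- detectEpisodes(sub$series, ldSched(6))
  scaled <- TelemetrySeries(lma = lma(sub$series) * 7.3,
                            tb = tb(sub$series))
  ep2 <- detectEpisodes(scaled, ldSched(6))
  expect_equal(ep1$onset_h, ep2$onset_h)
  expect_equal(ep1$offset_h, ep2$offset_h)
})

test_that("alpha equals offset minus onset for every detected episode", {
  sub <- simSubject("SPF-DD", ddSched(8), seed = 31)
  ep <- detectEpisodes(sub$series, ddSched(8))
  det <- ep[ep$detected, ]
  expect_true(all(det$offset_h > det$onset_h))
  expect_equal(det$alpha_h, det$offset_h - det$onset_h)
})

test_that("edge fidelity holds for noiseless sigmoid-edged envelopes", {
  cfg <- noJitter(makePreset("SPF-LD"))
  tr <- simulatePhaseTrack(cfg, ldSched(6))
  t <- (seq_len(6 * 1440) - 0.5) / 60
  env <- chronotel:::envelopeAt(t, tr$onsets, cfg@alphaTrue, cfg@rampMin)
  s <- TelemetrySeries(lma = 100 * env)
  ep <- detectEpisodes(s, ldSched(6))
  m <- merge(ep[ep$detected, ], tr$truth, by = "cycle")
  expect_gte(nrow(m), 4)
  expect_true(all(abs(m$onset_h - m$onset) <= 0.1 + 1e-9))
  expect_true(all(abs(m$offset_h - m$offset) <= 0.1 + 1e-9))
})

test_that("mean absolute alpha error stays under 0.15 h across the grid", {
  sch <- ldSched(12)
  errs <- c()
  for (a in c(10, 11, 12, 13)) {
    for (i in 1:3) {
      sub <- simSubject("SPF-LD", sch, seed = 1000 + 10 * a + i,
                        tweak = function(cfg) {
                          cfg <- noJitter(cfg); cfg@alphaTrue <- a
                          cfg@onsetJitterSd <- 0.05; cfg
                        })
      errs <- c(errs,
                abs(alphaSummary(detectEpisodes(sub$series, sch))$mean_h - a))
    }
  }
  expect_lt(mean(errs), 0.15)
})
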