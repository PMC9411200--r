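# Free-running period, Type II phase shifts, jet-lag re-entrainment,
# activity midpoints and FAA.

mkEpisodes <- function(onsets, alpha = 12) {
  data.frame(cycle = seq_along(onsets) - 1, onset_h = onsets,
             offset_h = onsets + alpha, alpha_h = alpha,
             channel = "LMA", detected = TRUE)
}

test_that("tau regression is exact on noiseless onsets", {
  fit <- fitTau(mkEpisodes(c(0, 24.1, 48.2, 72.3)))
  expect_equal(tauHours(fit), 24.1)
  expect_equal(fit@rmsError, 0)
  expect_true(fit@accepted)

  fit24 <- fitTau(mkEpisodes(seq(18, by = 24, length.out = 12)))
  expect_equal(tauHours(fit24), 24.0)

  flagged <- fitTau(mkEpisodes(c(0, 30, 60, 90)))
  expect_false(flagged@accepted)
  expect_error(fitTau(mkEpisodes(c(0, 24))), "at least 3")
})

test_that("tau is recovered within 0.02 h from free-running cohorts", {
  sch <- ddSched(12)
  co <- simulateCohort("GF-DD", 6, baseSeed = 61, light = sch)
  errs <- vapply(co, function(s) {
    abs(tauHours(fitTau(detectEpisodes(s$series, sch))) - s$truth$tau)
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("Type II shift reads uniform displacements and the null exactly", {
  pre <- mkEpisodes(seq(0, by = 23.7, length.out = 5))
  # post onsets 1.0 h later than the pre-pulse projection -> 1-h delay
  post <- mkEpisodes(seq(23.7 * 5, by = 23.7, length.out = 10) + 1.0)
  post$cycle <- post$cycle + 5
  ps <- phaseShiftType2(pre, post, pulseTime = 23.7 * 4.5)
  expect_equal(ps@shift, -1.0)
  expect_equal(ps@nPostOnsets, 7)
  expect_equal(ps@transientsOmitted, 3)

  postNull <- mkEpisodes(seq(23.7 * 5, by = 23.7, length.out = 10))
  postNull$cycle <- postNull$cycle + 5
  expect_equal(phaseShiftType2(pre, postNull, 23.7 * 4.5)@shift, 0)
  expect_error(phaseShiftType2(pre, postNull[1:7, ], 23.7 * 4.5),
               "at least 6")
})

test_that("programmed PRC shifts are recovered from simulated pulses", {
  for (case in list(list(pzt = 15, shift = -1.0),
                    list(pzt = 22, shift = +0.5))) {
    tp <- -6 + 24 * 5 + (case$pzt - 12)
    sch <- ddSched(17, pulses = list(list(start_h = tp, duration_min = 15,
                                          label = "pulse")))
    rec <- vapply(1:10, function(i) {
      sub <- simSubject("SPF-DD", sch, seed = 700 + i,
                        tweak = function(cfg) {
                          cfg@onsetJitterSd <- 0.05; cfg
                        })
      ep <- detectEpisodes(sub$series, sch)
      pre <- ep[ep$detected & ep$onset_h < tp, ]
      post <- ep[ep$detected & ep$onset_h > tp, ]
      phaseShiftType2(pre, post, tp, schedule = sch)@shift
    }, numeric(1))
    expect_lt(abs(mean(rec) - case$shift), 0.2)
  }
})

test_that("null phase shift on unperturbed free run is within one bin", {
  sch <- ddSched(17)
  tp <- -6 + 24 * 5 + 3
  rec <- vapply(1:6, function(i) {
    sub <- simSubject("SPF-DD", sch, seed = 800 + i)
    ep <- detectEpisodes(sub$series, sch)
    pre <- ep[ep$detected & ep$onset_h < tp, ]
    post <- ep[ep$detected & ep$onset_h > tp, ]
    phaseShiftType2(pre, post, tp)@shift
  }, numeric(1))
  expect_lt(abs(mean(rec)), 0.1 + 1e-9)
})

test_that("re-entrainment day counting follows the 5.7-h criterion", {
  # onsets advancing 1.5 h/day: day 4 is the first at >= 5.7 h
  base <- seq(18, by = 24, length.out = 4)
  adv <- cumsum(rep(1.5, 8)); adv[adv > 6] <- 6
  post <- 18 + 24 * (4:11) - adv
  rr <- reentrainmentDays(mkEpisodes(c(base, post)), shiftTimeH = 96)
  expect_equal(rr@daysToCriterion, 4)
  expect_equal((rr@criterionShift - rr@tolerance) / rr@criterionShift, 0.95)

  # full shift achieved on day 1 and held
  post1 <- 18 + 24 * (4:9) - 6
  expect_equal(reentrainmentDays(mkEpisodes(c(base, post1)),
                                 96)@daysToCriterion, 1)

  # closed form ceil(5.7/k) under linear relaxation
  for (k in c(0.5, 1, 1.5, 2, 3)) {
    advk <- pmin(cumsum(rep(k, 16)), 6)
    postk <- 18 + 24 * (4:19) - advk
    rr <- reentrainmentDays(mkEpisodes(c(base, postk)), 96)
    expect_equal(rr@daysToCriterion, ceiling(5.7 / k))
  }

  # never re-entrained: sentinel, not an error
  stuck <- 18 + 24 * (4:12) - 1
  rs <- reentrainmentDays(mkEpisodes(c(base, stuck)), 96)
  expect_false(rs@reentrained)
  expect_true(is.na(rs@daysToCriterion))
})

test_that("re-entrainment speeds up with the simulated relaxation rate", {
  days <- vapply(c(0.5, 1.0, 1.5, 3.0), function(rate) {
    jl <- lightSchedule(list(list(type = "LD", on = 6, off = 18, days = 4),
                             list(type = "LD", on = 0, off = 12, days = 15)))
    sub <- simSubject("SPF-LD", jl, seed = 900,
                      tweak = function(cfg) {
                        cfg@reentrainRate <- rate; cfg
                      })
    ep <- detectEpisodes(sub$series, jl)
    reentrainmentDays(ep, shiftTimeH = 96)@daysToCriterion
  }, numeric(1))
  expect_true(all(diff(days) <= 0))
})

test_that("activity midpoints sit at the centre of mass of the night", {
  sq <- squareSeries(days = 4, onClock = 18, alpha = 12, high = 20, low = 0)
  ep <- detectEpisodes(sq, ldSched(4))
  mid <- activityMidpoint(sq, ep)
  det <- mid[mid$detected, ]
  expect_true(all(abs(det$midpoint_h %% 24 - 0) <= 0.2 |
                    abs(det$midpoint_h %% 24 - 24) <= 0.2))

  # a point mass: all counts at clock 20:00
  n <- 4 * 240
  x <- rep(0, n); t <- (seq_len(n) - 1) * 0.1
  x[t %% 24 == 20] <- 50
  x[(t %% 24) >= 18 & (t %% 24) < 21] <- x[(t %% 24) >= 18 & (t %% 24) < 21] + 1
  pm <- TelemetrySeries(lma = x, binWidth = 6)
  epp <- data.frame(cycle = 0:3, onset_h = 18 + 24 * (0:3),
                    offset_h = 22 + 24 * (0:3), alpha_h = 4,
                    channel = "LMA", detected = TRUE)
  midp <- activityMidpoint(pm, epp)
  expect_true(all(abs(midp$midpoint_h %% 24 - 20) < 0.25))
})

test_that("onset- and midpoint-based re-entrainment agree within a day", {
  jl <- lightSchedule(list(list(type = "LD", on = 6, off = 18, days = 4),
                           list(type = "LD", on = 0, off = 12, days = 15)))
  diffs <- vapply(1:8, function(i) {
    sub <- simSubject("SPF-LD", jl, seed = 1100 + i)
    ep <- detectEpisodes(sub$series, jl)
    ep <- activityMidpoint(sub$series, ep)
    a <- reentrainmentDays(ep, 96, basis = "onset")@daysToCriterion
    b <- reentrainmentDays(ep, 96, basis = "midpoint")@daysToCriterion
    abs(a - b)
  }, numeric(1))
  expect_true(all(diffs <= 1))
})

test_that("FAA is the fraction of daily counts before food time", {
  feed <- rfSchedule(nTrainingDays = 3, adlibDays = 1, deprivationDays = 2)
  sch <- ldSched(8)
  uniform <- TelemetrySeries(lma = rep(3, 8 * 1440))
  fa <- faa(uniform, sch, feed)
  expect_equal(fa$faa_fraction, rep(3 / 24, 6))
  expect_equal(fa$day_type, c("training", "training", "training",
                              "adlib", "retention", "retention"))
  expect_equal(fa$food_zt[1:3], c(8, 8, 8))

  # all activity inside the pre-food window (ZT5-8 = clock 11-14)
  t <- (seq_len(8 * 1440) - 0.5) / 60
  x <- ifelse(t %% 24 >= 11 & t %% 24 < 14, 10, 0)
  concentrated <- TelemetrySeries(lma = x)
  fc <- faa(concentrated, sch, feed)
  expect_equal(fc$faa_fraction, rep(1, 6))

  # scale invariance and window/complement additivity
  half <- TelemetrySeries(lma = lma(uniform) * 0.5)
  expect_equal(faa(half, sch, feed)$faa_fraction, fa$faa_fraction)
})
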