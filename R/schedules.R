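# Experimental protocol containers and the Zeitgeber-time frame.
# Absolute experiment time is measured in hours from schedule start; clock
# times are hours-of-day in [0, 24).

clockToHours <- function(x) {
  if (is.numeric(x)) return(x %% 24)
  p <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(p, function(q) (as.numeric(q[1]) + as.numeric(q[2]) / 60) %% 24,
         numeric(1))
}

#' Build a LightSchedule
#'
#' Segments tile the experiment in order; each is `LD` (with lights-on and
#' lights-off clock times), `DD` or `LL`, and lasts a whole number of days.
#'
#' @param segments list of lists; each element has `type` ("LD", "DD",
#'   "LL") and `days`, and for LD also `on` and `off` clock times
#'   ("HH:MM" or numeric hours).
#' @param pulses optional data.frame (or list of lists) with columns
#'   `start_h` (hours from schedule start), `duration_min`, `label`.
#' @param originClock clock hour-of-day at schedule time zero (default 0 =
#'   the recording starts at midnight).
#' @param referenceLightsOff hours from schedule start (possibly negative)
#'   of the lights-off event anchoring projected ZT when the schedule opens
#'   in DD/LL.  Ignored when the first segment is LD.
#' @return A [LightSchedule-class] object.
#' @examples
#' sched <- lightSchedule(list(
#'   list(type = "LD", on = "06:00", off = "18:00", days = 12),
#'   list(type = "DD", days = 11)))
#' @export
lightSchedule <- function(segments, pulses = NULL, originClock = 0,
                          referenceLightsOff = NA_real_) {
  seg <- do.call(rbind, lapply(segments, function(s) {
    data.frame(type = s$type,
               days = s$days,
               on_clock = if (identical(s$type, "LD"))
                 clockToHours(s$on) else NA_real_,
               off_clock = if (identical(s$type, "LD"))
                 clockToHours(s$off) else NA_real_)
  }))
  seg$end_h <- cumsum(seg$days) * 24
  seg$start_h <- seg$end_h - seg$days * 24
  seg <- seg[, c("type", "start_h", "end_h", "on_clock", "off_clock")]
  if (is.null(pulses)) {
    pulses <- data.frame(start_h = numeric(0), duration_min = numeric(0),
                         label = character(0))
  } else if (!is.data.frame(pulses)) {
    pulses <- do.call(rbind, lapply(pulses, function(p)
      data.frame(start_h = p$start_h, duration_min = p$duration_min,
                 label = if (is.null(p$label)) "" else p$label)))
  }
  if (seg$type[1] != "LD" && is.na(referenceLightsOff))
    stop("a schedule opening in ", seg$type[1],
         " needs referenceLightsOff to anchor projected ZT")
  new("LightSchedule", segments = seg, pulses = pulses,
      originClock = originClock %% 24,
      referenceLightsOff = referenceLightsOff)
}

# All lights-off event times (hours from start) across LD segments,
# plus the DD anchor when defined.
lightsOffEvents <- function(schedule) {
  seg <- schedule@segments
  ev <- numeric(0)
  if (!is.na(schedule@referenceLightsOff))
    ev <- schedule@referenceLightsOff
  for (i in seq_len(nrow(seg))) {
    if (seg$type[i] != "LD") next
    first <- seg$start_h[i] +
      ((seg$off_clock[i] - (schedule@originClock + seg$start_h[i])) %% 24)
    ev <- c(ev, seq(first, seg$end_h[i] - 1e-9, by = 24))
  }
  sort(ev)
}

lightsOnEvents <- function(schedule) {
  seg <- schedule@segments
  ev <- numeric(0)
  for (i in seq_len(nrow(seg))) {
    if (seg$type[i] != "LD") next
    first <- seg$start_h[i] +
      ((seg$on_clock[i] - (schedule@originClock + seg$start_h[i])) %% 24)
    ev <- c(ev, seq(first, seg$end_h[i] - 1e-9, by = 24))
  }
  sort(ev)
}

segmentIndexAt <- function(schedule, t) {
  seg <- schedule@segments
  idx <- findInterval(t, seg$start_h, rightmost.closed = FALSE)
  idx[t >= seg$end_h[nrow(seg)] + 1e-9] <- NA_integer_
  idx[idx == 0] <- NA_integer_
  pmin(idx, nrow(seg))
}

#' Zeitgeber time of experiment times
#'
#' Under LD, ZT0 is lights-on and ZT12 lights-off.  Under DD (or LL), the
#' projected ZT (pZT) extrapolates at exactly 24.0 h per cycle from the
#' last lights-off event, and `projected` is TRUE.
#'
#' @param t hours from schedule start (vectorized).
#' @param schedule a [LightSchedule-class].
#' @return data.frame with columns `zt` (hours in [0, 24)) and `projected`.
#' @examples
#' sched <- lightSchedule(list(list(type = "LD", on = 6, off = 18, days = 2)))
#' ztOf(18, sched)   # lights-off -> ZT12
#' @export
ztOf <- function(t, schedule) {
  stopifnot(is(schedule, "LightSchedule"))
  if (any(t < -1e-9)) stop("time before schedule start")
  seg <- schedule@segments
  if (any(t > seg$end_h[nrow(seg)] + 1e-9)) stop("time beyond schedule span")
  idx <- segmentIndexAt(schedule, pmin(t, seg$end_h[nrow(seg)] - 1e-9))
  zt <- numeric(length(t))
  proj <- seg$type[idx] != "LD"
  if (any(!proj)) {
    i <- which(!proj)
    zt[i] <- (schedule@originClock + t[i] - seg$on_clock[idx[i]]) %% 24
  }
  if (any(proj)) {
    offs <- lightsOffEvents(schedule)
    i <- which(proj)
    j <- findInterval(t[i] + 1e-9, offs)
    if (any(j == 0))
      stop("no lights-off event precedes t = ", t[i[j == 0][1]],
           "; set referenceLightsOff")
    zt[i] <- (12 + (t[i] - offs[j])) %% 24
  }
  data.frame(zt = zt, projected = proj)
}

# Hours from schedule start at which circadian day `day` (0-based) begins
# (ZT0/pZT0).  Days are 24.0 h by convention, anchored at the first ZT0 at
# or after schedule start.
circadianDayStart <- function(schedule, day = 0) {
  seg <- schedule@segments
  if (seg$type[1] == "LD") {
    t0 <- (seg$on_clock[1] - schedule@originClock) %% 24
  } else {
    t0 <- (schedule@referenceLightsOff + 12) %% 24
  }
  t0 + 24 * day
}

#' Build a FeedingSchedule
#'
#' @param days data.frame with columns `day` (0-based circadian day),
#'   `type` ("training", "adlib", "deprivation"), `food_start_zt`,
#'   `food_end_zt` (NA outside training days).
#' @param expectedFoodZT ZT hour of expected food delivery on
#'   retention-trial (deprivation) days.
#' @return A [FeedingSchedule-class].
#' @export
feedingSchedule <- function(days, expectedFoodZT = 8) {
  new("FeedingSchedule", days = days, expectedFoodZT = expectedFoodZT)
}

#' The restricted-feeding protocol with its adaptation ramp
#'
#' Training day 1 offers food ZT8-ZT16, day 2 ZT8-ZT14, and every further
#' training day ZT8-ZT12 (light phase only).  Training is followed by
#' ad libitum days and then a 48-h total food deprivation (retention probe
#' trial) during which FAA is referenced to the expected food time.
#'
#' @param nTrainingDays number of RF training days (10-12 in practice).
#' @param startDay 0-based circadian day on which RF starts.
#' @param adlibDays ad libitum days after training (default 2).
#' @param deprivationDays days of total food removal (default 2 = 48 h).
#' @param expectedFoodZT expected food time on retention days (default ZT8).
#' @return A [FeedingSchedule-class].
#' @export
rfSchedule <- function(nTrainingDays = 12, startDay = 0, adlibDays = 2,
                       deprivationDays = 2, expectedFoodZT = 8) {
  stopifnot(nTrainingDays >= 1)
  ends <- c(16, 14, rep(12, max(0, nTrainingDays - 2)))[seq_len(nTrainingDays)]
  d <- data.frame(
    day = startDay + seq_len(nTrainingDays) - 1,
    type = "training",
    food_start_zt = 8,
    food_end_zt = ends)
  if (adlibDays > 0)
    d <- rbind(d, data.frame(
      day = startDay + nTrainingDays + seq_len(adlibDays) - 1,
      type = "adlib", food_start_zt = NA_real_, food_end_zt = NA_real_))
  if (deprivationDays > 0)
    d <- rbind(d, data.frame(
      day = startDay + nTrainingDays + adlibDays + seq_len(deprivationDays) - 1,
      type = "deprivation", food_start_zt = NA_real_, food_end_zt = NA_real_))
  feedingSchedule(d, expectedFoodZT = expectedFoodZT)
}

#' Read light and feeding schedules from a YAML/JSON config
#'
#' The config carries a `light` list of segments (`type`, `days`, `on`,
#' `off`), optional `pulses` (`start_h`, `duration_min`, `label`), optional
#' `origin_clock` and `reference_lights_off`, and an optional `feeding`
#' block (`training_days`, `start_day`, `adlib_days`, `deprivation_days`,
#' `expected_food_zt`).
#'
#' @param path path to a YAML (or JSON, which YAML subsumes) file.
#' @return list with elements `light` ([LightSchedule-class]) and
#'   `feeding` ([FeedingSchedule-class] or NULL).
#' @export
readScheduleConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 parses bare `on`/`off` keys as booleans; map them back
  segs <- lapply(cfg$light, function(s) {
    names(s)[names(s) == "TRUE"] <- "on"
    names(s)[names(s) == "FALSE"] <- "off"
    s
  })
  light <- lightSchedule(
    segs,
    pulses = cfg$pulses,
    originClock = if (is.null(cfg$origin_clock)) 0 else
      clockToHours(cfg$origin_clock),
    referenceLightsOff = if (is.null(cfg$reference_lights_off)) NA_real_
      else cfg$reference_lights_off)
  feeding <- NULL
  if (!is.null(cfg$feeding)) {
    f <- cfg$feeding
    feeding <- rfSchedule(
      nTrainingDays = f$training_days,
      startDay = if (is.null(f$start_day)) 0 else f$start_day,
      adlibDays = if (is.null(f$adlib_days)) 2 else f$adlib_days,
      deprivationDays = if (is.null(f$deprivation_days)) 2 else
        f$deprivation_days,
      expectedFoodZT = if (is.null(f$expected_food_zt)) 8 else
        f$expected_food_zt)
  }
  list(light = light, feeding = feeding)
}
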