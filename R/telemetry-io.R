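# Telemetry CSV dialect: UTF-8, header `timestamp,lma,tb`, ISO-8601
# timestamps (bare HH:MM also accepted, wrapping across midnight), literal
# NA for missing tb, one file per subject.

parseTimestamps <- function(x) {
  t <- tryCatch(
    suppressWarnings(as.POSIXct(x, tz = "UTC",
                                tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                               "%Y-%m-%d %H:%M:%OS",
                                               "%Y-%m-%d %H:%M"))),
    error = function(e) NULL)
  if (!is.null(t) && !any(is.na(t))) return(t)
  if (all(grepl("^\\d{1,2}:\\d{2}(:\\d{2})?$", x))) {
    p <- strsplit(x, ":", fixed = TRUE)
    mins <- vapply(p, function(q) as.numeric(q[1]) * 60 + as.numeric(q[2]) +
                     if (length(q) > 2) as.numeric(q[3]) / 60 else 0,
                   numeric(1))
    # wrap past midnight: any backward step is taken as a day boundary
    day <- cumsum(c(0, diff(mins) < 0))
    return(as.POSIXct("2020-01-01", tz = "UTC") + (mins + day * 1440) * 60)
  }
  stop("unparseable timestamps (expect ISO-8601 or HH:MM)")
}

#' Read a telemetry CSV into a TelemetrySeries
#'
#' Expects columns `timestamp,lma,tb` at a constant nominal interval.
#' Rows whose tb is absent or unparseable keep their activity counts and
#' get `NA` temperature; rows whose activity is unparseable are masked.
#' Row order is preserved.
#'
#' @param path file path.
#' @param subjectId,groupLabel labels attached to the series.
#' @return A [TelemetrySeries-class] on a uniform grid.
#' @export
readTelemetry <- function(path, subjectId = basename(path),
                          groupLabel = "group") {
  stopifnot(file.exists(path))
  d <- read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("timestamp", "lma", "tb") %in% names(d)))
    stop("telemetry file needs columns timestamp, lma, tb")
  t <- parseTimestamps(d$timestamp)
  dt <- diff(as.numeric(t))
  if (any(dt == 0)) {
    i <- which(dt == 0)[1] + 1
    stop("duplicate timestamp at row ", i, " (", d$timestamp[i], ")")
  }
  if (any(dt < 0)) stop("non-monotone timestamps")
  if (length(dt) > 0 && any(abs(dt - dt[1]) > 1e-6))
    stop("timestamps not at a constant interval")
  width <- if (length(dt) > 0) dt[1] / 60 else 1
  lmav <- suppressWarnings(as.numeric(d$lma))
  tbv <- suppressWarnings(as.numeric(d$tb))
  TelemetrySeries(lma = ifelse(is.na(lmav), 0, lmav), tb = tbv,
                  binWidth = width, startTime = t[1],
                  mask = is.na(lmav),
                  subjectId = subjectId, groupLabel = groupLabel)
}

#' Write a TelemetrySeries to the telemetry CSV dialect
#'
#' @param series a [TelemetrySeries-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTelemetry <- function(series, path) {
  t <- series@startTime + (seq_len(nBins(series)) - 1) * binWidth(series) * 60
  d <- data.frame(
    timestamp = format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lma = format(series@lma, digits = 15, trim = TRUE, scientific = FALSE),
    tb = ifelse(is.na(series@tb), "NA",
                format(series@tb, digits = 15, trim = TRUE,
                       scientific = FALSE)))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Re-bin a telemetry series to a coarser grid
#'
#' Activity counts are summed within each window; temperature is averaged
#' over the window's unmasked, non-missing bins.  A window whose bins are
#' all masked is itself masked.  Total unmasked counts are conserved.
#'
#' @param series a [TelemetrySeries-class].
#' @param width new bin width in minutes; must be a positive multiple of
#'   the current width and divide 24 h.
#' @return A re-binned [TelemetrySeries-class].
#' @export
rebin <- function(series, width) {
  bw <- binWidth(series)
  f <- width / bw
  if (width <= 0 || abs(f - round(f)) > 1e-9 || (1440 %% width) != 0)
    stop("width must be a positive multiple of binWidth that divides 24 h")
  f <- as.integer(round(f))
  if (f == 1) return(series)
  n <- (nBins(series) %/% f) * f
  g <- rep(seq_len(n %/% f), each = f)
  lmau <- series@lma[seq_len(n)]
  tbu <- series@tb[seq_len(n)]
  masku <- series@mask[seq_len(n)]
  lmau[masku] <- 0
  lma2 <- as.numeric(tapply(lmau, g, sum))
  tbv <- ifelse(masku | is.na(tbu), NA_real_, tbu)
  tb2 <- as.numeric(tapply(tbv, g, function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)))
  mask2 <- as.logical(tapply(masku, g, all))
  TelemetrySeries(lma = lma2, tb = tb2, binWidth = width,
                  startTime = series@startTime, mask = mask2,
                  subjectId = series@subjectId,
                  groupLabel = series@groupLabel)
}

#' Flag usable days by missing-data fraction
#'
#' A day is unusable when the fraction of masked bins among its bins
#' exceeds the threshold.  Days are consecutive 24-h blocks from series
#' start; a trailing partial day is assessed over its available bins.
#'
#' @param series a [TelemetrySeries-class].
#' @param maxMissingFracPerDay threshold fraction (default 0.05).
#' @return logical vector, one element per day, TRUE = usable.
#' @export
qualityMask <- function(series, maxMissingFracPerDay = 0.05) {
  perDay <- as.integer(round(1440 / binWidth(series)))
  stopifnot(nBins(series) >= 1)
  day <- (seq_len(nBins(series)) - 1) %/% perDay
  frac <- as.numeric(tapply(series@mask, day, mean))
  frac <= maxMissingFracPerDay
}
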