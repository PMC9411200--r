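#' Double-plotted actogram
#'
#' Draws the conventional chronobiology raster: one row per day, each row
#' spanning 48 h (the day and the following day), activity as vertical
#' bars.  Intended for visual QC of simulated or recorded series.
#'
#' @param series a [TelemetrySeries-class].
#' @param binWidth plotting bin width, minutes (default 6).
#' @param doublePlot span 48 h per row (default TRUE).
#' @param main plot title.
#' @return invisibly, the matrix of plotted day-by-bin activity.
#' @importFrom graphics axis box par rect title
#' @export
plotActogram <- function(series, binWidth = 6, doublePlot = TRUE,
                         main = subjectId(series)) {
  w <- if (abs(binWidth(series) - binWidth) > 1e-9)
    rebin(series, binWidth) else series
  perDay <- as.integer(round(1440 / binWidth))
  nDays <- nBins(w) %/% perDay
  stopifnot(nDays >= 1)
  m <- matrix(lma(w)[seq_len(nDays * perDay)], nrow = nDays,
              ncol = perDay, byrow = TRUE)
  m[matrix(seriesMask(w)[seq_len(nDays * perDay)], nrow = nDays,
           byrow = TRUE)] <- NA
  top <- quantile(m, 0.98, na.rm = TRUE)
  if (top <= 0) top <- 1
  cols <- if (doublePlot) 2 * perDay else perDay
  rows <- if (doublePlot) max(1, nDays - 1) else nDays
  op <- par(mar = c(3, 3, 2, 1))
  on.exit(par(op))
  plot(NA, xlim = c(0, cols * binWidth / 60), ylim = c(rows, 0),
       xlab = "", ylab = "", axes = FALSE)
  axis(1, at = seq(0, cols * binWidth / 60, by = 12))
  axis(2, at = seq_len(rows) - 0.5, labels = seq_len(rows), las = 1)
  title(main = main, xlab = "time (h)", ylab = "day")
  for (d in seq_len(rows)) {
    v <- if (doublePlot) c(m[d, ], if (d < nDays) m[d + 1, ] else
      rep(NA, perDay)) else m[d, ]
    h <- pmin(v / top, 1)
    x0 <- (seq_along(v) - 1) * binWidth / 60
    ok <- !is.na(h) & h > 0
    if (any(ok))
      rect(x0[ok], d, x0[ok] + binWidth / 60, d - h[ok],
           col = "black", border = NA)
  }
  box()
  invisible(m)
}
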