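# small constructors used across test files

makeSubTr <- function(x, rate, source = "magnitude") {
  new("SubTrSignal", samples = as.numeric(x), rate = rate,
      times = (seq_along(x) - 1) / rate, source = source)
}

makeEstimate <- function(f0, band, kind = "cardiac") {
  new("FundamentalEstimate", f0 = f0, band = as.numeric(band),
      excluded = matrix(numeric(), 0, 2,
                        dimnames = list(NULL, c("center", "halfwidth"))),
      kind = kind, nIterations = 1L)
}

makeWaveform <- function(x, rate, f0, kind = "cardiac",
                         source = "magnitude", halfwidth = NULL) {
  if (is.null(halfwidth)) halfwidth <- if (kind == "resp") 2.5 / 60 else 6.5 / 60
  band <- c(f0 - halfwidth, f0 + halfwidth)
  est <- makeEstimate(f0, band, kind)
  new("PhysioWaveform", samples = as.numeric(x), rate = rate,
      times = (seq_along(x) - 1) / rate, band = band, kind = kind,
      source = source, fundamental = est)
}

# linear-interpolation percentile oracle (sort-based)
percentileOracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# a fast small simulation for unit tests
smallConfig <- function(...) {
  args <- list(grid = c(16, 16, 6), mbFactor = 1L, nReps = 200L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthConfig, args)
}
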