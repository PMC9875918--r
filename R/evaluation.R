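#' Lag-aware correlation between two waveforms
#'
#' Maximum normalized (Pearson) cross-correlation over integer-sample lags in
#' `[-maxLag, +maxLag]` seconds, with the lag at which it occurs.  The second
#' input should already be resampled to the first's rate and band-passed with
#' the identical narrowband filter (see [matchExternalToWaveform()]), so the
#' comparison is fair.
#'
#' @param a a [PhysioWaveform-class], [SubTrSignal-class] or numeric vector.
#' @param b numeric vector at the same rate (same length as `a` or longer).
#' @param maxLag maximum lag magnitude in seconds (default 5).
#' @param rate sampling rate in Hz when `a` is a plain vector.
#' @return a list with `corr` (signed correlation at the lag of maximum
#'   absolute correlation) and `lag` (seconds; positive means `b` lags `a`).
#' @export
laggedCorrelation <- function(a, b, maxLag = 5, rate = NULL) {
  if (is(a, "PhysioWaveform") || is(a, "SubTrSignal")) {
    rate <- sampleRate(a); a <- samples(a)
  }
  if (is.null(rate)) stop("rate must be given for plain vectors", call. = FALSE)
  b <- as.numeric(b)
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  maxShift <- floor(maxLag * rate)
  if (n - maxShift < 32L) {
    maxShift <- max(0L, n - 32L)
    warning(sprintf("lag range clipped to +/-%.2f s (too few overlapping samples)",
                    maxShift / rate))
  }
  shifts <- (-maxShift):maxShift
  cors <- vapply(shifts, function(k) {
    if (k >= 0) cor(a[seq_len(n - k)], b[seq_len(n - k) + k])
    else cor(a[seq_len(n + k) - k], b[seq_len(n + k)])
  }, numeric(1))
  best <- which.max(abs(cors))
  list(corr = cors[best], lag = shifts[best] / rate)
}

#' Resample and band-match an external recording to a waveform
#'
#' Linearly interpolates the requested channel of an external recording to
#' the waveform's sample times and applies the waveform's own narrowband
#' zero-phase filter, as required for a fair lag-aware comparison.
#'
#' @param waveform a [PhysioWaveform-class].
#' @param recording an [ExternalRecording-class].
#' @return numeric vector aligned with `sampleTimes(waveform)`.
#' @export
matchExternalToWaveform <- function(waveform, recording) {
  channel <- if (waveform@kind == "resp") recording@resp else recording@cardiac
  tExt <- recording@t0 + (seq_along(channel) - 1) * recording@dt
  y <- approx(tExt, channel, xout = waveform@times, rule = 2)$y
  butterBandpass(y, waveform@rate, waveform@band)
}

#' Flatten a 4D series to a sub-TR signal without detrending
#'
#' Plain slice averaging followed by acquisition-order reordering; used to
#' visualize physiological noise in corrected or uncorrected magnitude data.
#'
#' @param data a 4D array or [EpiSeries-class].
#' @param params an [AcquisitionParams-class] (taken from the series when
#'   omitted).
#' @param mask logical 3D array.
#' @return a [SubTrSignal-class].
#' @export
flattenToSubTr <- function(data, params = NULL, mask) {
  if (is(data, "EpiSeries")) {
    params <- data@params
    data <- data@magnitude
  }
  if (is.null(params)) stop("params required for a plain array", call. = FALSE)
  dm <- dim(data)
  n <- dm[3]; nt <- dm[4]
  vals <- matrix(NA_real_, n, nt)
  for (s in seq_len(n)) {
    sel <- mask[, , s]
    if (!any(sel)) stop(sprintf("slice %d has no masked voxels", s),
                        call. = FALSE)
    vals[s, ] <- colMeans(matrix(data[, , s, ], ncol = nt)[sel, ,
                                                           drop = FALSE])
  }
  avg <- new("SliceSignal", values = vals, trVol = params@trVol,
             source = "magnitude", detrended = FALSE)
  reorderToSubTr(avg, params)
}

#' Sliding-window spectrogram of a sub-TR signal
#'
#' Within each window (45 s, stepped by 4 s, by default) a Welch estimate is
#' formed from three Hann-tapered, mean-removed, 50%-overlapping segments.
#'
#' @param signal a [SubTrSignal-class] with duration >= `window`.
#' @param window window length in seconds.
#' @param step step size in seconds.
#' @param nSegments Welch segments per window.
#' @param db return decibel-scaled power.
#' @return a list with `times` (window centers, s), `freqs` (Hz) and `power`
#'   (matrix `freq x time`).
#' @export
slidingSpectrogram <- function(signal, window = 45, step = 4,
                               nSegments = 3L, db = FALSE) {
  x <- signal@samples; rate <- signal@rate
  winN <- round(window * rate)
  stepN <- max(1L, round(step * rate))
  n <- length(x)
  if (winN > n)
    stop(sprintf("signal duration (%.1f s) shorter than window (%.1f s); use a smaller window",
                 n / rate, window), call. = FALSE)
  starts <- seq(1L, n - winN + 1L, by = stepN)
  segN <- floor(2 * winN / (nSegments + 1))        # 50% overlap
  hop <- floor(segN / 2)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(segN) / (segN + 1))
  u <- mean(taper^2)
  nf <- floor(segN / 2) + 1L
  power <- matrix(0, nf, length(starts))
  for (w in seq_along(starts)) {
    seg0 <- starts[w]
    acc <- numeric(nf)
    for (j in seq_len(nSegments)) {
      i0 <- seg0 + (j - 1L) * hop
      seg <- x[i0:(i0 + segN - 1L)]
      seg <- (seg - mean(seg)) * taper
      p <- Mod(fft(seg))^2 / (segN^2 * u)
      ps <- p[seq_len(nf)]
      ps[2:(nf - 1L)] <- 2 * ps[2:(nf - 1L)]
      acc <- acc + ps
    }
    power[, w] <- acc / nSegments
  }
  freqs <- (seq_len(nf) - 1L) * rate / segN
  times <- signal@times[starts] + window / 2
  if (db) power <- 10 * log10(pmax(power, .Machine$double.xmin))
  list(times = times, freqs = freqs, power = power)
}

# frequency-bin membership of an (aliased) band: bin frequency g (sampled at
# fs) belongs to band [lo, hi] iff some replicate k*fs +/- g falls inside it
aliasedBandBins <- function(freqs, band, fs) {
  kMaxi <- ceiling(band[2] / fs) + 1L
  inBand <- rep(FALSE, length(freqs))
  for (k in 0:kMaxi) {
    inBand <- inBand |
      (k * fs + freqs >= band[1] & k * fs + freqs <= band[2]) |
      (k * fs - freqs >= band[1] & k * fs - freqs <= band[2])
  }
  inBand
}

#' Physiological evaluation bands including harmonics
#'
#' Builds the fundamental band `f0 +/- halfwidth` and, when the second
#' harmonic (or its alias at the volume sampling rate) is separated from the
#' fundamental band by at least one spectral bin, the harmonic band
#' `2*f0 +/- halfwidth`.
#'
#' @param f0 fundamental frequency, Hz.
#' @param halfwidth band halfwidth, Hz.
#' @param fs volume sampling rate `1/trVol`, Hz.
#' @param resolution spectral bin width, Hz.
#' @return list of `[low, high]` bands (on the true, un-aliased scale).
#' @export
physioBands <- function(f0, halfwidth, fs, resolution) {
  bands <- list(c(f0 - halfwidth, f0 + halfwidth))
  alias <- function(f) abs(f - fs * round(f / fs))
  a2 <- alias(2 * f0)
  aLo <- min(alias(bands[[1]][1]), alias(bands[[1]][2]))
  aHi <- max(alias(bands[[1]][1]), alias(bands[[1]][2]))
  sep <- if (a2 >= aLo && a2 <= aHi) 0 else min(abs(a2 - c(aLo, aHi)))
  if (sep >= resolution)
    bands <- c(bands, list(c(2 * f0 - halfwidth, 2 * f0 + halfwidth)))
  bands
}

voxelBandPower <- function(data4d, mask, sliceIdx, binSel) {
  nt <- dim(data4d)[4]
  sel <- mask[, , sliceIdx]
  if (!any(sel)) return(NULL)
  Y <- t(matrix(data4d[, , sliceIdx, ], ncol = nt)[sel, , drop = FALSE])
  Y <- sweep(Y, 2L, colMeans(Y))
  P <- Mod(mvfft(Y))^2 / nt^2
  half <- floor(nt / 2)
  P <- P[seq_len(half + 1L), , drop = FALSE]
  dbl <- 2:(half + if (nt %% 2 == 0) 0L else 1L)
  P[dbl, ] <- 2 * P[dbl, ]
  colSums(P[binSel, , drop = FALSE])
}

#' Proportion of physiological band power removed by a correction
#'
#' Per voxel, `1 - P_after(band) / P_before(band)` from the voxel's
#' periodogram at the volume TR; averaged over each slice.  Bands above the
#' volume Nyquist are mapped to their aliased frequencies before
#' integration.  A value of 1 means total removal; negative values mean the
#' correction added noise.  Voxels with zero in-band power before correction
#' are excluded and counted.
#'
#' @param before,after 4D magnitude arrays (uncorrected / corrected).
#' @param params an [AcquisitionParams-class].
#' @param mask logical 3D array.
#' @param bands list of `[low, high]` Hz bands (true frequencies; see
#'   [physioBands()]).
#' @return a list with `perSlice` (numeric vector of slice-mean proportions),
#'   `overall` (mask-wide mean), `bins` (logical bin selector used) and
#'   `nExcluded`.
#' @export
bandPowerProportion <- function(before, after, params, mask, bands) {
  fs <- 1 / params@trVol
  nt <- dim(before)[4]
  freqs <- (seq_len(floor(nt / 2) + 1L) - 1L) * fs / nt
  binSel <- rep(FALSE, length(freqs))
  for (b in bands) binSel <- binSel | aliasedBandBins(freqs, b, fs)
  binSel[1] <- FALSE                      # DC excluded
  n <- dim(before)[3]
  perSlice <- rep(NA_real_, n)
  allProps <- numeric(); nExcl <- 0L
  for (s in seq_len(n)) {
    pb <- voxelBandPower(before, mask, s, binSel)
    if (is.null(pb)) next
    pa <- voxelBandPower(after, mask, s, binSel)
    ok <- pb > 0
    nExcl <- nExcl + sum(!ok)
    if (!any(ok)) next
    props <- 1 - pa[ok] / pb[ok]
    perSlice[s] <- mean(props)
    allProps <- c(allProps, props)
  }
  list(perSlice = perSlice, overall = mean(allProps), bins = binSel,
       nExcluded = nExcl)
}

#' Out-of-band power fluctuation after a correction
#'
#' The same relative-change statistic as [bandPowerProportion()], computed
#' over all frequencies outside the physiological bands and their harmonics.
#' Values near zero indicate the correction preserved the rest of the
#' signal; negative values mean power was added.
#'
#' @inheritParams bandPowerProportion
#' @return a list with `perSlice`, `overall` and `nExcluded`.
#' @export
outOfBandFluctuation <- function(before, after, params, mask, bands) {
  fs <- 1 / params@trVol
  nt <- dim(before)[4]
  freqs <- (seq_len(floor(nt / 2) + 1L) - 1L) * fs / nt
  binSel <- rep(FALSE, length(freqs))
  for (b in bands) binSel <- binSel | aliasedBandBins(freqs, b, fs)
  outSel <- !binSel
  outSel[1] <- FALSE                      # DC excluded
  n <- dim(before)[3]
  perSlice <- rep(NA_real_, n)
  allProps <- numeric(); nExcl <- 0L
  for (s in seq_len(n)) {
    pb <- voxelBandPower(before, mask, s, outSel)
    if (is.null(pb)) next
    pa <- voxelBandPower(after, mask, s, outSel)
    ok <- pb > 0
    nExcl <- nExcl + sum(!ok)
    if (!any(ok)) next
    props <- 1 - pa[ok] / pb[ok]
    perSlice[s] <- mean(props)
    allProps <- c(allProps, props)
  }
  list(perSlice = perSlice, overall = mean(allProps), nExcluded = nExcl)
}

#' Temporal SNR gain of a correction
#'
#' tSNR is the voxel's temporal mean divided by its temporal standard
#' deviation; the gain map is `100 * (after - before) / before` percent.
#' Optional named ROI masks are summarized by mean gain and quartiles.
#'
#' @param before,after 4D magnitude arrays.
#' @param mask logical 3D array; maps are NA outside it.
#' @param rois optional named list of logical 3D ROI masks.
#' @return a list with `tsnrBefore`, `tsnrAfter`, `gainPercent` (3D arrays),
#'   `roiSummaries` (data.frame) and `nZeroSd`.
#' @export
tsnrGain <- function(before, after, mask, rois = NULL) {
  tsnrMap <- function(x) {
    mu <- rowMeans(x, dims = 3L)
    sdv <- sqrt(pmax(rowMeans(x^2, dims = 3L) - mu^2, 0) *
                  dim(x)[4] / (dim(x)[4] - 1))
    out <- mu / sdv
    out[sdv == 0] <- NA_real_
    out
  }
  tb <- tsnrMap(before); ta <- tsnrMap(after)
  tb[!mask] <- NA_real_; ta[!mask] <- NA_real_
  nZero <- sum(mask & (is.na(tb) | is.na(ta)))
  gain <- 100 * (ta - tb) / tb
  gain[!is.finite(gain)] <- NA_real_
  roiSummaries <- NULL
  if (!is.null(rois)) {
    rows <- lapply(names(rois), function(nm) {
      g <- gain[rois[[nm]] & mask]
      g <- g[!is.na(g)]
      data.frame(roi = nm, meanGain = mean(g),
                 q25 = quantile(g, 0.25, names = FALSE),
                 q50 = quantile(g, 0.50, names = FALSE),
                 q75 = quantile(g, 0.75, names = FALSE))
    })
    roiSummaries <- do.call(rbind, rows)
  }
  list(tsnrBefore = tb, tsnrAfter = ta, gainPercent = gain,
       roiSummaries = roiSummaries, nZeroSd = nZero)
}
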