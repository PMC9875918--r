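#' Default analysis bands and halfwidths
#'
#' Typical physiological ranges: respiration 9-30 cycles per minute, cardiac
#' 42-96 beats per minute, narrowband halfwidths 2.5 cpm and 6.5 bpm (the
#' average spread of natural breathing and heart rates), pump search band
#' 0.08-0.2 Hz.  All values in Hz.
#'
#' @return a named list of numeric vectors.
#' @export
defaultBands <- function() {
  list(resp = c(9, 30) / 60, cardiac = c(42, 96) / 60,
       respHalfwidth = 2.5 / 60, cardiacHalfwidth = 6.5 / 60,
       pump = c(0.08, 0.2))
}

butterBandpass <- function(x, rate, band, order = 2L) {
  nyq <- rate / 2
  if (band[1] <= 0 || band[2] >= nyq)
    stop(sprintf("band [%.3f, %.3f] Hz outside (0, Nyquist = %.3f Hz)",
                 band[1], band[2], nyq), call. = FALSE)
  b <- signal::butter(order, band / nyq, type = "pass")
  as.numeric(signal::filtfilt(b, x))
}

#' Band-pass prefilter of a sub-TR signal
#'
#' Applies a zero-phase (forward-backward) second-order Butterworth band-pass
#' selecting the physiological contributions before fundamental-frequency
#' identification.  Default bands are `[0.15, 0.5]` Hz for respiration and
#' `[0.7, 1.6]` Hz for cardiac.
#'
#' @param signal a [SubTrSignal-class].
#' @param band `[low, high]` in Hz; must lie inside `(0, rate/2)`.
#' @param kind `"resp"` or `"cardiac"` (informational).
#' @return the filtered [SubTrSignal-class] (same length and times).
#' @export
bandPrefilter <- function(signal, band, kind = c("resp", "cardiac")) {
  kind <- match.arg(kind)
  res <- signal@rate / length(signal@samples)
  if (diff(band) <= 2 * res)
    warning("band width is not much larger than the spectral resolution")
  y <- butterBandpass(signal@samples, signal@rate, band)
  new("SubTrSignal", samples = y, rate = signal@rate, times = signal@times,
      source = signal@source)
}

#' One-sided periodogram of a sub-TR signal
#'
#' Mean-removed, rectangular-window periodogram normalised so the total
#' power equals the time-domain (population) variance; resolution is
#' `rate / length`.
#'
#' @param signal a [SubTrSignal-class] or [PhysioWaveform-class] (length
#'   at least 16), or a plain numeric vector with `rate` given.
#' @param rate sampling rate in Hz (ignored when `signal` carries one).
#' @return a [PowerSpectrum-class].
#' @export
subTrPeriodogram <- function(signal, rate = NULL) {
  if (is(signal, "SubTrSignal") || is(signal, "PhysioWaveform")) {
    x <- samples(signal); rate <- sampleRate(signal)
  } else {
    x <- as.numeric(signal)
    if (is.null(rate)) stop("rate must be given for a plain vector", call. = FALSE)
  }
  n <- length(x)
  if (n < 16L) stop("need at least 16 samples", call. = FALSE)
  x <- x - mean(x)
  p <- Mod(fft(x))^2 / n^2
  half <- floor(n / 2)
  idx <- seq_len(half + 1L)            # DC .. Nyquist (or near-Nyquist)
  power <- p[idx]
  # fold the negative frequencies onto the positive side
  dbl <- 2:(half + if (n %% 2 == 0) 0L else 1L)
  power[dbl] <- 2 * power[dbl]
  freqs <- (idx - 1L) * rate / n
  new("PowerSpectrum", freqs = freqs, power = power, resolution = rate / n)
}

#' Sideband frequencies of the slice-reordering carrier
#'
#' Temporal reordering turns per-slice amplitude differences into a carrier
#' at `1/TR` (and harmonics `k/TR`); any low-frequency modulator `f_m`
#' (respiration, the cold-head pump line) then produces spectral lines at
#' `S = k/TR +/- f_m`.  This returns all such candidates inside a band.
#'
#' @param trVol volume TR in seconds.
#' @param modulators modulator frequencies in Hz (may be empty).
#' @param band `[low, high]` Hz; only sidebands inside it are returned.
#' @param kMax maximum carrier harmonic considered.
#' @return sorted numeric vector of sideband frequencies in Hz.
#' @examples
#' sidebandFrequencies(0.7, modulators = 0.13, band = c(0.7, 1.6))  # 1.30 Hz
#' @export
sidebandFrequencies <- function(trVol, modulators, band, kMax = 4L) {
  if (!length(modulators)) return(numeric())
  f1 <- 1 / trVol
  out <- numeric()
  for (k in seq_len(kMax)) {
    for (fm in modulators) out <- c(out, k * f1 - fm, k * f1 + fm)
  }
  sort(unique(out[out >= band[1] & out <= band[2]]))
}

#' Detect the cold-head pump line in a phase-derived signal
#'
#' The scanner's cold-head helium pump produces a narrowband disturbance
#' that is much stronger in the phase than the magnitude.  The highest
#' periodogram peak inside `pumpBand` is reported when its power exceeds
#' `prominence` times the band's upper noise envelope, taken as the 95th
#' percentile of the in-band power with the peak's immediate neighborhood
#' removed.  (A raw-periodogram noise maximum routinely reaches several
#' times the band median, so the median is not a usable reference; the
#' upper envelope keeps the same detection intent with a stable false-alarm
#' behavior.)  The respiratory notch `fResp +/- respHalfwidth` is excluded
#' from the search when `fResp` is known.  Absence (NULL) is a valid
#' outcome.
#'
#' @param phaseSubtr a phase-derived [SubTrSignal-class].
#' @param pumpBand `[low, high]` Hz search band.
#' @param fResp optional known respiratory fundamental (Hz).
#' @param respHalfwidth halfwidth of the respiratory notch (Hz).
#' @param prominence required ratio of peak power to the band's upper noise
#'   envelope.
#' @return pump frequency in Hz, or NULL if no credible line is found.
#' @export
estimatePumpFrequency <- function(phaseSubtr, pumpBand = c(0.08, 0.2),
                                  fResp = NULL, respHalfwidth = 2.5 / 60,
                                  prominence = 3) {
  spec <- subTrPeriodogram(phaseSubtr)
  inBand <- spec@freqs >= pumpBand[1] & spec@freqs <= pumpBand[2]
  if (!is.null(fResp))
    inBand <- inBand & abs(spec@freqs - fResp) > respHalfwidth
  if (sum(inBand) < 5L) return(NULL)
  idx <- which(inBand)
  i <- idx[which.max(spec@power[idx])]
  rest <- spec@power[setdiff(idx, (i - 2L):(i + 2L))]
  if (!length(rest)) return(NULL)
  envelope <- quantile(rest, 0.95, names = FALSE)
  if (envelope <= 0 || spec@power[i] < prominence * envelope) return(NULL)
  refinePeak(spec, i)
}

# parabolic (quadratic) interpolation of a spectral peak on log power
refinePeak <- function(spec, i) {
  n <- length(spec@power)
  if (i <= 1L || i >= n) return(spec@freqs[i])
  p <- spec@power[(i - 1L):(i + 1L)]
  if (any(p <= 0)) return(spec@freqs[i])
  lp <- log(p)
  denom <- lp[1] - 2 * lp[2] + lp[3]
  if (denom >= 0) return(spec@freqs[i])
  delta <- 0.5 * (lp[1] - lp[3]) / denom
  delta <- max(-0.5, min(0.5, delta))
  spec@freqs[i] + delta * spec@resolution
}

#' Iterative fundamental-frequency search with sideband exclusion
#'
#' Locates the highest-power bin inside the search band; if it falls inside
#' one of the exclusion notches (sidebands of the slice-reordering carrier,
#' the pump line), the whole notch is zeroed and the search repeats.  Zeroing
#' rather than filtering avoids attenuating genuine physiological power that
#' can lie close to the unrelated lines.  The winning peak is refined by
#' parabolic interpolation on log power.
#'
#' @param spectrum a [PowerSpectrum-class].
#' @param band `[low, high]` Hz search band.
#' @param exclusions two-column matrix or list of `c(center, halfwidth)` Hz
#'   notches; may be empty.
#' @param kind `"resp"` or `"cardiac"`.
#' @return a [FundamentalEstimate-class].
#' @export
findFundamental <- function(spectrum, band, exclusions = NULL,
                            kind = c("resp", "cardiac")) {
  kind <- match.arg(kind)
  excl <- normaliseExclusions(exclusions)
  power <- spectrum@power
  inBand <- spectrum@freqs >= band[1] & spectrum@freqs <= band[2]
  if (!any(inBand)) stop("search band outside spectrum range", call. = FALSE)
  used <- matrix(numeric(), 0, 2, dimnames = list(NULL, c("center", "halfwidth")))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cand <- which(inBand & power > 0)
    if (!length(cand))
      stop(paste("no spectral power left inside the search band after",
                 "exclusions; widen the band"), call. = FALSE)
    i <- cand[which.max(power[cand])]
    f <- spectrum@freqs[i]
    hit <- which(abs(f - excl[, 1]) <= excl[, 2])
    if (!length(hit)) {
      specZ <- new("PowerSpectrum", freqs = spectrum@freqs, power = power,
                   resolution = spectrum@resolution)
      f0 <- refinePeak(specZ, i)
      # keep the refined value out of any notch and inside the band
      for (j in seq_len(nrow(excl))) {
        if (abs(f0 - excl[j, 1]) < excl[j, 2]) { f0 <- f; break }
      }
      f0 <- max(band[1], min(band[2], f0))
      return(new("FundamentalEstimate", f0 = f0, band = as.numeric(band),
                 excluded = used, kind = kind, nIterations = iter))
    }
    for (j in hit) {
      zero <- abs(spectrum@freqs - excl[j, 1]) <= excl[j, 2]
      power[zero] <- 0
      used <- rbind(used, excl[j, , drop = FALSE])
    }
  }
}

normaliseExclusions <- function(exclusions) {
  if (is.null(exclusions) || (is.matrix(exclusions) && nrow(exclusions) == 0L))
    return(matrix(numeric(), 0, 2,
                  dimnames = list(NULL, c("center", "halfwidth"))))
  if (is.list(exclusions)) exclusions <- do.call(rbind, exclusions)
  exclusions <- matrix(as.numeric(exclusions), ncol = 2)
  colnames(exclusions) <- c("center", "halfwidth")
  exclusions
}

#' Notch halfwidth used when zeroing sideband lines
#'
#' Wide enough to cover the spectral leakage of a drifting modulator
#' (at least 2 bins) without eating into the physiological band.
#'
#' @param resolution spectral resolution in Hz.
#' @param minHz floor in Hz.
#' @return halfwidth in Hz.
#' @export
notchHalfwidth <- function(resolution, minHz = 0.01) {
  max(2 * resolution, minHz)
}

#' Extract the narrowband physiological waveform
#'
#' Zero-phase band-pass of `fundamental +/- halfwidth` around the identified
#' fundamental (defaults: 2.5 cpm for respiration, 6.5 bpm for cardiac),
#' producing the waveform from which cycle phases and regressors are built.
#'
#' @param signal a [SubTrSignal-class] (typically the detrended, reordered
#'   series, not the prefiltered one).
#' @param estimate a [FundamentalEstimate-class].
#' @param halfwidth halfwidth in Hz; default depends on `estimate@kind`.
#' @return a [PhysioWaveform-class].
#' @export
narrowbandExtract <- function(signal, estimate, halfwidth = NULL) {
  if (is.null(halfwidth))
    halfwidth <- if (estimate@kind == "resp") 2.5 / 60 else 6.5 / 60
  nyq <- signal@rate / 2
  band <- c(estimate@f0 - halfwidth, estimate@f0 + halfwidth)
  if (band[2] >= nyq) {
    warning(sprintf("narrowband upper edge clipped at Nyquist (%.3f Hz)", nyq))
    band[2] <- nyq * 0.999
  }
  if (band[1] <= 0) {
    warning("narrowband lower edge clipped above 0 Hz")
    band[1] <- signal@rate / length(signal@samples)
  }
  y <- butterBandpass(signal@samples, signal@rate, band)
  new("PhysioWaveform", samples = y, rate = signal@rate,
      times = signal@times, band = band, kind = estimate@kind,
      source = signal@source, fundamental = estimate)
}

#' Fraction of a waveform's power inside its own pass band
#'
#' @param waveform a [PhysioWaveform-class].
#' @return fraction in `[0, 1]`.
#' @export
inBandPowerFraction <- function(waveform) {
  spec <- subTrPeriodogram(waveform)
  inBand <- spec@freqs >= waveform@band[1] & spec@freqs <= waveform@band[2]
  sum(spec@power[inBand]) / sum(spec@power)
}

#' Identify respiratory and cardiac fundamentals in one sub-TR signal
#'
#' Runs the identification chain on a single source: respiratory prefilter
#' and peak search first (no exclusions are normally needed in the
#' respiratory band); then, for phase data, pump-line detection; then the
#' cardiac search on a slightly widened band (edges relaxed by
#' `cardiacRelax` so unusual rhythms are not cut off) with the sidebands
#' `k/TR +/- f_R` and `k/TR +/- f_pump` zeroed.
#'
#' @param subtr a detrended [SubTrSignal-class].
#' @param trVol volume TR in seconds.
#' @param respBand,cardiacBand analysis bands in Hz.
#' @param respHalfwidth,cardiacHalfwidth narrowband halfwidths in Hz.
#' @param pumpBand pump search band in Hz (phase source only).
#' @param cardiacRelax fractional relaxation of the cardiac band edges for
#'   the peak search.
#' @param kMax maximum carrier harmonic for sideband prediction.
#' @return a list with `resp` and `cardiac` [PhysioWaveform-class] objects,
#'   the two [FundamentalEstimate-class]s, and `pumpHz` (or NULL).
#' @export
identifyPhysio <- function(subtr, trVol,
                           respBand = c(0.15, 0.5),
                           cardiacBand = c(0.7, 1.6),
                           respHalfwidth = 2.5 / 60,
                           cardiacHalfwidth = 6.5 / 60,
                           pumpBand = c(0.08, 0.2),
                           cardiacRelax = 0.1, kMax = 4L) {
  respPre <- bandPrefilter(subtr, respBand, "resp")
  respSpec <- subTrPeriodogram(respPre)
  respEst <- findFundamental(respSpec, respBand, NULL, "resp")

  pumpHz <- if (subtr@source == "phase")
    estimatePumpFrequency(subtr, pumpBand, fResp = respEst@f0,
                          respHalfwidth = respHalfwidth) else NULL

  searchBand <- cardiacBand * c(1 - cardiacRelax, 1 + cardiacRelax)
  searchBand[2] <- min(searchBand[2], subtr@rate / 2 * 0.999)
  cardPre <- bandPrefilter(subtr, searchBand, "cardiac")
  cardSpec <- subTrPeriodogram(cardPre)
  modulators <- c(respEst@f0, pumpHz)
  sidebands <- sidebandFrequencies(trVol, modulators, searchBand, kMax)
  hw <- notchHalfwidth(cardSpec@resolution)
  exclusions <- if (length(sidebands)) cbind(sidebands, hw) else NULL
  cardEst <- findFundamental(cardSpec, searchBand, exclusions, "cardiac")

  list(resp = narrowbandExtract(subtr, respEst, respHalfwidth),
       cardiac = narrowbandExtract(subtr, cardEst, cardiacHalfwidth),
       respEstimate = respEst, cardiacEstimate = cardEst, pumpHz = pumpHz)
}
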