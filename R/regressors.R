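#' Detect peaks of a narrowband waveform
#'
#' Local maxima with minimum separation `0.5 / f0` seconds and prominence
#' above `promFactor` times the waveform's root-mean-square amplitude; peak
#' times are refined by parabolic interpolation of the three samples around
#' each maximum.
#'
#' @param waveform a [PhysioWaveform-class] (or numeric vector with `rate`
#'   and `f0` supplied).
#' @param rate,f0 sampling rate and fundamental in Hz for plain vectors.
#' @param promFactor prominence threshold as a multiple of the RMS amplitude.
#' @return numeric vector of peak times in seconds.
#' @export
detectPeaks <- function(waveform, rate = NULL, f0 = NULL, promFactor = 0.25) {
  if (is(waveform, "PhysioWaveform")) {
    x <- waveform@samples; rate <- waveform@rate
    f0 <- waveform@fundamental@f0
    t0 <- waveform@times[1]
  } else {
    x <- as.numeric(waveform)
    if (is.null(rate) || is.null(f0))
      stop("rate and f0 must be given for a plain vector", call. = FALSE)
    t0 <- 0
  }
  n <- length(x)
  rms <- sqrt(mean(x^2))
  if (rms == 0) stop("insufficient cycles: constant signal", call. = FALSE)
  isMax <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE)
  idx <- which(isMax)
  if (length(idx)) {
    prom <- vapply(idx, function(i) peakProminence(x, i), numeric(1))
    idx <- idx[prom > promFactor * rms]
  }
  # enforce minimum separation, keeping the taller of close peaks
  minSep <- max(1L, round(0.5 / f0 * rate))
  if (length(idx) > 1L) {
    keep <- logical(length(idx))
    ord <- order(x[idx], decreasing = TRUE)
    taken <- integer()
    for (j in ord) {
      if (!length(taken) || all(abs(idx[j] - taken) >= minSep)) {
        keep[j] <- TRUE
        taken <- c(taken, idx[j])
      }
    }
    idx <- sort(idx[keep])
  }
  if (length(idx) < 2L)
    stop("insufficient cycles: fewer than 2 peaks detected", call. = FALSE)
  # parabolic refinement of peak positions
  tPeak <- vapply(idx, function(i) {
    if (i <= 1L || i >= n) return((i - 1) / rate)
    y <- x[(i - 1L):(i + 1L)]
    denom <- y[1] - 2 * y[2] + y[3]
    delta <- if (denom < 0) 0.5 * (y[1] - y[3]) / denom else 0
    (i - 1 + max(-0.5, min(0.5, delta))) / rate
  }, numeric(1))
  tPeak + t0
}

peakProminence <- function(x, i) {
  # lowest point between the peak and the nearest higher terrain on each side
  leftMin <- x[i]; j <- i
  while (j > 1L) {
    j <- j - 1L
    if (x[j] > x[i]) break
    leftMin <- min(leftMin, x[j])
  }
  if (j == 1L && x[j] <= x[i]) leftMin <- min(leftMin, x[1])
  rightMin <- x[i]; j <- i; n <- length(x)
  while (j < n) {
    j <- j + 1L
    if (x[j] > x[i]) break
    rightMin <- min(rightMin, x[j])
  }
  if (j == n && x[j] <= x[i]) rightMin <- min(rightMin, x[n])
  x[i] - max(leftMin, rightMin)
}

#' Cardiac cycle phase from peak times
#'
#' Between consecutive peaks `t_k`, `t_{k+1}`, the phase grows linearly from
#' 0 to `2*pi`; before the first and after the last peak the nearest period
#' is extrapolated.
#'
#' @param peaks strictly increasing peak times in seconds (>= 2).
#' @param queryTimes times at which to evaluate the phase.
#' @return a [CyclePhase-class] with `kind = "cardiac"`.
#' @export
cardiacCyclePhase <- function(peaks, queryTimes) {
  if (length(peaks) < 2L) stop("need at least 2 peaks", call. = FALSE)
  if (any(diff(peaks) <= 0)) stop("peak times must be strictly increasing",
                                  call. = FALSE)
  k <- findInterval(queryTimes, peaks)
  np <- length(peaks)
  lo <- pmin(pmax(k, 1L), np - 1L)          # interval used (extrapolating)
  frac <- (queryTimes - peaks[lo]) / (peaks[lo + 1L] - peaks[lo])
  phi <- 2 * pi * (frac - floor(frac))
  phi[phi >= 2 * pi] <- 0
  new("CyclePhase", phi = phi, times = as.numeric(queryTimes),
      kind = "cardiac")
}

#' Respiratory cycle phase (amplitude-histogram convention)
#'
#' `phi(t) = pi * H(a(t)) * sgn(da/dt)` mapped into `[0, 2*pi)`, where `H`
#' is the empirical cumulative histogram (`nBins` bins) of the waveform
#' amplitude and `da/dt` a centered finite difference.  This is the
#' RETROICOR respiratory convention: inhalation and exhalation at the same
#' chest amplitude get distinct phases.  Amplitude and derivative are
#' linearly interpolated to the query times before the mapping.
#'
#' @param waveform a [PhysioWaveform-class] (length >= 100) or numeric
#'   vector with `rate` given.
#' @param queryTimes times at which to evaluate the phase.
#' @param rate sampling rate for plain vectors.
#' @param nBins histogram bins for the amplitude CDF.
#' @return a [CyclePhase-class] with `kind = "resp"`.
#' @export
respiratoryCyclePhase <- function(waveform, queryTimes, rate = NULL,
                                  nBins = 100L) {
  if (is(waveform, "PhysioWaveform")) {
    a <- waveform@samples; times <- waveform@times
  } else {
    a <- as.numeric(waveform)
    if (is.null(rate)) stop("rate must be given for a plain vector", call. = FALSE)
    times <- (seq_along(a) - 1) / rate
  }
  n <- length(a)
  if (n < 100L) stop("waveform too short (need >= 100 samples)", call. = FALSE)
  if (sd(a) == 0) stop("zero-variance waveform", call. = FALSE)
  breaks <- seq(min(a), max(a), length.out = nBins + 1L)
  counts <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE),
                     nbins = nBins)
  cdf <- cumsum(counts) / n
  da <- c(a[2] - a[1], (a[3:n] - a[1:(n - 2)]) / 2, a[n] - a[n - 1])
  aq <- approx(times, a, xout = queryTimes, rule = 2)$y
  dq <- approx(times, da, xout = queryTimes, rule = 2)$y
  bins <- pmin(pmax(findInterval(aq, breaks, rightmost.closed = TRUE), 1L),
               nBins)
  h <- cdf[bins]
  phi <- ifelse(dq >= 0, pi * h, 2 * pi - pi * h)
  phi[phi >= 2 * pi] <- phi[phi >= 2 * pi] - 2 * pi
  phi[phi < 0] <- 0
  new("CyclePhase", phi = phi, times = as.numeric(queryTimes), kind = "resp")
}

#' Cycle phase of a waveform by its kind's convention
#'
#' Dispatches to [respiratoryCyclePhase()] (amplitude histogram) or
#' [cardiacCyclePhase()] (peak-to-peak) according to the waveform's kind.
#' `convention = "peaks"` forces the peak-to-peak phase for both kinds.
#'
#' @param waveform a [PhysioWaveform-class].
#' @param queryTimes evaluation times (defaults to the waveform's own times).
#' @param convention `"auto"` or `"peaks"`.
#' @return a [CyclePhase-class].
#' @export
cyclePhase <- function(waveform, queryTimes = NULL,
                       convention = c("auto", "peaks")) {
  convention <- match.arg(convention)
  if (is.null(queryTimes)) queryTimes <- waveform@times
  if (waveform@kind == "resp" && convention == "auto") {
    respiratoryCyclePhase(waveform, queryTimes)
  } else {
    peaks <- detectPeaks(waveform)
    cp <- cardiacCyclePhase(peaks, queryTimes)
    cp@kind <- waveform@kind
    cp
  }
}

#' Fourier expansion of a cycle phase
#'
#' Columns `sin(k*phi), cos(k*phi)` for `k = 1..nHarmonics`, evaluated at
#' the phase's time points.
#'
#' @param phase a [CyclePhase-class] or numeric vector of phases.
#' @param nHarmonics number of harmonics (default 2).
#' @return matrix with `2 * nHarmonics` columns named `sin1, cos1, ...`.
#' @export
fourierExpansion <- function(phase, nHarmonics = 2L) {
  phi <- if (is(phase, "CyclePhase")) phase@phi else as.numeric(phase)
  cols <- lapply(seq_len(nHarmonics), function(k) cbind(sin(k * phi),
                                                        cos(k * phi)))
  m <- do.call(cbind, cols)
  colnames(m) <- as.vector(vapply(seq_len(nHarmonics), function(k)
    c(paste0("sin", k), paste0("cos", k)), character(2)))
  m
}

#' Variance improvement of a candidate waveform against a target signal
#'
#' Builds the candidate's two-harmonic cycle-phase regressors at the target's
#' sample times, fits them plus an intercept to the target by least squares,
#' and returns the fraction of variance explained `1 - SS_resid / SS_total`.
#'
#' @param candidate a [PhysioWaveform-class].
#' @param target a [SubTrSignal-class] sharing the candidate's rate and
#'   length.
#' @param nHarmonics harmonics in the expansion.
#' @return R^2 fraction in `[0, 1]`.
#' @export
evaluateVarianceImprovement <- function(candidate, target, nHarmonics = 2L) {
  if (length(candidate@samples) != length(target@samples))
    stop("candidate and target must share length", call. = FALSE)
  phase <- cyclePhase(candidate, target@times)
  X <- cbind(1, fourierExpansion(phase, nHarmonics))
  y <- target@samples
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    warning("rank-deficient design; improvement computed on the reduced rank")
  resid <- qr.resid(qrX, y)
  ssTot <- sum((y - mean(y))^2)
  if (ssTot == 0) return(0)
  max(0, 1 - sum(resid^2) / ssTot)
}

#' Select the better source (magnitude or phase) per noise type
#'
#' Computes the variance improvement of each candidate and keeps the larger.
#' By default each candidate is scored against its own source's sub-TR trace
#' (the phase-derived candidate against the phase trace, the
#' magnitude-derived one against the magnitude trace), i.e. the source whose
#' trace carries more physiological variance of that kind wins; passing
#' `phaseTarget = NULL` scores both candidates against `magTarget`.
#' Ties (within 1e-9) break to phase for respiration and magnitude for
#' cardiac, the empirically typical winners.
#'
#' @param magCandidate,phaseCandidate [PhysioWaveform-class] candidates of
#'   the same kind; either may be NULL (e.g. no phase data), in which case
#'   the available source is selected with a message.
#' @param magTarget magnitude [SubTrSignal-class].
#' @param phaseTarget phase [SubTrSignal-class], or NULL to score both
#'   candidates against `magTarget`.
#' @return a list with `source` (`"magnitude"` or `"phase"`) and
#'   `improvement` (named numeric, NA for a missing candidate).
#' @export
selectSourceKind <- function(magCandidate, phaseCandidate, magTarget,
                             phaseTarget = NULL) {
  kind <- if (!is.null(magCandidate)) magCandidate@kind else phaseCandidate@kind
  impMag <- if (!is.null(magCandidate))
    evaluateVarianceImprovement(magCandidate, magTarget) else NA_real_
  impPhase <- if (!is.null(phaseCandidate))
    evaluateVarianceImprovement(phaseCandidate, phaseTarget %||% magTarget)
    else NA_real_
  imp <- c(magnitude = impMag, phase = impPhase)
  if (is.na(impPhase) && is.na(impMag))
    stop("no candidate available", call. = FALSE)
  if (is.na(impPhase) || is.na(impMag)) {
    src <- names(imp)[!is.na(imp)]
    message(sprintf("only the %s candidate is available for %s; selected it",
                    src, kind))
    return(list(source = src, improvement = imp))
  }
  src <- if (abs(impMag - impPhase) < 1e-9) {
    if (kind == "resp") "phase" else "magnitude"
  } else if (impMag > impPhase) "magnitude" else "phase"
  list(source = src, improvement = imp)
}

#' Select sources for both noise types
#'
#' @param candidates list with elements `resp.magnitude`, `resp.phase`,
#'   `cardiac.magnitude`, `cardiac.phase` ([PhysioWaveform-class] or NULL).
#' @param magTarget magnitude [SubTrSignal-class].
#' @param phaseTarget phase [SubTrSignal-class] or NULL (see
#'   [selectSourceKind()]).
#' @return a [SourceSelection-class].
#' @export
selectSource <- function(candidates, magTarget, phaseTarget = NULL) {
  resp <- selectSourceKind(candidates$resp.magnitude, candidates$resp.phase,
                           magTarget, phaseTarget)
  card <- selectSourceKind(candidates$cardiac.magnitude,
                           candidates$cardiac.phase, magTarget, phaseTarget)
  new("SourceSelection", respSource = resp$source,
      cardiacSource = card$source,
      improvement = c(resp.magnitude = unname(resp$improvement["magnitude"]),
                      resp.phase = unname(resp$improvement["phase"]),
                      cardiac.magnitude = unname(card$improvement["magnitude"]),
                      cardiac.phase = unname(card$improvement["phase"])))
}

#' Build slice-wise two-harmonic physiological regressors
#'
#' Evaluates the respiratory and cardiac cycle phases at each slice's
#' acquisition times and expands them into the 8-column design block
#' (`resp sin/cos` of harmonics 1-2, then `cardiac sin/cos`).  Slices
#' excited simultaneously share identical regressors.  Slice times outside
#' the waveforms' support are handled by nearest-sample extrapolation of the
#' respiratory amplitude and nearest-period extrapolation of the cardiac
#' phase.
#'
#' @param respWaveform selected respiratory [PhysioWaveform-class].
#' @param cardWaveform selected cardiac [PhysioWaveform-class].
#' @param params an [AcquisitionParams-class].
#' @param selection optional [SourceSelection-class] recorded in the output.
#' @return a [RegressorSet-class].
#' @export
buildSlicewiseRegressors <- function(respWaveform, cardWaveform, params,
                                     selection = NULL) {
  times <- sliceAcquisitionTimes(params)
  cardPeaks <- detectPeaks(cardWaveform)
  matrices <- lapply(seq_len(params@nSlices), function(s) {
    ts <- times[s, ]
    respPhi <- respiratoryCyclePhase(respWaveform, ts)
    cardPhi <- cardiacCyclePhase(cardPeaks, ts)
    m <- cbind(fourierExpansion(respPhi), fourierExpansion(cardPhi))
    colnames(m) <- regressorColumns
    m
  })
  sources <- if (!is.null(selection))
    c(resp = selection@respSource, cardiac = selection@cardiacSource)
  else c(resp = respWaveform@source, cardiac = cardWaveform@source)
  new("RegressorSet", matrices = matrices,
      sliceIndex = seq_len(params@nSlices), sources = sources,
      fundamentals = list(resp = respWaveform@fundamental,
                          cardiac = cardWaveform@fundamental))
}
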