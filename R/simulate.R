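#' Configuration for the synthetic EPI generator
#'
#' The generator emulates the noise content a physiological-correction
#' pipeline must cope with: an ellipsoidal "brain" with slice-dependent
#' baseline offsets, slow per-slice cubic drift, quasi-periodic respiratory
#' modulation (phase-dominant), quasi-periodic cardiac modulation
#' (magnitude-dominant, possibly aliased at the volume TR), a narrowband
#' cold-head pump line in the phase, Gaussian thermal noise, optional phase
#' wrapping and SMS slice grouping.  Respiratory and cardiac oscillators have
#' instantaneous frequency `base + AR(1) jitter` (coefficient 0.99,
#' innovation SD `jitterSd`) integrated to phase, so their spectral lines
#' have a realistic finite width.  Phase-borne low-frequency terms receive a
#' slice-dependent gain `1 + sliceMod * cos(2*pi*rank/NS)`, which after
#' temporal reordering is an amplitude-modulated carrier at `1/TR` and
#' produces the characteristic sidebands `k/TR +/- f_m`.
#'
#' @param grid `c(nx, ny, nSlices)` voxel grid.
#' @param trVol,mbFactor,nReps acquisition parameters (slice order is
#'   sequential ascending with default SMS grouping).
#' @param respHz,cardiacHz base frequencies in Hz (must be below the sub-TR
#'   Nyquist `NS / (2 * trVol)`).
#' @param respJitterSd,cardiacJitterSd AR(1) innovation SDs in Hz.
#' @param respPhaseAmp,cardiacPhaseAmp amplitudes in the phase, radians.
#' @param respMagFrac,cardiacMagFrac fractional magnitude amplitudes
#'   (relative to the local baseline).
#' @param pumpHz,pumpPhaseAmp cold-head pump line (set `pumpPhaseAmp = 0`
#'   for no pump).
#' @param sliceMod slice-gain modulation depth of the phase-borne
#'   low-frequency terms (drives sideband generation).
#' @param driftAmp per-slice cubic drift amplitude, magnitude units.
#' @param noiseSdMag,noiseSdPhase thermal noise SDs (magnitude units / rad).
#' @param wrapPhase wrap the phase into `(-pi, pi]`.
#' @param vesselFraction fraction of in-brain voxels carrying the cardiac
#'   magnitude modulation (1 = bulk pulsatility everywhere).
#' @param baseline peak baseline intensity, arbitrary units.
#' @param seed integer RNG seed; all outputs are reproducible from it.
#' @return a classed list (`prepairSynthConfig`).
#' @export
synthConfig <- function(grid = c(32, 32, 12), trVol = 1.0, mbFactor = 2L,
                        nReps = 300L,
                        respHz = 0.25, cardiacHz = 1.17,
                        respJitterSd = 5e-4, cardiacJitterSd = 5e-4,
                        respPhaseAmp = 0.1, cardiacPhaseAmp = 0.02,
                        respMagFrac = 0.015, cardiacMagFrac = 0.03,
                        pumpHz = 0.13, pumpPhaseAmp = 0.05,
                        sliceMod = 0.3, driftAmp = 10,
                        noiseSdMag = 3, noiseSdPhase = 0.02,
                        wrapPhase = FALSE, vesselFraction = 1.0,
                        baseline = 500, seed = 1L) {
  cfg <- list(grid = as.integer(grid), trVol = trVol,
              mbFactor = as.integer(mbFactor), nReps = as.integer(nReps),
              respHz = respHz, cardiacHz = cardiacHz,
              respJitterSd = respJitterSd, cardiacJitterSd = cardiacJitterSd,
              respPhaseAmp = respPhaseAmp, cardiacPhaseAmp = cardiacPhaseAmp,
              respMagFrac = respMagFrac, cardiacMagFrac = cardiacMagFrac,
              pumpHz = pumpHz, pumpPhaseAmp = pumpPhaseAmp,
              sliceMod = sliceMod, driftAmp = driftAmp,
              noiseSdMag = noiseSdMag, noiseSdPhase = noiseSdPhase,
              wrapPhase = isTRUE(wrapPhase), vesselFraction = vesselFraction,
              baseline = baseline, seed = as.integer(seed))
  ns <- cfg$grid[3] %/% cfg$mbFactor
  nyqSub <- ns / (2 * cfg$trVol)
  if (max(respHz, cardiacHz) >= nyqSub)
    stop(sprintf("physiological frequency above the sub-TR Nyquist (%.3f Hz)",
                 nyqSub), call. = FALSE)
  if (vesselFraction < 0 || vesselFraction > 1)
    stop("vesselFraction must be in [0, 1]", call. = FALSE)
  if (any(c(respPhaseAmp, cardiacPhaseAmp, respMagFrac, cardiacMagFrac,
            pumpPhaseAmp) < 0))
    stop("amplitudes must be >= 0", call. = FALSE)
  class(cfg) <- "prepairSynthConfig"
  cfg
}

# quasi-periodic oscillator: instantaneous frequency = base + AR(1) jitter,
# integrated to phase; returns the accumulated phase on the fine grid
oscillatorPhase <- function(base, innovSd, nFine, dtFine, rho = 0.99) {
  jitter <- numeric(nFine)
  if (innovSd > 0) {
    statSd <- innovSd / sqrt(1 - rho^2)
    jitter[1] <- rnorm(1, 0, statSd)
    innov <- rnorm(nFine - 1L, 0, innovSd)
    jitter[-1L] <- as.numeric(stats::filter(innov, rho, method = "recursive",
                                            init = jitter[1]))
  }
  2 * pi * cumsum(base + jitter) * dtFine
}

respShape <- function(phi) sin(phi) + 0.2 * sin(2 * phi)
cardShape <- function(phi) sin(phi) + 0.3 * sin(2 * phi)

#' Simulate a magnitude + phase EPI time series with known ground truth
#'
#' See [synthConfig()] for the generative model.  The same oscillators drive
#' the image data and the ground-truth waveform grids, so external-recording
#' emulation and waveform-fidelity checks are exact.
#'
#' @param config a [synthConfig()] list.
#' @return a list with `series` (an [EpiSeries-class]) and `truth`: the
#'   respiratory/cardiac waveforms and instantaneous phases at every
#'   excitation time (`subTimes`) and on a 1/400 s grid (`fineTimes`), plus
#'   the vessel mask and brain mask.
#' @export
simulateEpi <- function(config) {
  stopifnot(inherits(config, "prepairSynthConfig"))
  set.seed(config$seed)
  nx <- config$grid[1]; ny <- config$grid[2]; n <- config$grid[3]
  params <- acquisitionParams(config$trVol, n, config$mbFactor, config$nReps)
  ns <- nGroups(params)
  nr <- config$nReps
  duration <- nr * config$trVol

  dtFine <- 1 / 400
  nFine <- ceiling(duration / dtFine) + 1L
  fineTimes <- (seq_len(nFine) - 1L) * dtFine
  phiR <- oscillatorPhase(config$respHz, config$respJitterSd, nFine, dtFine)
  phiC <- oscillatorPhase(config$cardiacHz, config$cardiacJitterSd, nFine,
                          dtFine)
  respFine <- respShape(phiR)
  cardFine <- cardShape(phiC)

  # ellipsoidal brain with mild radial intensity falloff
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (n + 1) / 2
  ax <- 0.42 * nx; ay <- 0.42 * ny; az <- 0.55 * n
  xv <- (seq_len(nx) - cx) / ax
  yv <- (seq_len(ny) - cy) / ay
  zv <- (seq_len(n) - cz) / az
  rho2 <- outer(outer(xv^2, yv^2, `+`), zv^2, `+`)
  brain <- rho2 <= 1
  baseline <- array(0, c(nx, ny, n))
  baseline[brain] <- config$baseline * (1 - 0.25 * rho2[brain])
  sliceOffset <- 0.08 * config$baseline * sin(2 * pi * seq_len(n) / n)

  vessel <- array(FALSE, c(nx, ny, n))
  vessel[brain] <- runif(sum(brain)) < config$vesselFraction

  driftCoef <- matrix(rnorm(3L * n), n, 3L)   # per-slice cubic drift shape

  times <- sliceAcquisitionTimes(params)
  rank <- groupRank(params)
  sliceGain <- 1 + config$sliceMod * cos(2 * pi * (rank - 1L) / ns)

  mag <- array(0, c(nx, ny, n, nr))
  pha <- array(0, c(nx, ny, n, nr))
  phiSliceOffset <- 0.3 * sin(2 * pi * seq_len(n) / n + 1)
  for (s in seq_len(n)) {
    ts <- times[s, ]
    r <- approx(fineTimes, respFine, xout = ts, rule = 2)$y
    cc <- approx(fineTimes, cardFine, xout = ts, rule = 2)$y
    pump <- sin(2 * pi * config$pumpHz * ts)
    u <- ts / duration * 2 - 1
    drift <- config$driftAmp *
      (driftCoef[s, 1] * u + driftCoef[s, 2] * u^2 + driftCoef[s, 3] * u^3)
    base_s <- baseline[, , s]
    magSlab <- outer(base_s + sliceOffset[s] * (base_s > 0),
                     rep(1, nr)) +
      outer(base_s * config$respMagFrac, r) +
      outer(base_s * config$cardiacMagFrac * vessel[, , s], cc) +
      rep(drift, each = nx * ny) * rep(as.numeric(base_s > 0), nr) +
      rnorm(nx * ny * nr, 0, config$noiseSdMag)
    mag[, , s, ] <- pmax(magSlab, 0)
    lowFreq <- config$respPhaseAmp * r +
      config$pumpPhaseAmp * pump
    phaSlab <- phiSliceOffset[s] +
      outer(rep(1, nx * ny), sliceGain[s] * lowFreq +
                             config$cardiacPhaseAmp * cc) +
      rnorm(nx * ny * nr, 0, config$noiseSdPhase)
    pha[, , s, ] <- phaSlab
  }
  if (config$wrapPhase) pha <- (pha + pi) %% (2 * pi) - pi

  offsets <- (seq_len(ns) - 1) * config$trVol / ns
  subTimes <- as.vector(outer(offsets, (seq_len(nr) - 1) * config$trVol, `+`))
  truth <- list(
    subTimes = subTimes,
    resp = approx(fineTimes, respFine, xout = subTimes, rule = 2)$y,
    cardiac = approx(fineTimes, cardFine, xout = subTimes, rule = 2)$y,
    fineTimes = fineTimes, respFine = respFine, cardFine = cardFine,
    phiRespFine = phiR, phiCardFine = phiC,
    vesselMask = vessel, brainMask = brain,
    sliceTimes = times
  )
  list(series = epiSeries(mag, pha, params), truth = truth)
}

#' Emulate an external physiological recording from simulation ground truth
#'
#' The ground-truth respiratory and cardiac waveforms on the 1/400 s grid
#' plus additive Gaussian noise, mirroring a PMU trace.
#'
#' @param truth the `truth` element returned by [simulateEpi()].
#' @param noiseSd additive noise SD (waveforms have ~unit amplitude).
#' @return an [ExternalRecording-class] with `dt = 1/400` s and `t0 = 0`.
#' @export
simulateExternal <- function(truth, noiseSd = 0.05) {
  nFine <- length(truth$fineTimes)
  resp <- truth$respFine + rnorm(nFine, 0, noiseSd)
  cardiac <- truth$cardFine + rnorm(nFine, 0, noiseSd)
  new("ExternalRecording", resp = resp, cardiac = cardiac, dt = 1 / 400,
      t0 = 0)
}
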