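#' Run the full physiological-noise identification and correction pipeline
#'
#' Chains the whole method on one EPI run: high-SNR masking, slice averaging
#' (magnitude-weighted for phase), third-order detrending, reordering to the
#' sub-TR rate, fundamental identification with sideband and pump-line
#' exclusion (independently for the magnitude- and phase-derived signals),
#' narrowband waveform extraction, magnitude-vs-phase source selection by
#' variance improvement, slice-wise two-harmonic regressor construction and,
#' optionally, voxelwise correction of the magnitude images.
#'
#' @param series an [EpiSeries-class] (phase optional; if the phase may be
#'   wrapped, set `unwrap = TRUE`).
#' @param mask optional logical 3D array; computed by [computeHighSnrMask()]
#'   or [computeThresholdMask()] when NULL.
#' @param maskMode `"snr"` (percentile criterion) or `"threshold"`.
#' @param maskThreshold intensity for `maskMode = "threshold"`.
#' @param respBand,cardiacBand analysis bands, Hz.
#' @param respHalfwidth,cardiacHalfwidth narrowband halfwidths, Hz.
#' @param pumpBand pump-line search band, Hz.
#' @param unwrap apply per-voxel temporal phase unwrapping first.
#' @param correct run [regressOutPhysio()] on the magnitude data.
#' @param driftOrder drift order for the correction design.
#' @return an object of class `prepairFit`: a list with the mask, the
#'   magnitude/phase [SubTrSignal-class]s, per-source identification results,
#'   the candidate waveforms, the [SourceSelection-class], the selected
#'   waveforms, the [RegressorSet-class] and (when `correct`) the
#'   [CorrectionResult-class].
#' @export
prepair <- function(series, mask = NULL, maskMode = c("snr", "threshold"),
                    maskThreshold = 3000,
                    respBand = c(0.15, 0.5), cardiacBand = c(0.7, 1.6),
                    respHalfwidth = 2.5 / 60, cardiacHalfwidth = 6.5 / 60,
                    pumpBand = c(0.08, 0.2), unwrap = FALSE,
                    correct = TRUE, driftOrder = 3L) {
  maskMode <- match.arg(maskMode)
  params <- series@params
  if (is.null(mask)) {
    mask <- if (maskMode == "snr") computeHighSnrMask(series)
            else computeThresholdMask(series, maskThreshold)
  }
  if (unwrap && !is.null(series@phase))
    series@phase <- unwrapPhaseTemporal(series@phase)

  avg <- sliceAverage(series, mask)
  subtr <- lapply(avg, function(sig)
    reorderToSubTr(detrendSliceSignals(sig), params))

  ident <- lapply(subtr, identifyPhysio, trVol = params@trVol,
                  respBand = respBand, cardiacBand = cardiacBand,
                  respHalfwidth = respHalfwidth,
                  cardiacHalfwidth = cardiacHalfwidth, pumpBand = pumpBand)

  candidates <- list(
    resp.magnitude = ident$magnitude$resp,
    resp.phase = if (!is.null(ident$phase)) ident$phase$resp,
    cardiac.magnitude = ident$magnitude$cardiac,
    cardiac.phase = if (!is.null(ident$phase)) ident$phase$cardiac
  )
  selection <- selectSource(candidates, subtr$magnitude, subtr$phase)
  respWave <- candidates[[paste0("resp.", selection@respSource)]]
  cardWave <- candidates[[paste0("cardiac.", selection@cardiacSource)]]

  regressors <- buildSlicewiseRegressors(respWave, cardWave, params,
                                         selection)
  correction <- if (correct)
    regressOutPhysio(series, regressors, mask, driftOrder) else NULL

  structure(list(mask = mask, subTr = subtr, identification = ident,
                 candidates = candidates, selection = selection,
                 respWaveform = respWave, cardiacWaveform = cardWave,
                 regressors = regressors, correction = correction,
                 params = params),
            class = "prepairFit")
}

#' @export
print.prepairFit <- function(x, ...) {
  cat("PREPAIR fit\n")
  cat(sprintf("  mask: %d voxels\n", sum(x$mask)))
  cat(sprintf("  f_R = %.4f Hz (%s), f_C = %.4f Hz (%s)\n",
              x$respWaveform@fundamental@f0, x$selection@respSource,
              x$cardiacWaveform@fundamental@f0, x$selection@cardiacSource))
  if (!is.null(x$identification$phase$pumpHz))
    cat(sprintf("  pump line: %.4f Hz\n", x$identification$phase$pumpHz))
  if (!is.null(x$correction))
    cat(sprintf("  corrected: median physiological R^2 = %.3f\n",
                median(x$correction@r2Map, na.rm = TRUE)))
  invisible(x)
}

#' Evaluate a correction against the uncorrected data
#'
#' Convenience wrapper computing the evaluation battery for a finished
#' pipeline fit: band-power removal proportions in the respiratory and
#' cardiac bands (with second harmonics when separable), out-of-band power
#' fluctuation and tSNR gain.
#'
#' @param series the uncorrected [EpiSeries-class].
#' @param fit a `prepairFit` with a correction.
#' @param rois optional named list of logical ROI masks for the tSNR report.
#' @return a list with `respRemoval`, `cardiacRemoval` (each as returned by
#'   [bandPowerProportion()]), `outOfBand` and `tsnr`.
#' @export
evaluateCorrection <- function(series, fit, rois = NULL) {
  if (is.null(fit$correction)) stop("fit has no correction", call. = FALSE)
  params <- series@params
  fs <- 1 / params@trVol
  nt <- params@nReps
  res <- fs / nt
  respBands <- physioBands(fit$respWaveform@fundamental@f0,
                           respHalfwidthOf(fit), fs, res)
  cardBands <- physioBands(fit$cardiacWaveform@fundamental@f0,
                           cardiacHalfwidthOf(fit), fs, res)
  before <- series@magnitude
  after <- fit$correction@corrected
  list(
    respRemoval = bandPowerProportion(before, after, params, fit$mask,
                                      respBands),
    cardiacRemoval = bandPowerProportion(before, after, params, fit$mask,
                                         cardBands),
    outOfBand = outOfBandFluctuation(before, after, params, fit$mask,
                                     c(respBands, cardBands)),
    tsnr = tsnrGain(before, after, fit$mask, rois)
  )
}

respHalfwidthOf <- function(fit) diff(fit$respWaveform@band) / 2
cardiacHalfwidthOf <- function(fit) diff(fit$cardiacWaveform@band) / 2
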