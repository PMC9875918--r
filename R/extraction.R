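#' High-SNR voxel mask
#'
#' Includes a voxel when its mean intensity over time exceeds 20% of the
#' robust maximum, defined as the 98th percentile.  By default the percentile
#' is taken over the temporal-mean image (one value per voxel, linear
#' interpolation convention); `on = "all"` switches to the percentile of all
#' voxel-time values.
#'
#' @param magnitude 4D magnitude array `[x, y, z, t]` or an
#'   [EpiSeries-class].
#' @param fraction inclusion threshold as a fraction of the robust maximum.
#' @param probs percentile defining the robust maximum.
#' @param on `"mean"` (temporal-mean image) or `"all"` (all values).
#' @return logical 3D array with attribute `emptySlices` listing slices in
#'   which no voxel passed.
#' @export
computeHighSnrMask <- function(magnitude, fraction = 0.2, probs = 0.98,
                               on = c("mean", "all")) {
  on <- match.arg(on)
  if (is(magnitude, "EpiSeries")) magnitude <- magnitude@magnitude
  dm <- dim(magnitude)
  if (dm[4] < 2L) stop("need at least 2 time points", call. = FALSE)
  tmean <- rowMeans(magnitude, dims = 3L)
  if (max(magnitude) <= 0)
    stop("all-zero magnitude: mask would be empty", call. = FALSE)
  p98 <- if (on == "mean") quantile(tmean, probs, names = FALSE)
         else quantile(magnitude, probs, names = FALSE)
  mask <- tmean > fraction * p98
  finishMask(mask)
}

#' Fixed-intensity threshold mask
#'
#' Includes voxels whose temporal mean exceeds a fixed intensity; useful for
#' partial-coverage acquisitions (e.g. brainstem slabs) where aggressive
#' brain masking would discard tissue of interest.
#'
#' @param magnitude 4D magnitude array or [EpiSeries-class].
#' @param threshold intensity threshold (default 3000).
#' @return logical 3D array with attribute `emptySlices`.
#' @export
computeThresholdMask <- function(magnitude, threshold = 3000) {
  if (is(magnitude, "EpiSeries")) magnitude <- magnitude@magnitude
  tmean <- rowMeans(magnitude, dims = 3L)
  finishMask(tmean > threshold)
}

finishMask <- function(mask) {
  nz <- dim(mask)[3]
  empty <- which(vapply(seq_len(nz), function(s) !any(mask[, , s]), logical(1)))
  attr(mask, "emptySlices") <- as.integer(empty)
  mask
}

#' Temporal phase unwrapping
#'
#' Per voxel, successive phase differences are brought into `(-pi, pi]` by
#' adding multiples of `2*pi`; the first sample is left unchanged.  This is a
#' fallback for data that were not spatially unwrapped: it removes temporal
#' wraps but leaves any static spatial wrapping pattern in place (which is
#' harmless here, since downstream processing is purely temporal).
#'
#' @param phase 4D phase array in radians.
#' @return unwrapped 4D array of the same shape.
#' @export
unwrapPhaseTemporal <- function(phase) {
  dm <- dim(phase)
  nt <- dm[4]
  if (nt < 2L) return(phase)
  m <- matrix(phase, ncol = nt)       # voxels x time
  out <- m
  acc <- numeric(nrow(m))             # accumulated wrap counts per voxel
  for (tt in 2:nt) {
    acc <- acc + round((m[, tt] - m[, tt - 1L]) / (2 * pi))
    out[, tt] <- m[, tt] - 2 * pi * acc
  }
  array(out, dim = dm)
}

#' Slice-average an EPI series within a mask
#'
#' For each slice and time point, the magnitude value is the plain mean over
#' masked voxels; the phase value is the magnitude-weighted mean
#' `sum(m_i * phi_i) / sum(m_i)` (weights are the corresponding magnitude
#' values at the same time point).  Slices with an empty mask are filled from
#' the nearest slice with coverage, with a warning.
#'
#' @param series an [EpiSeries-class]; phase (if present) should already be
#'   unwrapped.
#' @param mask logical 3D array matching the series' spatial dimensions.
#' @return a list with elements `magnitude` and (if phase is present)
#'   `phase`, each a [SliceSignal-class].
#' @export
sliceAverage <- function(series, mask) {
  mag <- series@magnitude
  ph <- series@phase
  dm <- dim(mag)
  if (!identical(dim(mask), dm[1:3]))
    stop("mask dimensions do not match the series", call. = FALSE)
  n <- dm[3]; nt <- dm[4]
  magVals <- matrix(NA_real_, n, nt)
  phVals <- if (!is.null(ph)) matrix(NA_real_, n, nt) else NULL
  covered <- logical(n)
  for (s in seq_len(n)) {
    sel <- mask[, , s]
    if (!any(sel)) next
    covered[s] <- TRUE
    ms <- matrix(mag[, , s, ], ncol = nt)[sel, , drop = FALSE]
    magVals[s, ] <- colMeans(ms)
    if (!is.null(ph)) {
      ps <- matrix(ph[, , s, ], ncol = nt)[sel, , drop = FALSE]
      phVals[s, ] <- colSums(ms * ps) / colSums(ms)
    }
  }
  if (!any(covered)) stop("mask is empty in every slice", call. = FALSE)
  if (any(!covered)) {
    warning(sprintf("slice(s) %s have no masked voxels; filled from nearest slice",
                    paste(which(!covered), collapse = ", ")))
    src <- which(covered)
    for (s in which(!covered)) {
      nearest <- src[which.min(abs(src - s))]
      magVals[s, ] <- magVals[nearest, ]
      if (!is.null(ph)) phVals[s, ] <- phVals[nearest, ]
    }
  }
  out <- list(magnitude = new("SliceSignal", values = magVals,
                              trVol = series@params@trVol,
                              source = "magnitude", detrended = FALSE))
  if (!is.null(ph))
    out$phase <- new("SliceSignal", values = phVals,
                     trVol = series@params@trVol, source = "phase",
                     detrended = FALSE)
  out
}

#' Remove slice-dependent baseline and drift
#'
#' Fits and subtracts a third-order polynomial in time from each slice's time
#' series by ordinary least squares, removing the dependence of the values on
#' the imaging slice (coverage, tissue composition) and slow scanner drift.
#'
#' @param signal a [SliceSignal-class] with at least 5 time points.
#' @param degree polynomial degree (default 3).
#' @return the detrended [SliceSignal-class]; row means are ~0.
#' @export
detrendSliceSignals <- function(signal, degree = 3L) {
  nt <- ncol(signal@values)
  if (nt < degree + 2L)
    stop(sprintf("need at least %d time points for degree-%d detrending",
                 degree + 2L, degree), call. = FALSE)
  x <- seq_len(nt)
  basis <- cbind(1, poly(x, degree))
  q <- qr.Q(qr(basis))
  v <- signal@values
  resid <- v - (v %*% q) %*% t(q)
  new("SliceSignal", values = resid, trVol = signal@trVol,
      source = signal@source, detrended = TRUE)
}

#' Reorder slice signals into a sub-TR time series
#'
#' Averages simultaneously excited slices into `NS = N/MB` group rows, then
#' interleaves the groups in temporal rank order within each volume.  The
#' result is a single time series of length `NR * NS` with sampling rate
#' `NS / trVol`, on which cardiac fluctuations are critically sampled even
#' when the volume TR is long.
#'
#' @param signal a [SliceSignal-class] with `N` rows (pre-reduction).
#' @param params an [AcquisitionParams-class].
#' @return a [SubTrSignal-class].
#' @export
reorderToSubTr <- function(signal, params) {
  n <- params@nSlices
  if (nrow(signal@values) != n)
    stop(sprintf("signal has %d rows but params declare %d slices",
                 nrow(signal@values), n), call. = FALSE)
  if (n %% params@mbFactor != 0L)
    stop("nSlices not divisible by mbFactor", call. = FALSE)
  ns <- nGroups(params)
  nr <- ncol(signal@values)
  groupVals <- matrix(NA_real_, ns, nr)
  for (g in seq_len(ns))
    groupVals[g, ] <- colMeans(signal@values[params@sliceOrder[[g]], ,
                                             drop = FALSE])
  samples <- as.vector(groupVals)   # column-major: groups within each volume
  offsets <- if (length(params@sliceOffsets)) params@sliceOffsets
             else (seq_len(ns) - 1) * params@trVol / ns
  times <- as.vector(outer(offsets, (seq_len(nr) - 1) * params@trVol, `+`))
  new("SubTrSignal", samples = samples, rate = ns / params@trVol,
      times = times, source = signal@source)
}

#' Invert [reorderToSubTr()] for single-band data
#'
#' For `MB = 1` the reordering is a bijection; this recovers the
#' [SliceSignal-class] row matrix from a sub-TR signal.
#'
#' @param subtr a [SubTrSignal-class].
#' @param params an [AcquisitionParams-class] with `mbFactor = 1`.
#' @return a [SliceSignal-class].
#' @export
unreorderFromSubTr <- function(subtr, params) {
  if (params@mbFactor != 1L)
    stop("un-reordering is only defined for MB = 1", call. = FALSE)
  ns <- nGroups(params)
  nr <- length(subtr@samples) %/% ns
  groupVals <- matrix(subtr@samples, ns, nr)
  values <- matrix(NA_real_, params@nSlices, nr)
  for (g in seq_len(ns)) values[params@sliceOrder[[g]], ] <- groupVals[g, ]
  new("SliceSignal", values = values, trVol = params@trVol,
      source = subtr@source, detrended = TRUE)
}

#' Dump a signal as a TSV table for inspection
#'
#' @param signal a [SliceSignal-class], [SubTrSignal-class] or
#'   [PhysioWaveform-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSignalTable <- function(signal, path) {
  df <- if (is(signal, "SliceSignal")) {
    data.frame(slice = rep(seq_len(nrow(signal@values)), ncol(signal@values)),
               volume = rep(seq_len(ncol(signal@values)),
                            each = nrow(signal@values)),
               value = as.vector(signal@values))
  } else {
    data.frame(time = sampleTimes(signal), value = samples(signal))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
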