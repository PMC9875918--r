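#' @import methods
#' @importFrom stats approx coef cor fft lm.fit median mvfft poly quantile
#'   rnorm runif sd var
#' @importFrom utils head packageVersion read.delim tail write.table
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Acquisition parameters for an EPI time series
#'
#' Holds the timing and slice-grouping information needed to reconstruct the
#' acquisition order of a 2D multislice (optionally simultaneous-multislice,
#' SMS) EPI run: volume repetition time, slice count, multiband factor,
#' number of repetitions, the excitation groups in temporal order, and
#' optional within-TR excitation offsets.
#'
#' Slice indices are 1-based.  `sliceOrder` is a list with one integer vector
#' per RF excitation (in temporal order within one TR); each vector names the
#' `mbFactor` slices excited simultaneously.  When `sliceOffsets` is empty,
#' excitations are assumed uniformly spaced at `trVol / nGroups`.
#'
#' @slot trVol seconds per volume.
#' @slot nSlices number of slices N.
#' @slot mbFactor multiband factor MB; the number of excitations per TR is
#'   `NS = N / MB`.
#' @slot nReps number of repetitions (volumes) NR.
#' @slot sliceOrder list of integer vectors, one per excitation group.
#' @slot sliceOffsets numeric vector of per-group excitation times within the
#'   TR (seconds), strictly increasing in `[0, trVol)`; may be empty.
#' @seealso [acquisitionParams()] for the user-facing constructor.
#' @export
setClass("AcquisitionParams",
  representation(
    trVol = "numeric", nSlices = "integer", mbFactor = "integer",
    nReps = "integer", sliceOrder = "list", sliceOffsets = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (length(object@trVol) != 1L || !is.finite(object@trVol) || object@trVol <= 0)
    msg <- c(msg, "trVol must be a single positive number (seconds)")
  if (object@nSlices < 1L) msg <- c(msg, "nSlices must be >= 1")
  if (object@mbFactor < 1L) msg <- c(msg, "mbFactor must be >= 1")
  if (object@nReps < 1L) msg <- c(msg, "nReps must be >= 1")
  if (object@nSlices %% object@mbFactor != 0L)
    msg <- c(msg, sprintf("nSlices (%d) must be divisible by mbFactor (%d)",
                          object@nSlices, object@mbFactor))
  ns <- object@nSlices %/% object@mbFactor
  if (length(object@sliceOrder) != ns)
    msg <- c(msg, sprintf("sliceOrder must have NS = N/MB = %d groups", ns))
  else {
    sizes <- lengths(object@sliceOrder)
    if (any(sizes != object@mbFactor))
      msg <- c(msg, "every excitation group must have exactly mbFactor slices")
    all_idx <- sort(unlist(object@sliceOrder))
    if (!identical(as.integer(all_idx), seq_len(object@nSlices)))
      msg <- c(msg, "sliceOrder must contain every slice 1..N exactly once")
  }
  if (length(object@sliceOffsets)) {
    if (length(object@sliceOffsets) != ns)
      msg <- c(msg, "sliceOffsets must have one entry per excitation group")
    if (any(diff(object@sliceOffsets) <= 0))
      msg <- c(msg, "sliceOffsets must be strictly increasing")
    if (any(object@sliceOffsets < 0) || any(object@sliceOffsets >= object@trVol))
      msg <- c(msg, "sliceOffsets must lie in [0, trVol)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct acquisition parameters
#'
#' The default slice order is sequential ascending with SMS group `g`
#' containing slices `{g, g + NS, ..., g + (MB-1)*NS}`, the grouping used by
#' sequential-ascending multiband sequences.  Interleaved or custom orders
#' are given explicitly via `sliceOrder`.
#'
#' @param trVol volume repetition time in seconds.
#' @param nSlices number of slices N.
#' @param mbFactor multiband (SMS) factor MB; N must be divisible by MB.
#' @param nReps number of volumes NR.
#' @param sliceOrder optional list of integer vectors (1-based slice indices),
#'   one vector of length `mbFactor` per excitation, in temporal order.
#' @param sliceOffsets optional numeric vector of excitation times within the
#'   TR (seconds); defaults to uniform spacing `(g-1) * trVol / NS`.
#' @return an [AcquisitionParams-class] object.
#' @examples
#' p <- acquisitionParams(trVol = 0.7, nSlices = 48, mbFactor = 8, nReps = 450)
#' nGroups(p)  # 6 excitations per TR
#' @export
acquisitionParams <- function(trVol, nSlices, mbFactor = 1L, nReps,
                              sliceOrder = NULL, sliceOffsets = NULL) {
  nSlices <- as.integer(nSlices); mbFactor <- as.integer(mbFactor)
  nReps <- as.integer(nReps)
  if (is.null(sliceOrder)) {
    if (nSlices %% mbFactor != 0L)
      stop("nSlices must be divisible by mbFactor", call. = FALSE)
    ns <- nSlices %/% mbFactor
    sliceOrder <- lapply(seq_len(ns), function(g)
      as.integer(g + (seq_len(mbFactor) - 1L) * ns))
  } else {
    sliceOrder <- lapply(sliceOrder, as.integer)
  }
  new("AcquisitionParams", trVol = as.numeric(trVol), nSlices = nSlices,
      mbFactor = mbFactor, nReps = nReps, sliceOrder = sliceOrder,
      sliceOffsets = as.numeric(sliceOffsets %||% numeric()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn acquisitionParams number of excitation groups NS = N/MB.
#' @param params an `AcquisitionParams` object.
#' @export
nGroups <- function(params) params@nSlices %/% params@mbFactor

#' @export
setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf("AcquisitionParams: TRvol=%g s, N=%d slices, MB=%d (NS=%d), NR=%d\n",
              object@trVol, object@nSlices, object@mbFactor, nGroups(object),
              object@nReps))
})

#' 4D EPI magnitude (and optional phase) time series
#'
#' The pipeline's input/output container: a 4D magnitude array indexed
#' `[x, y, z, t]` (arbitrary units, nonnegative), an optional co-registered
#' phase array in radians (wrapped or unwrapped), and the acquisition
#' parameters.  The slice axis is the third array axis and the t-dimension
#' must equal the number of repetitions.
#'
#' @slot magnitude 4D numeric array, nonnegative.
#' @slot phase 4D numeric array in radians, or NULL.
#' @slot params [AcquisitionParams-class].
#' @seealso [epiSeries()], [loadEpiSeries()]
#' @export
setClass("EpiSeries",
  representation(magnitude = "array", phase = "arrayOrNULL",
                 params = "AcquisitionParams")
)

setValidity("EpiSeries", function(object) {
  msg <- character()
  dm <- dim(object@magnitude)
  if (length(dm) != 4L) msg <- c(msg, "magnitude must be a 4D array")
  else {
    if (dm[3] != object@params@nSlices)
      msg <- c(msg, sprintf("z-dimension (%d) must equal nSlices (%d)",
                            dm[3], object@params@nSlices))
    if (dm[4] != object@params@nReps)
      msg <- c(msg, sprintf("t-dimension (%d) must equal nReps (%d)",
                            dm[4], object@params@nReps))
    if (min(object@magnitude) < 0) msg <- c(msg, "magnitude values must be >= 0")
  }
  if (!is.null(object@phase) && !identical(dim(object@phase), dm))
    msg <- c(msg, "phase and magnitude must have identical dimensions")
  if (length(msg)) msg else TRUE
})

#' Construct an EpiSeries
#'
#' @param magnitude 4D numeric array `[x, y, z, t]`, nonnegative.
#' @param phase optional 4D numeric array of the same shape, radians.
#' @param params an [AcquisitionParams-class] object.
#' @return an [EpiSeries-class] object.
#' @export
epiSeries <- function(magnitude, phase = NULL, params) {
  new("EpiSeries", magnitude = magnitude, phase = phase, params = params)
}

#' Accessors for EpiSeries
#' @param object an `EpiSeries`.
#' @return `magnitude()`/`phaseData()` return the 4D arrays (`phaseData()` may
#'   be NULL); `acqParams()` the acquisition parameters.
#' @rdname EpiSeries-accessors
#' @export
setGeneric("magnitude", function(object) standardGeneric("magnitude"))
#' @rdname EpiSeries-accessors
#' @export
setMethod("magnitude", "EpiSeries", function(object) object@magnitude)
#' @rdname EpiSeries-accessors
#' @export
setGeneric("phaseData", function(object) standardGeneric("phaseData"))
#' @rdname EpiSeries-accessors
#' @export
setMethod("phaseData", "EpiSeries", function(object) object@phase)
#' @rdname EpiSeries-accessors
#' @export
setGeneric("acqParams", function(object) standardGeneric("acqParams"))
#' @rdname EpiSeries-accessors
#' @export
setMethod("acqParams", "EpiSeries", function(object) object@params)

#' @export
setMethod("show", "EpiSeries", function(object) {
  dm <- dim(object@magnitude)
  cat(sprintf("EpiSeries: %dx%dx%d voxels, %d volumes, phase %s\n",
              dm[1], dm[2], dm[3], dm[4],
              if (is.null(object@phase)) "absent" else "present"))
  show(object@params)
})

#' External physiological recording
#'
#' Respiratory-belt and plethysmograph samples on a shared regular time grid,
#' used only for validating the image-derived waveforms.
#'
#' @slot resp respiratory samples, arbitrary units.
#' @slot cardiac cardiac samples, arbitrary units.
#' @slot dt sampling interval in seconds (> 0).
#' @slot t0 time of the first sample relative to the first excitation, seconds.
#' @export
setClass("ExternalRecording",
  representation(resp = "numeric", cardiac = "numeric", dt = "numeric",
                 t0 = "numeric")
)

setValidity("ExternalRecording", function(object) {
  msg <- character()
  if (length(object@resp) != length(object@cardiac))
    msg <- c(msg, "resp and cardiac must have the same length")
  if (length(object@dt) != 1L || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "ExternalRecording", function(object) {
  cat(sprintf("ExternalRecording: %d samples at dt=%g s (%.1f s)\n",
              length(object@resp), object@dt, length(object@resp) * object@dt))
})

#' Per-slice scalar time series sampled at the volume TR
#'
#' One row per slice (or per excitation group after SMS reduction), one
#' column per volume; values are slice averages of masked voxels (for phase,
#' magnitude-weighted averages).
#'
#' @slot values matrix `[nRows x NR]`.
#' @slot trVol seconds between columns.
#' @slot source `"magnitude"` or `"phase"`.
#' @slot detrended logical.
#' @export
setClass("SliceSignal",
  representation(values = "matrix", trVol = "numeric", source = "character",
                 detrended = "logical")
)

setValidity("SliceSignal", function(object) {
  msg <- character()
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (!object@source %in% c("magnitude", "phase"))
    msg <- c(msg, "source must be 'magnitude' or 'phase'")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "SliceSignal", function(object) {
  cat(sprintf("SliceSignal (%s%s): %d rows x %d volumes at TRvol=%g s\n",
              object@source, if (object@detrended) ", detrended" else "",
              nrow(object@values), ncol(object@values), object@trVol))
})

#' Sub-TR time series
#'
#' A single scalar time series sampled at the slice repetition interval
#' `trVol / NS` (rate `NS / trVol` Hz), obtained by reordering slice-averaged
#' signals by acquisition time.  Length is `NR * NS`.
#'
#' @slot samples numeric vector of length `NR * NS`.
#' @slot rate sampling rate in Hz.
#' @slot times sample times in seconds, strictly increasing.
#' @slot source `"magnitude"` or `"phase"`.
#' @export
setClass("SubTrSignal",
  representation(samples = "numeric", rate = "numeric", times = "numeric",
                 source = "character")
)

setValidity("SubTrSignal", function(object) {
  msg <- character()
  if (length(object@samples) != length(object@times))
    msg <- c(msg, "samples and times must have equal length")
  if (any(diff(object@times) <= 0)) msg <- c(msg, "times must be strictly increasing")
  if (!object@source %in% c("magnitude", "phase"))
    msg <- c(msg, "source must be 'magnitude' or 'phase'")
  if (length(msg)) msg else TRUE
})

#' Accessors for sub-TR signals and waveforms
#' @param object a `SubTrSignal` or `PhysioWaveform`.
#' @return `samples()` the sample vector, `sampleRate()` the rate in Hz,
#'   `sampleTimes()` the time vector in seconds.
#' @rdname SubTrSignal-accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname SubTrSignal-accessors
#' @export
setMethod("samples", "SubTrSignal", function(object) object@samples)
#' @rdname SubTrSignal-accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname SubTrSignal-accessors
#' @export
setMethod("sampleRate", "SubTrSignal", function(object) object@rate)
#' @rdname SubTrSignal-accessors
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))
#' @rdname SubTrSignal-accessors
#' @export
setMethod("sampleTimes", "SubTrSignal", function(object) object@times)

#' @export
setMethod("show", "SubTrSignal", function(object) {
  cat(sprintf("SubTrSignal (%s): %d samples at %.3f Hz (%.1f s)\n",
              object@source, length(object@samples), object@rate,
              length(object@samples) / object@rate))
})

#' One-sided power spectrum
#'
#' @slot freqs frequencies in Hz, equally spaced from 0 to rate/2.
#' @slot power nonnegative power per bin (sums to the series variance).
#' @slot resolution frequency resolution in Hz.
#' @export
setClass("PowerSpectrum",
  representation(freqs = "numeric", power = "numeric", resolution = "numeric")
)

setValidity("PowerSpectrum", function(object) {
  msg <- character()
  if (length(object@freqs) != length(object@power))
    msg <- c(msg, "freqs and power must have equal length")
  if (any(object@power < 0)) msg <- c(msg, "power must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf("PowerSpectrum: %d bins, 0..%.3f Hz, resolution %.4g Hz\n",
              length(object@freqs), max(object@freqs), object@resolution))
})

#' An identified physiological fundamental frequency
#'
#' @slot f0 fundamental frequency in Hz.
#' @slot band the `[low, high]` Hz band searched.
#' @slot excluded two-column matrix (center Hz, halfwidth Hz) of notches that
#'   were zeroed during the search; may have zero rows.
#' @slot kind `"resp"` or `"cardiac"`.
#' @slot nIterations number of search iterations.
#' @export
setClass("FundamentalEstimate",
  representation(f0 = "numeric", band = "numeric", excluded = "matrix",
                 kind = "character", nIterations = "integer")
)

setValidity("FundamentalEstimate", function(object) {
  msg <- character()
  if (object@f0 < object@band[1] || object@f0 > object@band[2])
    msg <- c(msg, "f0 must lie inside the searched band")
  if (nrow(object@excluded) > 0) {
    inside <- abs(object@f0 - object@excluded[, 1]) < object@excluded[, 2]
    if (any(inside)) msg <- c(msg, "f0 must not lie inside an excluded notch")
  }
  if (!object@kind %in% c("resp", "cardiac"))
    msg <- c(msg, "kind must be 'resp' or 'cardiac'")
  if (length(msg)) msg else TRUE
})

#' @rdname FundamentalEstimate-class
#' @param object a `FundamentalEstimate`.
#' @return `fundamentalFreq()` returns the estimated frequency in Hz.
#' @export
setGeneric("fundamentalFreq", function(object) standardGeneric("fundamentalFreq"))
#' @rdname FundamentalEstimate-class
#' @export
setMethod("fundamentalFreq", "FundamentalEstimate", function(object) object@f0)

#' @export
setMethod("show", "FundamentalEstimate", function(object) {
  cat(sprintf("FundamentalEstimate (%s): f0=%.4f Hz in [%.3f, %.3f] Hz, %d notch(es), %d iteration(s)\n",
              object@kind, object@f0, object@band[1], object@band[2],
              nrow(object@excluded), object@nIterations))
})

#' A narrowband physiological waveform at the sub-TR rate
#'
#' @slot samples the band-limited waveform.
#' @slot rate sampling rate, Hz.
#' @slot times sample times, seconds.
#' @slot band `[low, high]` Hz pass band.
#' @slot kind `"resp"` or `"cardiac"`.
#' @slot source `"magnitude"` or `"phase"`.
#' @slot fundamental the [FundamentalEstimate-class] the band is centered on.
#' @export
setClass("PhysioWaveform",
  representation(samples = "numeric", rate = "numeric", times = "numeric",
                 band = "numeric", kind = "character", source = "character",
                 fundamental = "FundamentalEstimate")
)

#' @rdname SubTrSignal-accessors
#' @export
setMethod("samples", "PhysioWaveform", function(object) object@samples)
#' @rdname SubTrSignal-accessors
#' @export
setMethod("sampleRate", "PhysioWaveform", function(object) object@rate)
#' @rdname SubTrSignal-accessors
#' @export
setMethod("sampleTimes", "PhysioWaveform", function(object) object@times)

#' @export
setMethod("show", "PhysioWaveform", function(object) {
  cat(sprintf("PhysioWaveform (%s, %s): %d samples, band [%.3f, %.3f] Hz around f0=%.4f Hz\n",
              object@kind, object@source, length(object@samples),
              object@band[1], object@band[2], object@fundamental@f0))
})

#' Cycle phase of a physiological oscillation
#'
#' Phase values in `[0, 2*pi)` assigned to arbitrary query times: for cardiac,
#' linear phase between detected peaks (resetting to 0 at each peak); for
#' respiration, the amplitude-histogram convention.
#'
#' @slot phi phase values in `[0, 2*pi)`.
#' @slot times query times, seconds.
#' @slot kind `"resp"` or `"cardiac"`.
#' @export
setClass("CyclePhase",
  representation(phi = "numeric", times = "numeric", kind = "character")
)

setValidity("CyclePhase", function(object) {
  msg <- character()
  if (length(object@phi) != length(object@times))
    msg <- c(msg, "phi and times must have equal length")
  if (any(object@phi < 0) || any(object@phi >= 2 * pi))
    msg <- c(msg, "phi values must lie in [0, 2*pi)")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "CyclePhase", function(object) {
  cat(sprintf("CyclePhase (%s): %d time points\n", object@kind,
              length(object@phi)))
})

#' Per-slice physiological regressor matrices
#'
#' For each slice, an `NR x 8` design block: sine and cosine of the first two
#' harmonics of the respiratory cycle phase followed by the same for cardiac,
#' evaluated at that slice's acquisition times.  Simultaneously excited
#' slices share identical regressors.
#'
#' @slot matrices list of `NR x 8` matrices, one per slice (spatial order).
#' @slot sliceIndex integer vector of slice indices.
#' @slot sources named character vector: chosen source per kind.
#' @slot fundamentals named list of [FundamentalEstimate-class] per kind.
#' @export
setClass("RegressorSet",
  representation(matrices = "list", sliceIndex = "integer",
                 sources = "character", fundamentals = "list")
)

setValidity("RegressorSet", function(object) {
  msg <- character()
  if (length(object@matrices) != length(object@sliceIndex))
    msg <- c(msg, "one matrix per slice index required")
  bad <- vapply(object@matrices, function(m)
    ncol(m) != 8L || max(abs(m)) > 1 + 1e-9, logical(1))
  if (any(bad)) msg <- c(msg, "each matrix must have 8 columns with entries in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname RegressorSet-class
#' @param object a `RegressorSet`.
#' @param slice slice index.
#' @return `regressorMatrix()` returns one slice's `NR x 8` matrix.
#' @export
setGeneric("regressorMatrix", function(object, slice) standardGeneric("regressorMatrix"))
#' @rdname RegressorSet-class
#' @export
setMethod("regressorMatrix", "RegressorSet", function(object, slice)
  object@matrices[[match(slice, object@sliceIndex)]])

#' @export
setMethod("show", "RegressorSet", function(object) {
  cat(sprintf("RegressorSet: %d slices x %d volumes x 8 regressors (resp: %s, cardiac: %s)\n",
              length(object@matrices), nrow(object@matrices[[1]]),
              object@sources[["resp"]], object@sources[["cardiac"]]))
})

#' Outcome of the magnitude-vs-phase source selection
#'
#' @slot respSource `"magnitude"` or `"phase"`.
#' @slot cardiacSource `"magnitude"` or `"phase"`.
#' @slot improvement named numeric vector of variance-improvement fractions
#'   (`resp.magnitude`, `resp.phase`, `cardiac.magnitude`, `cardiac.phase`);
#'   entries are NA when a candidate was unavailable.
#' @export
setClass("SourceSelection",
  representation(respSource = "character", cardiacSource = "character",
                 improvement = "numeric")
)

#' @export
setMethod("show", "SourceSelection", function(object) {
  cat(sprintf("SourceSelection: resp=%s (mag %.3f / phase %.3f), cardiac=%s (mag %.3f / phase %.3f)\n",
              object@respSource,
              object@improvement[["resp.magnitude"]],
              object@improvement[["resp.phase"]],
              object@cardiacSource,
              object@improvement[["cardiac.magnitude"]],
              object@improvement[["cardiac.phase"]]))
})

#' Result of the voxelwise physiological-noise regression
#'
#' @slot corrected 4D magnitude array with the fitted physiological part
#'   subtracted (drift and mean retained).
#' @slot r2Map 3D array: fraction of each voxel's (mean-removed) variance
#'   explained by the physiological regressors; NA outside the mask.
#' @slot designInfo per-slice list with the physiological column count and
#'   rank actually used.
#' @export
setClass("CorrectionResult",
  representation(corrected = "array", r2Map = "array", designInfo = "list")
)

#' @export
setMethod("show", "CorrectionResult", function(object) {
  r2 <- object@r2Map[!is.na(object@r2Map)]
  cat(sprintf("CorrectionResult: %s volume, median physiological R^2 = %.3f\n",
              paste(dim(object@corrected), collapse = "x"),
              if (length(r2)) median(r2) else NA_real_))
})
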