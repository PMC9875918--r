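#' Load a 4D EPI series from NIfTI files
#'
#' Reads the magnitude (and optionally phase) images and checks their
#' dimensions against the acquisition parameters.  Arrays are returned in
#' `[x, y, z, t]` order; phase values are left exactly as stored (wrapped or
#' unwrapped).
#'
#' @param magnitudePath path to a 4D magnitude NIfTI.
#' @param phasePath optional path to a co-registered 4D phase NIfTI (radians).
#' @param params an [AcquisitionParams-class] object.
#' @return an [EpiSeries-class] object.
#' @export
loadEpiSeries <- function(magnitudePath, phasePath = NULL, params) {
  mag <- readNiftiArray(magnitudePath)
  if (length(dim(mag)) != 4L)
    stop("magnitude image is not 4D: ", magnitudePath, call. = FALSE)
  checkEpiDims(dim(mag), params, "magnitude")
  ph <- NULL
  if (!is.null(phasePath)) {
    ph <- readNiftiArray(phasePath)
    if (length(dim(ph)) != 4L)
      stop("phase image is not 4D: ", phasePath, call. = FALSE)
    if (!identical(dim(ph), dim(mag))) {
      ax <- which(dim(ph) != dim(mag))[1]
      stop(sprintf("phase/magnitude dimension mismatch on axis %d (%d vs %d)",
                   ax, dim(ph)[ax], dim(mag)[ax]), call. = FALSE)
    }
  }
  epiSeries(mag, ph, params)
}

readNiftiArray <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  a
}

checkEpiDims <- function(dm, params, what) {
  if (dm[3] != params@nSlices)
    stop(sprintf("%s z-dimension (%d) does not match nSlices (%d)",
                 what, dm[3], params@nSlices), call. = FALSE)
  if (dm[4] != params@nReps)
    stop(sprintf("%s t-dimension (%d) does not match nReps (%d)",
                 what, dm[4], params@nReps), call. = FALSE)
  invisible(TRUE)
}

#' Write an EpiSeries to NIfTI files
#'
#' @param series an [EpiSeries-class].
#' @param magnitudePath output path for the magnitude image.
#' @param phasePath optional output path for the phase image.
#' @param pixdim optional voxel dimensions (length 3, mm).
#' @return invisibly, the paths written.
#' @export
writeEpiSeries <- function(series, magnitudePath, phasePath = NULL,
                           pixdim = c(1, 1, 1)) {
  writeNiftiArray(series@magnitude, magnitudePath, pixdim,
                  tr = series@params@trVol)
  if (!is.null(phasePath)) {
    if (is.null(series@phase)) stop("series has no phase data", call. = FALSE)
    writeNiftiArray(series@phase, phasePath, pixdim, tr = series@params@trVol)
  }
  invisible(c(magnitudePath, phasePath))
}

writeNiftiArray <- function(a, path, pixdim = c(1, 1, 1), tr = NULL) {
  img <- RNifti::asNifti(a)
  pd <- c(pixdim, if (!is.null(tr) && length(dim(a)) == 4L) tr)
  RNifti::pixdim(img) <- pd[seq_len(length(dim(a)))]
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Per-slice acquisition times
#'
#' The acquisition time of slice `s` in volume `v` is
#' `(v-1) * trVol + offset(group(s))`, where all simultaneously excited
#' slices share their group's offset.  When no explicit offsets are given,
#' excitations are uniformly spaced at `trVol / NS`.
#'
#' @param params an [AcquisitionParams-class] object.
#' @return an `N x NR` matrix of times in seconds (rows in spatial slice
#'   order).
#' @examples
#' p <- acquisitionParams(trVol = 2, nSlices = 4, nReps = 5)
#' sliceAcquisitionTimes(p)[3, 4]  # slice 3, volume 4 -> 6 + 2*0.5 = 7 s
#' @export
sliceAcquisitionTimes <- function(params) {
  ns <- nGroups(params)
  offsets <- if (length(params@sliceOffsets)) params@sliceOffsets
             else (seq_len(ns) - 1) * params@trVol / ns
  sliceOffset <- numeric(params@nSlices)
  for (g in seq_len(ns)) sliceOffset[params@sliceOrder[[g]]] <- offsets[g]
  volStart <- (seq_len(params@nReps) - 1) * params@trVol
  outer(sliceOffset, volStart, `+`)
}

groupRank <- function(params) {
  # temporal rank (1-based) of the excitation group each slice belongs to
  ns <- nGroups(params)
  rank <- integer(params@nSlices)
  for (g in seq_len(ns)) rank[params@sliceOrder[[g]]] <- g
  rank
}

#' Load an external physiological recording
#'
#' Expects a two-column numeric table (respiratory, cardiac) in tab- or
#' whitespace-separated text, optionally with a header line naming the
#' columns `resp` and `cardiac`.
#'
#' @param path path to the table.
#' @param dt sampling interval in seconds (e.g. `1/400` for PMU traces).
#' @param t0 time of the first sample relative to the first excitation.
#' @return an [ExternalRecording-class] object.
#' @export
loadExternalRecording <- function(path, dt, t0 = 0) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("parse error: empty recording file", call. = FALSE)
  hasHeader <- grepl("[A-Za-z]", lines[1])
  dataLines <- if (hasHeader) lines[-1] else lines
  if (!length(dataLines)) stop("parse error: no data rows", call. = FALSE)
  vals <- lapply(seq_along(dataLines), function(i) {
    fields <- strsplit(trimws(dataLines[i]), "[\t ,]+")[[1]]
    v <- suppressWarnings(as.numeric(fields))
    if (length(v) < 2L || anyNA(v[1:2]))
      stop(sprintf("parse error at line %d: non-numeric row",
                   i + as.integer(hasHeader)), call. = FALSE)
    v[1:2]
  })
  m <- do.call(rbind, vals)
  new("ExternalRecording", resp = m[, 1], cardiac = m[, 2],
      dt = as.numeric(dt), t0 = as.numeric(t0))
}

#' Write an external physiological recording as TSV
#'
#' @param recording an [ExternalRecording-class].
#' @param path output path.
#' @return invisibly, the path written.
#' @export
writeExternalRecording <- function(recording, path) {
  df <- data.frame(resp = recording@resp, cardiac = recording@cardiac)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

regressorColumns <- c("resp_sin1", "resp_cos1", "resp_sin2", "resp_cos2",
                      "card_sin1", "card_cos1", "card_sin2", "card_cos2")

#' Write a regressor set as a long-format TSV table
#'
#' One row per (slice, volume) with the eight physiological columns, plus a
#' JSON sidecar recording the chosen sources, fundamental frequencies, bands
#' and software version.
#'
#' @param regressors a [RegressorSet-class].
#' @param path output TSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return invisibly, the TSV path.
#' @export
writeRegressorTable <- function(regressors, path) {
  blocks <- lapply(seq_along(regressors@sliceIndex), function(i) {
    m <- regressors@matrices[[i]]
    data.frame(slice = regressors@sliceIndex[i], volume = seq_len(nrow(m)), m)
  })
  df <- do.call(rbind, blocks)
  names(df) <- c("slice", "volume", regressorColumns)
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write regressor table to ", path, call. = FALSE)
  meta <- list(
    sources = as.list(regressors@sources),
    fundamentals_hz = lapply(regressors@fundamentals, function(f)
      if (is.null(f)) NULL else f@f0),
    bands_hz = lapply(regressors@fundamentals, function(f)
      if (is.null(f)) NULL else f@band),
    n_slices = length(regressors@sliceIndex),
    n_volumes = nrow(regressors@matrices[[1]]),
    software = paste0("prepair ", as.character(packageVersion("prepair")))
  )
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read back a regressor table written by [writeRegressorTable()]
#'
#' @param path TSV path.
#' @return a list with `matrices` (per-slice `NR x 8` matrices) and
#'   `sliceIndex`.
#' @export
readRegressorTable <- function(path) {
  df <- read.delim(path)
  slices <- sort(unique(df$slice))
  matrices <- lapply(slices, function(s) {
    block <- df[df$slice == s, , drop = FALSE]
    block <- block[order(block$volume), ]
    as.matrix(block[, regressorColumns])
  })
  list(matrices = matrices, sliceIndex = as.integer(slices))
}

#' Write a 3D map (mask, tSNR, R^2) as NIfTI
#'
#' @param map 3D numeric or logical array.
#' @param path output path.
#' @param pixdim voxel dimensions (mm).
#' @return invisibly, the path.
#' @export
writeMap <- function(map, path, pixdim = c(1, 1, 1)) {
  writeNiftiArray(array(as.numeric(map), dim = dim(map)), path, pixdim)
}
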