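#' Remove modeled physiological noise by slice-wise voxelwise regression
#'
#' Per slice, the eight physiological regressor columns are orthogonalized
#' against an intercept-plus-polynomial drift basis; each masked voxel's
#' time series is then regressed on the joint design and only the fitted
#' physiological part is subtracted, so the voxel's mean and slow drift are
#' retained and out-of-band content is untouched.  Orthogonalization
#' guarantees the corrected variance can never exceed the original.
#'
#' @param series an [EpiSeries-class] (magnitude is corrected).
#' @param regressors a [RegressorSet-class] covering every slice with
#'   matching NR.
#' @param mask logical 3D array; voxels outside it are returned unchanged.
#' @param driftOrder polynomial drift order included (but not removed),
#'   default 3.
#' @return a [CorrectionResult-class].
#' @export
regressOutPhysio <- function(series, regressors, mask, driftOrder = 3L) {
  mag <- series@magnitude
  dm <- dim(mag)
  n <- dm[3]; nt <- dm[4]
  if (!identical(dim(mask), dm[1:3]))
    stop("mask dimensions do not match the series", call. = FALSE)
  if (!all(seq_len(n) %in% regressors@sliceIndex))
    stop("regressors must cover every slice", call. = FALSE)
  if (nrow(regressors@matrices[[1]]) != nt)
    stop("regressor NR does not match the series", call. = FALSE)
  x <- seq_len(nt)
  drift <- cbind(1, if (driftOrder > 0) poly(x, driftOrder))
  qd <- qr.Q(qr(drift))
  corrected <- mag
  r2 <- array(NA_real_, dm[1:3])
  designInfo <- vector("list", n)
  for (s in seq_len(n)) {
    sel <- mask[, , s]
    X <- regressorMatrix(regressors, s)
    Xo <- X - qd %*% crossprod(qd, X)       # physio orthogonal to drift
    qx <- qr(Xo)
    rank <- qx$rank
    keep <- qx$pivot[seq_len(rank)]
    if (rank < ncol(Xo))
      message(sprintf("slice %d: dropped %d linearly dependent physiological column(s): %s",
                      s, ncol(Xo) - rank,
                      paste(colnames(X)[qx$pivot[-seq_len(rank)]],
                            collapse = ", ")))
    designInfo[[s]] <- list(nColumns = ncol(Xo), rank = rank)
    if (!any(sel) || rank == 0L) next
    Y <- t(matrix(mag[, , s, ], ncol = nt)[sel, , drop = FALSE])  # nt x V
    Xk <- Xo[, keep, drop = FALSE]
    fit <- Xk %*% qr.coef(qr(Xk), Y)
    Yc <- Y - fit
    slab <- matrix(mag[, , s, ], ncol = nt)
    slab[sel, ] <- t(Yc)
    corrected[, , s, ] <- array(slab, dim = c(dm[1], dm[2], nt))
    ssFit <- colSums(fit^2)
    ssTot <- colSums((Y - rep(colMeans(Y), each = nt))^2)
    r2s <- ifelse(ssTot > 0, ssFit / ssTot, NA_real_)
    r2slab <- array(NA_real_, dm[1:2])
    r2slab[sel] <- r2s
    r2[, , s] <- r2slab
  }
  new("CorrectionResult", corrected = corrected, r2Map = r2,
      designInfo = designInfo)
}
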