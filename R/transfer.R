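## The discrete sidelobe-mixing transfer matrix and its inversion.

#' Build the transfer matrix of the sidelobe comb
#'
#' The matrix lives on the extended scan grid: the in-FOV samples plus
#' ceiling(sidelobeSpan / pitch) padding points on each side (251 x 251
#' at the default 125-sample scan, 40 um field of view and 20 um
#' sidelobe span). Entry (i, j) is the comb weight a_l^2 of the sidelobe
#' whose object-space offset u_l / kr rounds to the grid offset
#' |i - j| * pitch; the diagonal is 1; weights of extrema that round to
#' the same grid offset add.
#'
#' A diagnostic condition number of the in-FOV block is stored. When the
#' off-diagonal row sum reaches 1 (loss of diagonal dominance) a warning
#' is issued and the matrix is flagged for ridge-regularized solves.
#'
#' @param comb a \linkS4class{BesselComb}
#' @param params an \linkS4class{AcquisitionParams} object
#' @param sidelobeSpan padding half-width in object space (um)
#' @return a \linkS4class{TransferMatrix}
#' @export
buildTransferMatrix <- function(comb, params = AcquisitionParams(),
                                sidelobeSpan = 20) {
  nFov <- params@samplesPerScan
  pitch <- scanPitch(params)
  pad <- as.integer(ceiling(sidelobeSpan / pitch))
  side <- nFov + 2L * pad
  co <- combGridOffsets(comb, pitch)
  if (max(abs(co$offsets)) > pad) {
    stop("comb sidelobes extend beyond the padded grid")
  }
  tm <- matrix(0, side, side)
  for (k in seq_along(co$offsets)) {
    d <- co$offsets[k]
    i <- seq.int(max(1L, 1L - d), min(side, side - d))
    tm[cbind(i, i + d)] <- co$weights[k]
  }
  offSum <- sum(co$weights) - 1
  regular <- offSum >= 1
  if (regular) {
    warning("transfer matrix is not diagonally dominant; ",
            "inversions will use a ridge-regularized solve")
  }
  fovIdx <- pad + seq_len(nFov)
  kap <- kappa(tm[fovIdx, fovIdx], exact = TRUE)
  new("TransferMatrix", values = tm, gridPitch = pitch, pad = pad,
      nFov = nFov, rowSum = sum(co$weights), conditioning = kap,
      regularized = regular)
}

## In-FOV block and the padding contribution (for background f = 1
## outside the field of view) of a transfer matrix.
tmBlocks <- function(tm) {
  fovIdx <- tm@pad + seq_len(tm@nFov)
  padIdx <- setdiff(seq_len(nrow(tm@values)), fovIdx)
  Tii <- tm@values[fovIdx, fovIdx, drop = FALSE]
  padContrib <- rowSums(tm@values[fovIdx, padIdx, drop = FALSE])
  list(Tii = Tii, padContrib = padContrib)
}

#' Invert per-scan signals to transmission lines
#'
#' Solves the transfer-matrix system for the in-FOV transmission line of
#' each scan. The measured scan only covers the in-FOV samples; objects
#' are confined to the field of view, so off-FOV transmission is closed
#' at the background value f = 1, whose known sidelobe contribution is
#' moved to the right-hand side. With this closure the forward model is
#' inverted exactly (direct solve); if the matrix was flagged as
#' non-dominant a ridge-regularized solve (lambda = 1e-3 trace/n) is
#' used instead.
#'
#' @param tm a \linkS4class{TransferMatrix}
#' @param scans baseline-normalized scan samples: a vector of
#'   samplesPerScan values or a matrix with one scan per column
#' @return transmission lines in the same shape as the input
#' @export
invertScans <- function(tm, scans) {
  vec <- is.null(dim(scans))
  m <- if (vec) matrix(scans, ncol = 1L) else scans
  if (nrow(m) != tm@nFov) stop("scans must have samplesPerScan rows")
  b <- tmBlocks(tm)
  rhs <- m * tm@rowSum - b$padContrib
  A <- b$Tii
  if (tm@regularized) {
    lambda <- 1e-3 * mean(diag(A))
    A <- A + diag(lambda, nrow(A))
  }
  f <- solve(A, rhs)
  if (vec) as.vector(f) else f
}

#' @rdname invertScans
#' @export
invertScan <- function(tm, scans) invertScans(tm, scans)
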