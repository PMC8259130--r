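## Waveform features: two-slit velocimetry, transit time T1, within-scan
## width T2, positive-peak count N.

## Centroid-based dip localization: center of mass of the depth over the
## contiguous region below half depth. Both velocimetry dips share the
## same shape, so any residual shape bias cancels in the time difference.
dipCenter <- function(x, t) {
  depth <- 1 - x
  dmax <- max(depth)
  if (dmax <= 0) return(NA_real_)
  idx <- which(depth > 0.4 * dmax)
  run <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  anchor <- which.max(depth)
  run <- run[[which(vapply(run, function(r) anchor %in% r, logical(1)))]]
  sum(t[run] * depth[run]) / sum(depth[run])
}

#' Estimate per-event object speed from the velocimetry channel
#'
#' Each object crossing the two velocimetry slits leaves two dips in the
#' LED transmission signal; the speed is the object-plane slit
#' separation divided by the time difference of the dip centers. Dips
#' are located on a lightly smoothed signal with sub-sample (centroid)
#' refinement. Events without two resolvable dips are flagged with NA.
#'
#' @param record a \linkS4class{WaveformRecord}
#' @param events data.frame from \code{detectEvents()}
#' @param minDepth minimum dip depth accepted (fraction of baseline)
#' @return numeric vector of speeds (cm/s), NA where estimation failed
#' @export
estimateSpeed <- function(record, events, minDepth = 0.12) {
  params <- record@params
  rateUs <- params@sampleRate * 1e-6
  sepObj <- params@ledSlitSeparation / params@magnification
  n <- length(record@speedChannel)
  vapply(seq_len(nrow(events)), function(i) {
    ## search from just before the event to after the slowest second dip
    t0 <- events$tStart[i] - 60
    t1 <- events$tEnd[i] + sepObj / (10 * CMS_TO_UMUS) + 120
    s0 <- max(1L, floor(t0 * rateUs)); s1 <- min(n, ceiling(t1 * rateUs))
    x <- record@speedChannel[s0:s1]
    k <- 31L
    xs <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2L))
    xs[is.na(xs)] <- 1
    below <- xs < 1 - minDepth
    if (!any(below)) return(NA_real_)
    idx <- which(below)
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    if (length(runs) < 2L) return(NA_real_)
    ts <- (s0:s1 - 0.5) / rateUs
    centers <- vapply(runs, function(r) {
      lo <- max(1L, min(r) - k); hi <- min(length(xs), max(r) + k)
      dipCenter(xs[lo:hi], ts[lo:hi])
    }, numeric(1))
    ## the first dip is aligned with the transmission event; the second
    ## trails by sepObj / v with v in [10, 25] cm/s
    tMid <- (events$tStart[i] + events$tEnd[i]) / 2
    i1 <- which.min(abs(centers - tMid))
    gap <- centers - centers[i1]
    lo <- 0.7 * sepObj / (25 * CMS_TO_UMUS)
    hi <- 1.3 * sepObj / (10 * CMS_TO_UMUS)
    cand <- which(gap >= lo & gap <= hi)
    if (length(cand) == 0L) return(NA_real_)
    if (length(cand) > 1L) {
      depths <- vapply(runs[cand], function(r) 1 - min(xs[r]), numeric(1))
      cand <- cand[which.max(depths)]
    }
    dt <- centers[cand] - centers[i1]
    if (!is.finite(dt) || dt <= 0) return(NA_real_)
    sepObj / dt / CMS_TO_UMUS
  }, numeric(1))
}

## Per-scan envelope of an event: minimum depth and its time, from the
## deconvolved transmission lines of the window
scanEnvelope <- function(fScans, firstScan, params) {
  rateUs <- params@sampleRate * 1e-6
  Tus <- params@scanPeriod
  n <- ncol(fScans)
  depth <- numeric(n); tMin <- numeric(n)
  for (j in seq_len(n)) {
    a <- which.min(fScans[, j])
    depth[j] <- 1 - fScans[a, j]
    tMin[j] <- (firstScan + j - 2L) * Tus + (a - 0.5) / rateUs
  }
  list(depth = depth, tMin = tMin)
}

## Noise scale of deconvolved lines, from the event's padding scans
lineSigma <- function(fScans, nPad = 2L, floorSigma = 1e-3) {
  n <- ncol(fScans)
  cols <- unique(c(seq_len(min(nPad, n)), seq.int(max(1L, n - nPad + 1L), n)))
  max(mad(fScans[, cols] - 1, center = 0), floorSigma)
}

#' Transit time T1 of an event
#'
#' T1 is the duration over which the object depresses the per-scan
#' envelope of negative peaks. The envelope is only sampled once per
#' scan, so the first-to-last-peak interval is quantized to the scan
#' period; instead, the duration is measured at the envelope's
#' half-depth crossings (interpolated on the steep, approximately
#' linear part of the slit-overlap ramp, which makes the estimate
#' sub-scan precise and independent of the scan phase). The slit ramp
#' is centered on the object edge, so the half-depth width spans the
#' object length itself; when the object's speed is supplied the known
#' slit-crossing duration slitHeight / v is added, giving the full
#' visibility window. T1 times the speed is then the object length
#' along the flow axis plus the slit height.
#'
#' @param fScans matrix of deconvolved transmission lines (one scan per
#'   column) covering the event window
#' @param firstScan scan index of the first column (1-based)
#' @param params an \linkS4class{AcquisitionParams} object
#' @param sigma noise scale of the lines (estimated from the window's
#'   padding scans when NULL)
#' @param kSigma peak-qualification threshold in sigmas
#' @param speed object speed (cm/s) used for the slit-crossing
#'   correction; omitted when NULL
#' @return list with T1 (us), firstQual/lastQual (scan indices of the
#'   first/last qualifying negative peaks) or T1 = NA when no scan
#'   qualifies
#' @export
computeT1 <- function(fScans, firstScan, params, sigma = NULL, kSigma = 4,
                      speed = NULL) {
  if (is.null(sigma)) sigma <- lineSigma(fScans)
  env <- scanEnvelope(fScans, firstScan, params)
  th <- kSigma * sigma
  qual <- which(env$depth > th)
  if (length(qual) == 0L) {
    return(list(T1 = NA_real_, firstQual = NA_integer_, lastQual = NA_integer_))
  }
  depth <- env$depth
  half <- max(depth) / 2
  idx <- which(depth > half)
  j0 <- idx[1]; j1 <- idx[length(idx)]
  tL <- env$tMin[j0]; tR <- env$tMin[j1]
  if (j0 > 1L) {
    fr <- (depth[j0] - half) / (depth[j0] - depth[j0 - 1L])
    tL <- env$tMin[j0] - fr * (env$tMin[j0] - env$tMin[j0 - 1L])
  }
  if (j1 < length(depth)) {
    fr <- (depth[j1] - half) / (depth[j1] - depth[j1 + 1L])
    tR <- env$tMin[j1] + fr * (env$tMin[j1 + 1L] - env$tMin[j1])
  }
  T1 <- tR - tL
  if (!is.null(speed) && is.finite(speed)) {
    T1 <- T1 + params@slitHeight / (speed * CMS_TO_UMUS)
  }
  list(T1 = T1, firstQual = firstScan + qual[1] - 1L,
       lastQual = firstScan + qual[length(qual)] - 1L)
}

#' Within-scan width profile T2 of an event
#'
#' For each scan, T2 is the duration of the contiguous sample run below
#' baseline - kSigma * sigma that contains the scan minimum. The widest
#' scan (T2 max) times the beam scan speed gives the object's extent
#' along the scan axis (its diameter for a round object); anchoring the
#' run at the minimum keeps a central bright spot from splitting the
#' measured region.
#'
#' @inheritParams computeT1
#' @return list with per-scan widths T2 (us, NA where the scan has no
#'   qualifying dip) and T2max (us; NA when no scan qualifies)
#' @export
computeT2Profile <- function(fScans, params, sigma = NULL, kSigma = 4) {
  if (is.null(sigma)) sigma <- lineSigma(fScans)
  rateUs <- params@sampleRate * 1e-6
  th <- 1 - kSigma * sigma
  T2 <- rep(NA_real_, ncol(fScans))
  for (j in seq_len(ncol(fScans))) {
    x <- fScans[, j]
    a <- which.min(x)
    if (x[a] >= th) next
    lo <- a; while (lo > 1L && x[lo - 1L] < th) lo <- lo - 1L
    hi <- a; while (hi < length(x) && x[hi + 1L] < th) hi <- hi + 1L
    T2[j] <- (hi - lo + 1L) / rateUs
  }
  list(T2 = T2, T2max = if (all(is.na(T2))) NA_real_ else max(T2, na.rm = TRUE))
}

#' Count positive (above-baseline) waveform peaks of an event
#'
#' Local maxima exceeding baseline + kSigma * sigma with a minimum
#' separation of \code{minSep} samples, summed over the event's scans.
#' Bright granules and forward-scattering spots produce such peaks, so
#' the count is a granularity proxy (a granule spanning several scans is
#' counted in each, which the speed multiplication N * v normalizes).
#'
#' @inheritParams computeT1
#' @param minSep minimum separation between counted peaks (samples)
#' @return integer peak count
#' @export
countPositivePeaks <- function(fScans, sigma = NULL, kSigma = 4, minSep = 2L) {
  if (is.null(sigma)) sigma <- lineSigma(fScans)
  th <- 1 + kSigma * sigma
  total <- 0L
  n <- nrow(fScans)
  for (j in seq_len(ncol(fScans))) {
    x <- fScans[, j]
    cand <- which(x > th)
    cand <- cand[cand > 1L & cand < n]
    cand <- cand[x[cand] >= x[cand - 1L] & x[cand] > x[cand + 1L]]
    if (length(cand) == 0L) next
    ## enforce the minimum separation, keeping the taller peak
    keep <- integer(0)
    for (p in cand[order(x[cand], decreasing = TRUE)]) {
      if (all(abs(keep - p) > minSep)) keep <- c(keep, p)
    }
    total <- total + length(keep)
  }
  total
}

#' Extract the per-event feature table of a record
#'
#' For every detected event the scans in its window are deconvolved
#' against the transfer matrix and the waveform features are computed:
#' transit time T1, widest within-scan width T2max, positive-peak count
#' N, and the two-slit speed v. Speed-corrected sizes follow the
#' standard axes: L = T1 * v (flow-axis length, um), W = T2max * vScan
#' (scan-axis width, um), sizeProduct = L * W (um^2) and Nv = N * v.
#' Events without a usable speed estimate or without a qualifying
#' negative peak are reason-coded in \code{flag} and excluded from
#' sorting.
#'
#' @param record a background-subtracted \linkS4class{WaveformRecord}
#' @param events data.frame from \code{detectEvents()}
#' @param tm a \linkS4class{TransferMatrix}
#' @param speeds optional per-event speeds (cm/s); estimated from the
#'   velocimetry channel when NULL
#' @param kSigma feature threshold in sigmas
#' @return data.frame with one row per event and a ground-truth label
#'   column (NA when no truth window matches)
#' @export
extractFeatures <- function(record, events, tm, speeds = NULL, kSigma = 4) {
  params <- record@params
  if (!record@backgroundSubtracted) {
    warning("record is not background-subtracted; features may be biased")
  }
  if (is.null(speeds)) speeds <- estimateSpeed(record, events)
  m <- scanMatrix(record)
  vScan <- scanSpeed(params)
  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    scans <- events$firstScan[i]:events$lastScan[i]
    f <- invertScans(tm, m[, scans, drop = FALSE])
    sigma <- lineSigma(f)
    t1 <- computeT1(f, events$firstScan[i], params, sigma, kSigma,
                    speed = speeds[i])
    t2 <- computeT2Profile(f, params, sigma, kSigma)
    npk <- countPositivePeaks(f, sigma, kSigma)
    v <- speeds[i]
    flag <- if (!is.finite(v)) "noSpeed" else if (!is.finite(t1$T1)) "noPeak" else "ok"
    L <- t1$T1 * v * CMS_TO_UMUS
    W <- t2$T2max * vScan
    lbl <- record@truth$label[record@truth$arrivalTime >= events$tStart[i] &
                               record@truth$arrivalTime <= events$tEnd[i]]
    out[[i]] <- data.frame(
      eventId = events$eventId[i], firstScan = events$firstScan[i],
      lastScan = events$lastScan[i], tStart = events$tStart[i],
      tEnd = events$tEnd[i], speed = v, T1 = t1$T1, T2max = t2$T2max,
      nPosPeaks = npk, L = L, W = W, sizeProduct = L * W,
      Nv = npk * v, flag = flag,
      truthLabel = if (length(lbl) == 1L) lbl else NA_character_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
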