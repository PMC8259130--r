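## Forward model: from a scene plan to the two-channel temporal record.

#' Construct acquisition parameters
#'
#' Defaults follow the reference operating point: 5 us scans over a
#' 40 um field of view sampled at 25 MS/s (125 samples per scan, scan
#' speed 8 m/s), a 1.5 um imaging slit, 10x detection optics, and a
#' 200 um velocimetry slit separation at the mask (20 um at the object
#' plane).
#'
#' @param scanPeriod scan duration (us)
#' @param fovY field of view along the scan axis (um)
#' @param sampleRate digitizer rate (samples/s)
#' @param slitHeight imaging-slit height at the object plane (um)
#' @param magnification detection magnification
#' @param ledSlitSeparation velocimetry slit separation at the mask (um)
#' @param noiseSigma additive Gaussian noise (fraction of baseline)
#' @param backgroundAmplitude fixed per-scan ripple amplitude
#' @return an \linkS4class{AcquisitionParams} object
#' @export
AcquisitionParams <- function(scanPeriod = 5, fovY = 40, sampleRate = 25e6,
                              slitHeight = 1.5, magnification = 10,
                              ledSlitSeparation = 200, noiseSigma = 0.01,
                              backgroundAmplitude = 0.02) {
  n <- sampleRate * scanPeriod * 1e-6
  new("AcquisitionParams", scanPeriod = scanPeriod, fovY = fovY,
      sampleRate = sampleRate, samplesPerScan = as.integer(round(n)),
      slitHeight = slitHeight, magnification = magnification,
      ledSlitSeparation = ledSlitSeparation, noiseSigma = noiseSigma,
      backgroundAmplitude = backgroundAmplitude)
}

#' Scan-grid pitch (um per sample)
#' @param params an \linkS4class{AcquisitionParams} object
#' @return pitch in um
#' @export
scanPitch <- function(params) params@fovY / params@samplesPerScan

#' Beam scan speed (um/us)
#' @param params an \linkS4class{AcquisitionParams} object
#' @return fovY / scanPeriod in um/us (1 um/us = 1 m/s)
#' @export
scanSpeed <- function(params) params@fovY / params@scanPeriod

#' Map a sample time to object-plane coordinates
#'
#' Within one scan the beam sweeps the field of view, y' = (fovY/T) t;
#' across scans the object advances with the flow, z' = v (jT + t). The
#' scan is ~40x faster than the flow, so the within-scan z' advance is
#' negligible and each scan reads out one line of the object.
#'
#' @param tInScan time since the start of the scan (us), in [0, T)
#' @param scanIndex zero-based scan counter
#' @param speed object speed (cm/s)
#' @param params an \linkS4class{AcquisitionParams} object
#' @return named vector c(y, z) in um
#' @export
temporalMapping <- function(tInScan, scanIndex, speed, params) {
  stopifnot(all(tInScan >= 0), all(tInScan <= params@scanPeriod))
  y <- scanSpeed(params) * tInScan
  z <- speed * CMS_TO_UMUS * (scanIndex * params@scanPeriod + tInScan)
  c(y = unname(y), z = unname(z))
}

## Comb offsets on the scan grid: signed grid offsets (nearest-point
## assignment) with weights of coinciding extrema summed.
combGridOffsets <- function(comb, pitch) {
  d <- round(comb@positions / comb@kr / pitch)
  agg <- tapply(comb@weights, d, sum)
  list(offsets = as.integer(names(agg)), weights = as.numeric(agg))
}

#' Per-scan response of the sidelobe comb to a transmission line
#'
#' Computes the weighted shift-sum J(y_i) = sum_l a_l^2 f(y_i - u_l/kr)
#' for the in-FOV scan positions, with sidelobe offsets assigned to the
#' nearest grid point. \code{fLine} must cover the extended grid (in-FOV
#' positions plus equal padding on both sides); off-FOV entries are the
#' background (1) unless an object reaches beyond the field of view.
#' The f = 1 baseline gives the normalization constant sum(a_l^2).
#'
#' @param fLine transmission values on the extended scan grid
#' @param comb a \linkS4class{BesselComb}
#' @param params an \linkS4class{AcquisitionParams} object
#' @return the samplesPerScan in-FOV response samples (unnormalized)
#' @export
scanResponse <- function(fLine, comb, params) {
  nFov <- params@samplesPerScan
  pad <- (length(fLine) - nFov) / 2
  if (pad != round(pad) || pad < 0) {
    stop("fLine length must be samplesPerScan + an equal padding on each side")
  }
  pad <- as.integer(pad)
  co <- combGridOffsets(comb, scanPitch(params))
  if (max(abs(co$offsets)) > pad) {
    stop("comb sidelobes extend beyond the padded grid (pitch mismatch?)")
  }
  J <- numeric(nFov)
  idx <- seq_len(nFov) + pad
  for (k in seq_along(co$offsets)) {
    J <- J + co$weights[k] * fLine[idx - co$offsets[k]]
  }
  J
}

## Slit integration kernel along z: box of slitHeight um expressed as
## fractional pixel weights (normalized).
slitKernel <- function(slitHeight, pitch) {
  half <- slitHeight / 2 / pitch
  n <- floor(half - 0.5)
  full <- if (n >= 0) rep(1, 2L * n + 1L) else numeric(0)
  fr <- half - 0.5 - n
  k <- if (fr > 1e-12) c(fr, full, fr) else full
  if (length(k) == 0L) k <- 1
  k / sum(k)
}

## Convolve map columns (z axis) with the slit kernel, padding with the
## background value 1 at the edges.
slitIntegrate <- function(map, slitHeight) {
  k <- slitKernel(slitHeight, map@pitchZ)
  if (length(k) == 1L) return(map@values)
  v <- map@values
  h <- (length(k) - 1L) / 2L
  vp <- cbind(matrix(1, nrow(v), h), v, matrix(1, nrow(v), h))
  out <- matrix(0, nrow(v), ncol(v))
  for (j in seq_along(k)) {
    out <- out + k[j] * vp[, (j - 1L) + seq_len(ncol(v)), drop = FALSE]
  }
  out
}

## Smooth seeded per-scan ripple profile with max deviation = amplitude
backgroundProfile <- function(nFov, amplitude, seed) {
  if (amplitude <= 0) return(rep(1, nFov))
  rng <- localRNG(seed)
  x <- seq(0, 2 * pi, length.out = nFov + 1L)[seq_len(nFov)]
  p <- numeric(nFov)
  for (h in 1:3) {
    p <- p + rng$runif(1, 0.3, 1) * sin(h * x + rng$runif(1, 0, 2 * pi))
  }
  1 + amplitude * p / max(abs(p))
}

#' Synthesize the two-slit LED velocimetry channel
#'
#' Each object produces two transmission dips as it crosses the two
#' velocimetry slits; the dip separation is (slit separation at the
#' object plane) / speed and the dip width is (object length + slit
#' width) / speed. Dips are raised-cosine in shape (smooth minima for
#' sub-sample localization) and additive Gaussian noise is applied.
#'
#' @param scene a \linkS4class{ScenePlan}
#' @param params an \linkS4class{AcquisitionParams} object
#' @param seed integer seed for the channel noise
#' @param nSamples record length in samples
#' @param dipDepth depth of a full dip (fraction of baseline)
#' @return numeric vector of nSamples
#' @export
synthesizeSpeedChannel <- function(scene, params, seed = 1L,
                                   nSamples = NULL, dipDepth = 0.35) {
  rateUs <- params@sampleRate * 1e-6          # samples per us
  ob <- scene@objects
  if (is.null(nSamples)) {
    nSamples <- as.integer(ceiling(recordDuration(scene, params) * rateUs))
  }
  rng <- localRNG(deriveSeed(seed, 3L))
  x <- rep(1, nSamples)
  sepObj <- params@ledSlitSeparation / params@magnification
  for (i in seq_len(nrow(ob))) {
    v <- ob$speed[i] * CMS_TO_UMUS
    width <- (ob$lengthZ[i] + 1) / v          # slit width 1 um in z
    for (tc in c(ob$arrivalTime[i], ob$arrivalTime[i] + sepObj / v)) {
      s0 <- max(1L, floor((tc - width / 2) * rateUs))
      s1 <- min(nSamples, ceiling((tc + width / 2) * rateUs))
      if (s1 < s0) next
      ts <- (s0:s1 - 0.5) / rateUs
      g <- cos(pi * (ts - tc) / width)^2
      g[abs(ts - tc) > width / 2] <- 0
      x[s0:s1] <- x[s0:s1] - dipDepth * g
    }
  }
  if (params@noiseSigma > 0) {
    x <- x + rng$rnorm(nSamples, 0, params@noiseSigma)
  }
  x
}

## Total record duration (us) needed to cover the scene plus padding
recordDuration <- function(scene, params) {
  ob <- scene@objects
  Tus <- params@scanPeriod
  if (nrow(ob) == 0L) return(40 * Tus)
  i <- nrow(ob)
  v <- ob$speed[i] * CMS_TO_UMUS
  sepObj <- params@ledSlitSeparation / params@magnification
  tail <- (ob$lengthZ[i] / 2 + params@slitHeight + 1) / v +
    sepObj / v + (ob$lengthZ[i] + 1) / (2 * v) + 12 * Tus
  ob$arrivalTime[i] + tail
}

#' Synthesize the transmission waveform of a scene
#'
#' For every scan during which an object overlaps the imaging slit, the
#' object's transmission map is integrated over the slit height along
#' the flow axis, sampled at the object's current z position, embedded
#' in a background-1 line on the extended scan grid, and passed through
#' the sidelobe comb (weighted shift-sum). The fixed per-scan background
#' ripple is multiplied in, Gaussian noise added, and the record is
#' normalized so the object-free baseline is 1.
#'
#' @param scene a \linkS4class{ScenePlan}
#' @param comb a \linkS4class{BesselComb}
#' @param params an \linkS4class{AcquisitionParams} object
#' @param seed integer master seed for noise and ripple
#' @param sidelobeSpan padding half-width (um) of the extended grid;
#'   must cover the comb offsets
#' @param maps optional list of pre-built \linkS4class{TransmissionMap}
#'   objects, one per scene object (built on demand otherwise)
#' @return a \linkS4class{WaveformRecord}
#' @export
synthesizeWaveform <- function(scene, comb, params = AcquisitionParams(),
                               seed = 1L, sidelobeSpan = 20, maps = NULL) {
  nFov <- params@samplesPerScan
  pitch <- scanPitch(params)
  pad <- as.integer(ceiling(sidelobeSpan / pitch))
  side <- nFov + 2L * pad
  co <- combGridOffsets(comb, pitch)
  if (max(abs(co$offsets)) > pad) {
    stop("sidelobeSpan too small for the comb offsets")
  }
  S <- sum(co$weights)
  Tus <- params@scanPeriod
  rateUs <- params@sampleRate * 1e-6
  ob <- scene@objects
  nScans <- as.integer(ceiling(recordDuration(scene, params) / Tus))
  M <- matrix(1, nFov, nScans)
  truth <- data.frame(label = character(0), arrivalTime = numeric(0),
                      speed = numeric(0), diameter = numeric(0),
                      firstScan = integer(0), lastScan = integer(0))
  used <- rep(FALSE, nScans)
  inIdx <- seq_len(nFov) + pad
  for (i in seq_len(nrow(ob))) {
    map <- if (!is.null(maps)) maps[[i]] else buildObjectMap(ob[i, ], pitch)
    if (abs(map@pitchY - pitch) > 1e-9) {
      stop("object map pitch must equal the scan-grid pitch")
    }
    ms <- slitIntegrate(map, params@slitHeight)
    v <- ob$speed[i] * CMS_TO_UMUS
    t0 <- ob$arrivalTime[i]
    halfWin <- (ob$lengthZ[i] + params@slitHeight) / 2 + 2 * pitch
    jRange <- which(abs(((seq_len(nScans) - 0.5) * Tus - t0) * v) <= halfWin)
    jRange <- jRange[jRange >= 1 & jRange <= nScans]
    if (length(jRange) == 0L) next
    if (any(used[jRange])) {
      stop("objects overlap in time within one interrogation window")
    }
    used[jRange] <- TRUE
    ## embed the map rows into the extended grid
    yc <- params@fovY / 2 + ob$lateralOffset[i]
    e0 <- as.integer(round(yc / pitch)) - (as.integer(round(map@origin[1])) - 1L) +
      pad + 1L
    rows <- seq_len(nrow(ms))
    keep <- (e0 + rows - 1L) >= 1L & (e0 + rows - 1L) <= side
    Fext <- matrix(1, side, length(jRange))
    zc <- map@origin[2]
    for (k in seq_along(jRange)) {
      zRel <- ((jRange[k] - 0.5) * Tus - t0) * v
      ci <- zc + zRel / map@pitchZ
      c0 <- floor(ci); w <- ci - c0
      profA <- if (c0 >= 1 && c0 <= ncol(ms)) ms[, c0] else rep(1, nrow(ms))
      profB <- if (c0 + 1 >= 1 && c0 + 1 <= ncol(ms)) ms[, c0 + 1] else rep(1, nrow(ms))
      prof <- (1 - w) * profA + w * profB
      Fext[e0 + rows[keep] - 1L, k] <- prof[keep]
    }
    J <- matrix(0, nFov, length(jRange))
    for (k in seq_along(co$offsets)) {
      J <- J + co$weights[k] * Fext[inIdx - co$offsets[k], , drop = FALSE]
    }
    M[, jRange] <- J / S
    truth <- rbind(truth, data.frame(
      label = ob$label[i], arrivalTime = t0, speed = ob$speed[i],
      diameter = ob$diameter[i], firstScan = jRange[1],
      lastScan = jRange[length(jRange)]))
  }
  bg <- backgroundProfile(nFov, params@backgroundAmplitude,
                          deriveSeed(seed, 2L))
  M <- M * bg
  if (params@noiseSigma > 0) {
    rng <- localRNG(deriveSeed(seed, 4L))
    M <- M + rng$rnorm(length(M), 0, params@noiseSigma)
  }
  sp <- synthesizeSpeedChannel(scene, params, seed = seed,
                               nSamples = nFov * nScans)
  new("WaveformRecord", transmission = as.vector(M), speedChannel = sp,
      params = params, nScans = nScans, truth = truth,
      backgroundSubtracted = FALSE)
}
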