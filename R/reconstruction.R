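## Background subtraction, event detection and 2D image assembly.

#' Remove the fixed per-scan background ripple
#'
#' Imperfections intersected by the scanning beam imprint the same
#' multiplicative profile on every scan. The profile is estimated as the
#' per-scan-position median over object-free scans (scans whose minimum
#' stays near baseline) and divided out, then the baseline is
#' renormalized to 1 using the object-free scans.
#'
#' @param record a \linkS4class{WaveformRecord}
#' @return the record with transmission background-subtracted
#' @export
subtractBackground <- function(record) {
  m <- scanMatrix(record)
  mins <- fastColMins(m)
  ## rough noise scale from per-scan minima of quiet scans
  sigmaRough <- mad(m[1L, ], center = median(m[1L, ]))
  clean <- mins > 1 - max(6 * sigmaRough, 0.04) - record@params@backgroundAmplitude
  if (!any(clean)) stop("no object-free scans found; cannot estimate background")
  if (sum(clean) < 3L) stop("need at least 3 object-free scans")
  pattern <- apply(m[, clean, drop = FALSE], 1L, median)
  pattern[pattern <= 0] <- 1
  m <- m / pattern
  base <- median(m[, clean])
  if (base > 0) m <- m / base
  new("WaveformRecord", transmission = as.vector(m),
      speedChannel = record@speedChannel, params = record@params,
      nScans = record@nScans, truth = record@truth,
      backgroundSubtracted = TRUE)
}

#' Detect object events in a background-subtracted record
#'
#' An object in the interrogation zone pulls per-scan minima below the
#' baseline. Events are maximal runs of scans whose minimum dips below
#' 1 - threshold, padded by \code{pad} clean scans on each side (the
#' padding keeps the shallow leading/trailing dips of an object inside
#' its window); overlapping padded runs merge.
#'
#' @param record a background-subtracted \linkS4class{WaveformRecord}
#' @param threshold detection depth (fraction of baseline)
#' @param pad number of padding scans on each side of a run
#' @return data.frame with eventId, firstScan, lastScan, tStart, tEnd
#'   (us); zero rows when nothing is detected
#' @export
detectEvents <- function(record, threshold = 0.08, pad = 3L) {
  m <- scanMatrix(record)
  mins <- fastColMins(m)
  hit <- mins < 1 - threshold
  empty <- data.frame(eventId = integer(0), firstScan = integer(0),
                      lastScan = integer(0), tStart = numeric(0),
                      tEnd = numeric(0))
  if (!any(hit)) return(empty)
  pad <- as.integer(pad)
  r <- rle(hit)
  ends <- as.integer(cumsum(r$lengths))
  starts <- ends - r$lengths + 1L
  first <- pmax(1L, starts[r$values] - pad)
  last <- pmin(record@nScans, ends[r$values] + pad)
  ## merge overlapping padded windows
  keepF <- first[1]; keepL <- last[1]
  outF <- integer(0); outL <- integer(0)
  for (i in seq_along(first)[-1]) {
    if (first[i] <= keepL + 1L) {
      keepL <- max(keepL, last[i])
    } else {
      outF <- c(outF, keepF); outL <- c(outL, keepL)
      keepF <- first[i]; keepL <- last[i]
    }
  }
  outF <- c(outF, keepF); outL <- c(outL, keepL)
  Tus <- record@params@scanPeriod
  data.frame(eventId = seq_along(outF), firstScan = outF, lastScan = outL,
             tStart = (outF - 1L) * Tus, tEnd = outL * Tus)
}

#' Reconstruct the 2D transmission image of one event
#'
#' Every scan in the event window is inverted against the transfer
#' matrix and the restored lines are stacked at the flow-direction pitch
#' v * T given by the event's speed (speed correction). Optionally the
#' image is resampled along z to square pixels at the scan-grid pitch
#' (bilinear); feature extraction always uses the raw grid, resampling
#' is presentation only.
#'
#' @param record a background-subtracted \linkS4class{WaveformRecord}
#' @param event one row of \code{detectEvents()} output
#' @param speed object speed (cm/s); required for the z scaling
#' @param tm a \linkS4class{TransferMatrix}
#' @param squarePixels resample rows to the scan-grid pitch
#' @return a \linkS4class{ReconstructedImage}
#' @export
reconstructImage <- function(record, event, speed, tm,
                             squarePixels = FALSE) {
  if (missing(speed) || is.null(speed) || !is.finite(speed)) {
    stop("a per-event speed estimate is required to reconstruct the image")
  }
  scans <- event$firstScan:event$lastScan
  m <- scanMatrix(record)[, scans, drop = FALSE]
  f <- invertScans(tm, m)
  img <- t(f)                                  # rows = scans (z), cols = y
  pitchZ <- speed * CMS_TO_UMUS * record@params@scanPeriod
  pitchY <- scanPitch(record@params)
  if (squarePixels && nrow(img) > 1L) {
    z <- (seq_len(nrow(img)) - 1) * pitchZ
    zi <- seq(0, max(z), by = pitchY)
    img <- apply(img, 2L, function(col) approx(z, col, zi)$y)
    pitchZ <- pitchY
  }
  new("ReconstructedImage", values = img, pitchY = pitchY,
      pitchZ = pitchZ, speed = speed,
      eventScans = as.integer(c(event$firstScan, event$lastScan)))
}
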