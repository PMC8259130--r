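#' @import methods
#' @importFrom stats approx mad median quantile rnorm runif sd setNames uniroot
#' @importFrom utils head tail read.csv write.csv write.table
NULL

## Unit conventions used throughout:
##   length  micrometres (um)
##   time    microseconds (us)
##   speed   cm/s at the user interface; 1 cm/s == 0.01 um/us internally
CMS_TO_UMUS <- 0.01

#' BeamParameters: the Bessel-Gaussian illumination beam
#'
#' Holds the parameters of the Bessel-Gaussian beam that scans across the
#' flow channel: the transverse wavevector \code{kr} which sets the J0
#' lobe spacing, the waist \code{w0} of the broad Gaussian envelope that
#' apodizes the ideal Bessel profile, the vacuum wavelength, the medium
#' refractive index, and the half-width of object-space sidelobes kept in
#' the discrete model. Only \code{kr}, \code{w0} and \code{n0} enter the
#' computations downstream; wavelength is retained as metadata (the field
#' amplitude, axial wavevector and Gouy phase of the full beam expression
#' drop out of the phase-matched transmitted-power model).
#'
#' @slot wavelength vacuum wavelength (um)
#' @slot kr transverse wavevector (rad/um)
#' @slot w0 Gaussian envelope waist (um)
#' @slot n0 refractive index of the medium (water)
#' @slot sidelobeSpan half-width of modeled sidelobes in object space (um)
#' @exportClass BeamParameters
setClass("BeamParameters",
  representation(
    wavelength = "numeric",
    kr = "numeric",
    w0 = "numeric",
    n0 = "numeric",
    sidelobeSpan = "numeric"
  )
)

setValidity("BeamParameters", function(object) {
  msg <- character()
  for (s in c("wavelength", "kr", "w0", "n0", "sidelobeSpan")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
    }
  }
  if (length(msg) == 0L) {
    if (object@kr * object@w0 <= 1) {
      msg <- c(msg, "kr * w0 must exceed 1 (envelope much broader than main lobe)")
    }
    ## the span must reach at least the first extremum of J0
    if (object@sidelobeSpan < J0_FIRST_MIN / object@kr) {
      msg <- c(msg, "sidelobeSpan must cover at least the first J0 extremum")
    }
  }
  if (length(msg)) msg else TRUE
})

#' BesselComb: delta-comb approximation of the J0 profile
#'
#' The J0 transverse profile is approximated by weighted delta functions
#' at its extrema. Positions are the dimensionless J0 arguments u_l
#' (symmetric about 0), coefficients are J0(u_l), and the weights are the
#' intensity weights a_l^2 = J0(u_l)^2 * exp(-2 u_l^2 / (kr w0)^2), i.e.
#' the squared coefficient attenuated by the Gaussian envelope. The
#' central lobe has weight exactly 1.
#'
#' @slot positions extremum arguments u_l, ordered, symmetric about 0
#' @slot coefficients J0(u_l)
#' @slot weights a_l^2 in (0, 1]
#' @slot kr transverse wavevector (rad/um), converts u_l to object-space
#'   offsets u_l / kr
#' @exportClass BesselComb
setClass("BesselComb",
  representation(
    positions = "numeric",
    coefficients = "numeric",
    weights = "numeric",
    kr = "numeric"
  )
)

setValidity("BesselComb", function(object) {
  u <- object@positions
  w <- object@weights
  msg <- character()
  if (length(u) != length(w) || length(u) != length(object@coefficients)) {
    return("positions, coefficients and weights must have equal length")
  }
  if (is.unsorted(u)) msg <- c(msg, "positions must be ordered")
  if (!any(u == 0)) msg <- c(msg, "comb must contain the central lobe u = 0")
  if (any(u == 0) && abs(w[u == 0] - 1) > 1e-12) {
    msg <- c(msg, "central lobe must have weight 1")
  }
  if (max(abs(rev(u) + u)) > 1e-9) msg <- c(msg, "positions must be symmetric about 0")
  if (max(abs(rev(w) - w)) > 1e-12) msg <- c(msg, "weights must be symmetric")
  if (any(w <= 0) || any(w > 1 + 1e-12)) msg <- c(msg, "weights must lie in (0, 1]")
  onesided <- w[u >= 0]
  if (is.unsorted(rev(onesided), strictly = TRUE)) {
    msg <- c(msg, "weights must strictly decrease with |u|")
  }
  if (length(msg)) msg else TRUE
})

#' AcquisitionParams: scan timing, sampling and detection geometry
#'
#' @slot scanPeriod duration of one beam scan (us)
#' @slot fovY field of view along the scan direction (um)
#' @slot sampleRate digitizer rate (samples/s)
#' @slot samplesPerScan samples per scan (sampleRate * scanPeriod, integer)
#' @slot slitHeight flow-direction extent of the imaging slit at the
#'   object plane (um); the slit blocks flow-direction sidelobes
#' @slot magnification detection-optics magnification
#' @slot ledSlitSeparation separation of the two velocimetry slits at the
#'   mask plane (um); object-plane separation is this / magnification
#' @slot noiseSigma additive Gaussian noise, fraction of baseline
#' @slot backgroundAmplitude amplitude of the fixed per-scan background
#'   ripple (fraction of baseline)
#' @exportClass AcquisitionParams
setClass("AcquisitionParams",
  representation(
    scanPeriod = "numeric",
    fovY = "numeric",
    sampleRate = "numeric",
    samplesPerScan = "integer",
    slitHeight = "numeric",
    magnification = "numeric",
    ledSlitSeparation = "numeric",
    noiseSigma = "numeric",
    backgroundAmplitude = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  n <- object@sampleRate * object@scanPeriod * 1e-6
  if (abs(n - round(n)) > 1e-9) {
    msg <- c(msg, "sampleRate * scanPeriod must be an integer number of samples")
  } else if (object@samplesPerScan != as.integer(round(n))) {
    msg <- c(msg, "samplesPerScan must equal sampleRate * scanPeriod")
  }
  for (s in c("scanPeriod", "fovY", "sampleRate", "slitHeight", "magnification")) {
    if (slot(object, s) <= 0) msg <- c(msg, sprintf("'%s' must be positive", s))
  }
  if (object@noiseSigma < 0 || object@backgroundAmplitude < 0) {
    msg <- c(msg, "noise and background amplitudes must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' TransmissionMap: effective 2D transmission of one object
#'
#' A grid of effective transmission f(y, z): 1 in the background, below 1
#' where the object scatters light outside the collection aperture, and
#' possibly above 1 (up to 1.3) in small-angle forward-scattering bright
#' spots. Rows index the scan (y) axis, columns the flow (z) axis.
#'
#' @slot values numeric matrix, rows = y, cols = z
#' @slot pitchY grid pitch along y (um)
#' @slot pitchZ grid pitch along z (um)
#' @slot origin (row, col) grid coordinate of the object center
#' @exportClass TransmissionMap
setClass("TransmissionMap",
  representation(
    values = "matrix",
    pitchY = "numeric",
    pitchZ = "numeric",
    origin = "numeric"
  )
)

setValidity("TransmissionMap", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (any(!is.finite(v))) msg <- c(msg, "values must be finite")
  if (any(v < 0) || any(v > 1.3 + 1e-9)) {
    msg <- c(msg, "transmission values must lie in [0, 1.3]")
  }
  if (object@pitchY <= 0 || object@pitchZ <= 0) msg <- c(msg, "pitches must be positive")
  if (length(object@origin) != 2L) msg <- c(msg, "origin must be (row, col)")
  if (length(msg)) msg else TRUE
})

#' ScenePlan: an ordered sequence of objects flowing through the system
#'
#' @slot objects data.frame with one row per object: kind, label,
#'   diameter (um), lengthZ/lengthY footprint extents (um), nGranules,
#'   granuleDiameter (um), rim/center transmission levels, speed (cm/s),
#'   arrivalTime (us), lateralOffset (um), objectSeed
#' @slot seed master seed the plan was drawn from
#' @exportClass ScenePlan
setClass("ScenePlan",
  representation(objects = "data.frame", seed = "integer")
)

setValidity("ScenePlan", function(object) {
  ob <- object@objects
  need <- c("kind", "label", "diameter", "lengthZ", "lengthY", "speed",
            "arrivalTime", "lateralOffset")
  miss <- setdiff(need, names(ob))
  if (length(miss)) return(paste("objects lacks columns:", paste(miss, collapse = ", ")))
  if (nrow(ob) > 1 && any(diff(ob$arrivalTime) <= 0)) {
    return("arrival times must be strictly increasing")
  }
  if (any(ob$speed < 10 - 1e-9) || any(ob$speed > 25 + 1e-9)) {
    return("object speeds must lie in [10, 25] cm/s")
  }
  TRUE
})

#' WaveformRecord: the simulated two-channel acquisition
#'
#' @slot transmission PMT transmission samples, baseline-normalized to 1
#' @slot speedChannel LED velocimetry channel samples
#' @slot params the AcquisitionParams used
#' @slot nScans number of complete scans in the record
#' @slot truth data.frame of ground-truth object windows (may have 0 rows)
#' @slot backgroundSubtracted logical flag
#' @exportClass WaveformRecord
setClass("WaveformRecord",
  representation(
    transmission = "numeric",
    speedChannel = "numeric",
    params = "AcquisitionParams",
    nScans = "integer",
    truth = "data.frame",
    backgroundSubtracted = "logical"
  )
)

setValidity("WaveformRecord", function(object) {
  n <- object@params@samplesPerScan
  if (length(object@transmission) != object@nScans * n) {
    return("transmission length must be nScans * samplesPerScan")
  }
  if (length(object@speedChannel) != length(object@transmission)) {
    return("speed channel must have the same length as transmission")
  }
  TRUE
})

#' TransferMatrix: the discrete sidelobe-mixing operator
#'
#' Square banded matrix on the extended scan grid (in-FOV samples plus
#' sidelobe padding on each side). Entry (i, j) carries the comb weight
#' a_l^2 of the sidelobe whose object-space offset u_l / kr rounds to the
#' grid offset |i - j|; the diagonal is 1.
#'
#' @slot values the full square matrix
#' @slot gridPitch scan-grid pitch (um)
#' @slot pad number of padding points on each side of the FOV block
#' @slot nFov number of in-FOV points
#' @slot rowSum full row sum at a central row (the f = 1 baseline response)
#' @slot conditioning condition number of the in-FOV block (diagnostic)
#' @slot regularized TRUE when diagonal dominance failed and the solver
#'   must fall back to a ridge-regularized solve
#' @exportClass TransferMatrix
setClass("TransferMatrix",
  representation(
    values = "matrix",
    gridPitch = "numeric",
    pad = "integer",
    nFov = "integer",
    rowSum = "numeric",
    conditioning = "numeric",
    regularized = "logical"
  )
)

setValidity("TransferMatrix", function(object) {
  v <- object@values
  side <- object@nFov + 2L * object@pad
  msg <- character()
  if (nrow(v) != side || ncol(v) != side) msg <- c(msg, "matrix side must be nFov + 2 * pad")
  if (any(abs(diag(v) - 1) > 1e-12)) msg <- c(msg, "diagonal must be 1")
  if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

#' ReconstructedImage: a speed-corrected 2D transmission image
#'
#' @slot values restored f, rows = scans (z axis), cols = scan samples (y)
#' @slot pitchY scan-grid pitch (um)
#' @slot pitchZ flow-direction pitch = speed * scanPeriod (um)
#' @slot speed object speed used for the z scaling (cm/s)
#' @slot eventScans (first, last) scan indices of the event window
#' @exportClass ReconstructedImage
setClass("ReconstructedImage",
  representation(
    values = "matrix",
    pitchY = "numeric",
    pitchZ = "numeric",
    speed = "numeric",
    eventScans = "integer"
  )
)

#' GateSpec: a 1D or 2D rectangular gate on waveform features
#'
#' @slot axes named list of closed intervals c(lo, hi), one per gated
#'   feature column
#' @slot target the class label the gate is meant to select
#' @exportClass GateSpec
setClass("GateSpec",
  representation(axes = "list", target = "character")
)

setValidity("GateSpec", function(object) {
  if (length(object@axes) < 1L) return("gate must have at least one axis")
  if (is.null(names(object@axes)) || any(!nzchar(names(object@axes)))) {
    return("gate axes must be named after feature columns")
  }
  for (b in object@axes) {
    if (length(b) != 2L || !(b[1] < b[2])) {
      return("each axis needs bounds c(lo, hi) with lo < hi")
    }
  }
  TRUE
})

#' SortReport: purity, yield and enrichment of a gated sort
#'
#' @slot counts named integer vector: sortedTarget (true positives),
#'   sortedOther (false positives), unsortedTarget, unsortedOther
#' @slot purity percent of sorted objects that are true targets
#' @slot yield percent of targets captured by the gate
#' @slot enrichment target:background odds after sorting over odds before
#' @slot target the gated class label
#' @exportClass SortReport
setClass("SortReport",
  representation(
    counts = "integer",
    purity = "numeric",
    yield = "numeric",
    enrichment = "numeric",
    target = "character"
  )
)

## ---- show methods -------------------------------------------------------

setMethod("show", "BeamParameters", function(object) {
  cat("BeamParameters\n")
  cat(sprintf("  wavelength: %.4g um   kr: %.6g rad/um   w0: %.4g um\n",
              object@wavelength, object@kr, object@w0))
  cat(sprintf("  n0: %.4g   sidelobe span: %.4g um\n", object@n0, object@sidelobeSpan))
  cat(sprintf("  main-lobe intensity FWHM: %.4g um\n", mainLobeFWHM(object)))
})

setMethod("show", "BesselComb", function(object) {
  k <- sum(object@positions > 0)
  cat(sprintf("BesselComb: central lobe + %d sidelobes per side (kr = %.4g rad/um)\n",
              k, object@kr))
  cat(sprintf("  one-sided weight sum: %.4g   baseline response: %.6g\n",
              sum(object@weights[object@positions > 0]), sum(object@weights)))
})

setMethod("show", "AcquisitionParams", function(object) {
  cat("AcquisitionParams\n")
  cat(sprintf("  scan: %g us over %g um (%d samples, %.3g MS/s)\n",
              object@scanPeriod, object@fovY, object@samplesPerScan,
              object@sampleRate / 1e6))
  cat(sprintf("  slit height: %g um   magnification: %gx   LED slit sep: %g um (mask)\n",
              object@slitHeight, object@magnification, object@ledSlitSeparation))
  cat(sprintf("  noise sigma: %g   background ripple: %g\n",
              object@noiseSigma, object@backgroundAmplitude))
})

setMethod("show", "TransmissionMap", function(object) {
  cat(sprintf("TransmissionMap: %d x %d grid at %.3g x %.3g um pitch, f in [%.3g, %.3g]\n",
              nrow(object@values), ncol(object@values), object@pitchY,
              object@pitchZ, min(object@values), max(object@values)))
})

setMethod("show", "ScenePlan", function(object) {
  cat(sprintf("ScenePlan: %d objects (seed %d)\n", nrow(object@objects), object@seed))
  if (nrow(object@objects)) {
    print(table(object@objects$label))
  }
})

setMethod("show", "WaveformRecord", function(object) {
  cat(sprintf("WaveformRecord: %d scans (%.3g ms), %d truth objects%s\n",
              object@nScans,
              object@nScans * object@params@scanPeriod / 1e3,
              nrow(object@truth),
              if (object@backgroundSubtracted) ", background-subtracted" else ""))
})

setMethod("show", "TransferMatrix", function(object) {
  cat(sprintf("TransferMatrix: %d x %d (pad %d, FOV %d), cond(FOV block) = %.3g%s\n",
              nrow(object@values), ncol(object@values), object@pad, object@nFov,
              object@conditioning,
              if (object@regularized) " [regularized solve]" else ""))
})

setMethod("show", "ReconstructedImage", function(object) {
  cat(sprintf("ReconstructedImage: %d scans x %d samples, pitch %.3g x %.3g um, v = %.3g cm/s\n",
              nrow(object@values), ncol(object@values), object@pitchZ,
              object@pitchY, object@speed))
})

setMethod("show", "SortReport", function(object) {
  cat(sprintf("SortReport (target '%s')\n", object@target))
  cat(sprintf("  sorted: %d target + %d other -> purity %.1f%%\n",
              object@counts["sortedTarget"], object@counts["sortedOther"],
              object@purity))
  cat(sprintf("  yield: %.1f%%   enrichment: %.3g\n", object@yield, object@enrichment))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for BesselFlow containers
#'
#' Small read-only accessors so user code does not touch slots directly.
#'
#' @param x the object
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
combPositions <- function(x) x@positions

#' @rdname accessors
#' @export
combCoefficients <- function(x) x@coefficients

#' @rdname accessors
#' @export
combWeightValues <- function(x) x@weights

#' @rdname accessors
#' @export
mapValues <- function(x) x@values

#' @rdname accessors
#' @export
mapPitch <- function(x) c(y = x@pitchY, z = x@pitchZ)

#' @rdname accessors
#' @export
sceneObjects <- function(x) x@objects

#' @rdname accessors
#' @export
waveTransmission <- function(x) x@transmission

#' @rdname accessors
#' @export
waveSpeedChannel <- function(x) x@speedChannel

#' @rdname accessors
#' @export
waveParams <- function(x) x@params

#' @rdname accessors
#' @export
waveTruth <- function(x) x@truth

#' @rdname accessors
#' @export
tmValues <- function(x) x@values

#' @rdname accessors
#' @export
tmConditionNumber <- function(x) x@conditioning

#' @rdname accessors
#' @export
imageValues <- function(x) x@values

#' @rdname accessors
#' @export
sortCounts <- function(x) x@counts

#' @rdname accessors
#' @export
sortPurity <- function(x) x@purity

#' @rdname accessors
#' @export
sortYield <- function(x) x@yield

#' @rdname accessors
#' @export
sortEnrichment <- function(x) x@enrichment

#' Scan-wise view of a waveform record
#'
#' @param x a WaveformRecord
#' @param channel "transmission" or "speed"
#' @return matrix with samplesPerScan rows and nScans columns
#' @export
scanMatrix <- function(x, channel = c("transmission", "speed")) {
  channel <- match.arg(channel)
  v <- if (channel == "transmission") x@transmission else x@speedChannel
  matrix(v, nrow = x@params@samplesPerScan, ncol = x@nScans)
}
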