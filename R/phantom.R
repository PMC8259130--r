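## Synthetic phantoms: effective 2D transmission maps for beads, cells
## and algal colonies. Maps specify the effective transmission f(y, z)
## directly (dark scattering rims, bright forward-scattering spots); the
## Fresnel-style index-to-transmission map is provided for index-defined
## phantoms but is far too weak to explain observed bead contrast (a
## polystyrene bead in water gives f ~ 0.99), which is why phantom
## contrast is specified at the effective level.

#' Effective transmission of a thin layer of raised refractive index
#'
#' For a projected index contrast \code{deltaN} over a medium of index
#' \code{n0}, the no-absorption transmission coefficient of the
#' phase-matched model is 4 n0 (n0 + deltaN) / (2 n0 + deltaN)^2. It
#' equals 1 at deltaN = 0 and decreases monotonically with deltaN.
#'
#' @param deltaN projected index contrast, must be >= 0 (cells and beads
#'   are denser than water)
#' @param n0 medium refractive index
#' @return transmission in (0, 1]
#' @export
#' @examples
#' transmissionFromIndex(0.27, 1.33)  # polystyrene bead in water
transmissionFromIndex <- function(deltaN, n0 = 1.33) {
  if (any(!is.finite(deltaN)) || any(deltaN < 0)) {
    stop("deltaN must be non-negative (objects are denser than the medium)")
  }
  if (any(n0 <= 0)) stop("n0 must be positive")
  4 * n0 * (n0 + deltaN) / (2 * n0 + deltaN)^2
}

## Smoothstep ramp on [0, 1]
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

## Square grid of radial distances for a disk phantom
radiusGrid <- function(halfSize, pitch) {
  n <- 2L * ceiling(halfSize / pitch) + 1L
  ax <- (seq_len(n) - (n + 1L) / 2L) * pitch
  list(n = n, ax = ax,
       r = sqrt(outer(ax^2, ax^2, "+")))
}

#' Synthetic polystyrene bead phantom
#'
#' A circular disk whose transmission drops to \code{rimTransmission}
#' over an outer annulus (standing in for large-angle scattering at the
#' bead boundary) and rises to \code{centerTransmission} in a small
#' central spot (small-angle forward scattering through the bead
#' center). The disk body sits slightly above the rim level; outside the
#' disk the map is exactly 1.
#'
#' @param diameter bead diameter (um)
#' @param rimTransmission darkest rim transmission, in (0, 1)
#' @param centerTransmission central bright-spot transmission, >= 1
#'   (clipped at 1.3)
#' @param pitch grid pitch (um); must be <= diameter / 4
#' @return a \linkS4class{TransmissionMap}
#' @export
makeBead <- function(diameter, rimTransmission = 0.45,
                     centerTransmission = 1.25, pitch = 0.32) {
  stopifnot(diameter > 0)
  if (!(rimTransmission > 0 && rimTransmission < 1) && rimTransmission != 1) {
    stop("rimTransmission must lie in (0, 1) (or 1 for an invisible bead)")
  }
  if (centerTransmission < 1) stop("centerTransmission must be >= 1")
  if (pitch > diameter / 4) {
    stop("pitch too coarse to resolve the bead (need pitch <= diameter / 4)")
  }
  R <- diameter / 2
  g <- radiusGrid(R + pitch, pitch)
  body <- rimTransmission + 0.15 * (1 - rimTransmission)
  wr <- max(0.15 * diameter, 2 * pitch)     # rim annulus width
  base <- body + (rimTransmission - body) *
    smoothstep((g$r - (R - wr)) / wr)
  rs <- min(diameter / 6, 1.25)             # bright-spot radius (um)
  spot <- (centerTransmission - body) * cos(pi * pmin(g$r, rs) / (2 * rs))^2
  fin <- pmin(pmax(base + spot, 0), 1.3)
  ## anti-aliased edge: fraction of each boundary pixel inside the disk
  cov <- pmin(pmax((R - g$r) / pitch + 0.5, 0), 1)
  f <- 1 + cov * (fin - 1)
  ctr <- (g$n + 1) / 2
  new("TransmissionMap", values = f, pitchY = pitch, pitchZ = pitch,
      origin = c(ctr, ctr))
}

#' Synthetic cell phantom with intracellular granules
#'
#' A smooth disk (transmission slightly below 1, darker at the membrane
#' rim) carrying \code{nGranules} granules placed at random inside the
#' cell: half bright (forward-scattering organelles rising above the
#' baseline, the source of positive waveform peaks) and half dark.
#' Placement is seeded and enforces a minimum center separation of one
#' granule diameter; infeasible packings fail after bounded retries.
#'
#' @param diameter cell diameter (um)
#' @param nGranules number of granules (>= 0); \code{ceiling(n/2)} are
#'   bright, the rest dark
#' @param granuleDiameter granule diameter (um)
#' @param granuleContrast transmission excursion relative to the
#'   background: bright granules peak at min(1 + granuleContrast, 1.3),
#'   dark granules dip to body - granuleContrast
#' @param seed integer seed for reproducible placement
#' @param pitch grid pitch (um)
#' @return a \linkS4class{TransmissionMap}
#' @export
makeCell <- function(diameter, nGranules = 0L, granuleDiameter = 2.5,
                     granuleContrast = 0.3, seed = 1L, pitch = 0.32) {
  stopifnot(diameter > 0, nGranules >= 0)
  if (pitch > diameter / 4) stop("pitch too coarse to resolve the cell")
  if (nGranules > 0 && granuleDiameter > 0.75 * diameter) {
    stop("granules must fit inside the cell")
  }
  R <- diameter / 2
  g <- radiusGrid(R + pitch, pitch)
  inside <- g$r <= R
  body <- 0.85
  rimLevel <- 0.72
  we <- max(0.12 * diameter, 2 * pitch)
  base <- body + (rimLevel - body) * smoothstep((g$r - (R - we)) / we)
  cov <- pmin(pmax((R - g$r) / pitch + 0.5, 0), 1)
  f <- 1 + cov * (base - 1)
  if (nGranules > 0) {
    rng <- localRNG(seed)
    rg <- granuleDiameter / 2
    rmax <- max(0.6 * R, R - rg)
    minSep <- 0.7 * granuleDiameter    # granules may touch, not coincide
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < nGranules) {
      tries <- tries + 1L
      if (tries > 800L * nGranules) {
        stop("could not place granules without overlap (infeasible packing)")
      }
      th <- rng$runif(1, 0, 2 * pi)
      rr <- rmax * sqrt(rng$runif(1))
      cand <- c(rr * cos(th), rr * sin(th))
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= minSep) {
        centers <- rbind(centers, cand)
      }
    }
    nBright <- ceiling(nGranules / 2)
    bright <- rep(c(TRUE, FALSE), length.out = nGranules)
    bright <- bright[order(rng$runif(nGranules))]
    if (sum(bright) != nBright) {  # enforce the deterministic split
      bright <- c(rep(TRUE, nBright), rep(FALSE, nGranules - nBright))
      bright <- bright[order(rng$runif(nGranules))]
    }
    brightPeak <- min(1 + granuleContrast, 1.3)
    darkTrough <- max(body - granuleContrast, 0)
    for (i in seq_len(nGranules)) {
      d <- sqrt(outer((g$ax - centers[i, 1])^2, (g$ax - centers[i, 2])^2, "+"))
      sel <- d < rg & inside
      tgt <- if (bright[i]) brightPeak else darkTrough
      bump <- cos(pi * d[sel] / (2 * rg))^2
      f[sel] <- f[sel] + (tgt - f[sel]) * bump
    }
  }
  f <- pmin(pmax(f, 0), 1.3)
  ctr <- (g$n + 1) / 2
  new("TransmissionMap", values = f, pitchY = pitch, pitchZ = pitch,
      origin = c(ctr, ctr))
}

#' Synthetic linear algal colony phantom
#'
#' Colonial green algae form flat linear colonies of 1, 2, 4 or 8
#' elongated cells lying side by side. Each cell is an ellipse with its
#' long axis across the flow, and cells stack along the flow (z) axis,
#' so the colony footprint is about nCells * cellWidth long in z and
#' cellLength wide in y.
#'
#' @param nCells colony size, one of 1, 2, 4, 8
#' @param cellLength ellipse major axis (um), across the flow
#' @param cellWidth ellipse minor axis (um), along the flow
#' @param pitch grid pitch (um)
#' @return a \linkS4class{TransmissionMap}
#' @export
makeAlgaColony <- function(nCells = 4L, cellLength = 10, cellWidth = 4,
                           pitch = 0.32) {
  if (!nCells %in% c(1L, 2L, 4L, 8L)) stop("nCells must be one of 1, 2, 4, 8")
  stopifnot(cellLength > 0, cellWidth > 0)
  halfY <- cellLength / 2 + pitch
  halfZ <- nCells * cellWidth / 2 + pitch
  ny <- 2L * ceiling(halfY / pitch) + 1L
  nz <- 2L * ceiling(halfZ / pitch) + 1L
  ay <- (seq_len(ny) - (ny + 1L) / 2L) * pitch
  az <- (seq_len(nz) - (nz + 1L) / 2L) * pitch
  f <- matrix(1, ny, nz)
  zCenters <- (seq_len(nCells) - (nCells + 1) / 2) * cellWidth
  body <- 0.62
  for (zc in zCenters) {
    e <- outer((ay / (cellLength / 2))^2, ((az - zc) / (cellWidth / 2))^2, "+")
    sel <- e <= 1
    ## darker toward each cell boundary, like a chloroplast-filled cell
    f[sel] <- pmin(f[sel], body + 0.18 * e[sel])
  }
  new("TransmissionMap", values = f, pitchY = pitch, pitchZ = pitch,
      origin = c((ny + 1) / 2, (nz + 1) / 2))
}

## Footprint extents (um) along y and z for scene bookkeeping
objectExtents <- function(kind, diameter, nCells = 1, cellLength = 10,
                          cellWidth = 4) {
  if (kind == "alga_colony") {
    c(y = cellLength, z = nCells * cellWidth)
  } else {
    c(y = diameter, z = diameter)
  }
}

#' Build the transmission map for one scene object
#'
#' Dispatch helper mapping a row of a \linkS4class{ScenePlan} object
#' table to its phantom generator.
#'
#' @param object one-row data.frame from \code{sceneObjects()}
#' @param pitch grid pitch (um)
#' @return a \linkS4class{TransmissionMap}
#' @export
buildObjectMap <- function(object, pitch = 0.32) {
  stopifnot(is.data.frame(object), nrow(object) == 1L)
  switch(object$kind,
    bead = makeBead(object$diameter, object$rimTransmission,
                    object$centerTransmission, pitch),
    cell = makeCell(object$diameter, object$nGranules,
                    min(object$granuleDiameter, 0.4 * object$diameter),
                    object$granuleContrast,
                    seed = object$objectSeed, pitch = pitch),
    alga_colony = makeAlgaColony(object$nCells, object$cellLength,
                                 object$cellWidth, pitch),
    stop("unknown object kind: ", object$kind)
  )
}
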