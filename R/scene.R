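## Scene planning: draw a mixture of objects with sizes, speeds and
## non-overlapping arrival times.

#' Describe one object class of a scene mixture
#'
#' @param label ground-truth class label
#' @param kind phantom kind: "bead", "cell" or "alga_colony"
#' @param count number of objects of this class
#' @param diameter mean diameter (um); for colonies this is the cell
#'   length across the flow
#' @param sizeCV coefficient of variation of the diameter (0.03 for
#'   beads, 0.10 for cells by default)
#' @param rimTransmission,centerTransmission bead phantom levels
#' @param nGranules granule count, a single value or a c(lo, hi) range
#'   sampled uniformly per cell
#' @param granuleDiameter,granuleContrast granule geometry/contrast
#' @param nCells colony size for "alga_colony" (1, 2, 4 or 8)
#' @param cellWidth colony cell width along the flow (um)
#' @return a list suitable for \code{makeScene(classes = ...)}
#' @export
sceneClass <- function(label, kind = c("bead", "cell", "alga_colony"),
                       count, diameter = 10,
                       sizeCV = if (kind[1] == "bead") 0.03 else 0.10,
                       rimTransmission = 0.45, centerTransmission = 1.25,
                       nGranules = 0L, granuleDiameter = 2.5,
                       granuleContrast = 0.3, nCells = 4L, cellWidth = 4) {
  kind <- match.arg(kind)
  stopifnot(count >= 1, diameter > 0, sizeCV >= 0)
  list(label = label, kind = kind, count = as.integer(count),
       diameter = diameter, sizeCV = sizeCV,
       rimTransmission = rimTransmission,
       centerTransmission = centerTransmission,
       nGranules = as.integer(nGranules),
       granuleDiameter = granuleDiameter,
       granuleContrast = granuleContrast,
       nCells = as.integer(nCells), cellWidth = cellWidth)
}

#' Draw a scene plan from a class mixture
#'
#' Objects of all classes are pooled and presented in random order.
#' Per-object diameters are normal with the class coefficient of
#' variation (truncated at 3 CV), speeds are uniform on [10, 25] cm/s,
#' lateral offsets uniform on +/- 2 um, and arrival times are spaced so
#' that no two objects overlap within one interrogation window
#' (transmission event plus both velocimetry dips plus clean-scan
#' padding).
#'
#' @param classes list of \code{sceneClass()} descriptions
#' @param params an \linkS4class{AcquisitionParams} object
#' @param seed integer master seed
#' @return a \linkS4class{ScenePlan}
#' @export
makeScene <- function(classes, params = AcquisitionParams(), seed = 1L) {
  stopifnot(length(classes) >= 1L)
  rng <- localRNG(deriveSeed(seed, 1L))
  rows <- list()
  for (cl in classes) {
    for (i in seq_len(cl$count)) {
      d <- cl$diameter * (1 + pmin(pmax(rng$rnorm(1), -3), 3) * cl$sizeCV)
      ng <- if (length(cl$nGranules) == 2L) {
        cl$nGranules[1] + rng$sample(cl$nGranules[2] - cl$nGranules[1] + 1L, 1L) - 1L
      } else cl$nGranules
      ext <- objectExtents(cl$kind, d, cl$nCells, d, cl$cellWidth)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = cl$kind, label = cl$label, diameter = d,
        lengthY = unname(ext["y"]), lengthZ = unname(ext["z"]),
        rimTransmission = cl$rimTransmission,
        centerTransmission = cl$centerTransmission,
        nGranules = as.integer(ng),
        granuleDiameter = cl$granuleDiameter,
        granuleContrast = cl$granuleContrast,
        nCells = cl$nCells, cellLength = d, cellWidth = cl$cellWidth,
        speed = rng$runif(1, 10, 25),
        lateralOffset = rng$runif(1, -2, 2),
        stringsAsFactors = FALSE)
    }
  }
  ob <- do.call(rbind, rows)
  ob <- ob[rng$sample(nrow(ob)), , drop = FALSE]
  rownames(ob) <- NULL
  ob$objectSeed <- vapply(seq_len(nrow(ob)), function(i) {
    deriveSeed(seed, 1000L + i)
  }, integer(1))

  ## arrival spacing: each object owns [t - head, t + tail] where the
  ## head/tail cover the transmission event, the trailing velocimetry
  ## dip, and clean-scan padding on both sides
  Tus <- params@scanPeriod
  sepObj <- params@ledSlitSeparation / params@magnification
  v <- ob$speed * CMS_TO_UMUS
  head <- (ob$lengthZ / 2 + params@slitHeight + 1) / v + 10 * Tus
  tail <- head + sepObj / v + (ob$lengthZ + 1) / (2 * v)
  t <- numeric(nrow(ob))
  t[1] <- head[1] + 10 * Tus
  if (nrow(ob) > 1) {
    for (i in 2:nrow(ob)) {
      t[i] <- t[i - 1] + tail[i - 1] + head[i] + rng$runif(1, 30, 120)
    }
  }
  ob$arrivalTime <- t
  new("ScenePlan", objects = ob, seed = as.integer(seed))
}
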