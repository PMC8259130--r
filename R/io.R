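## Plain-text serialization: waveform CSV containers with key=value
## headers, transmission-map CSV/TIFF export, JSON reports.

#' Write a waveform record to a CSV container
#'
#' One row per sample with both channels; acquisition metadata is kept
#' in commented key=value header lines and the ground-truth windows in
#' a JSON sidecar next to the CSV.
#'
#' @param record a \linkS4class{WaveformRecord}
#' @param path output CSV path
#' @return the path, invisibly
#' @export
writeWaveformCSV <- function(record, path) {
  p <- record@params
  hdr <- c(
    sprintf("#sample_rate=%.10g", p@sampleRate),
    sprintf("#scan_period_us=%.10g", p@scanPeriod),
    sprintf("#fov_um=%.10g", p@fovY),
    sprintf("#slit_height_um=%.10g", p@slitHeight),
    sprintf("#magnification=%.10g", p@magnification),
    sprintf("#led_slit_separation_um=%.10g", p@ledSlitSeparation),
    sprintf("#noise_sigma=%.10g", p@noiseSigma),
    sprintf("#background_amplitude=%.10g", p@backgroundAmplitude),
    sprintf("#n_scans=%d", record@nScans),
    sprintf("#background_subtracted=%d", as.integer(record@backgroundSubtracted))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("sample,transmission,speed_channel", con)
  writeLines(paste(seq_along(record@transmission),
                   formatC(record@transmission, format = "g", digits = 12),
                   formatC(record@speedChannel, format = "g", digits = 12),
                   sep = ","), con)
  jsonlite::write_json(record@truth, paste0(path, ".truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(path)
}

#' Read a waveform record written by \code{writeWaveformCSV}
#'
#' @param path CSV path
#' @return a \linkS4class{WaveformRecord}
#' @export
readWaveformCSV <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  num <- function(k) as.numeric(meta[[k]])
  params <- AcquisitionParams(
    scanPeriod = num("scan_period_us"), fovY = num("fov_um"),
    sampleRate = num("sample_rate"), slitHeight = num("slit_height_um"),
    magnification = num("magnification"),
    ledSlitSeparation = num("led_slit_separation_um"),
    noiseSigma = num("noise_sigma"),
    backgroundAmplitude = num("background_amplitude"))
  d <- read.csv(path, comment.char = "#")
  truthPath <- paste0(path, ".truth.json")
  truth <- if (file.exists(truthPath)) {
    as.data.frame(jsonlite::read_json(truthPath, simplifyVector = TRUE))
  } else {
    data.frame(label = character(0), arrivalTime = numeric(0),
               speed = numeric(0), diameter = numeric(0),
               firstScan = integer(0), lastScan = integer(0))
  }
  new("WaveformRecord", transmission = d$transmission,
      speedChannel = d$speed_channel, params = params,
      nScans = as.integer(num("n_scans")), truth = truth,
      backgroundSubtracted = as.logical(num("background_subtracted")))
}

#' Write a transmission map or reconstructed image as CSV
#'
#' @param x a \linkS4class{TransmissionMap} or
#'   \linkS4class{ReconstructedImage}
#' @param path output CSV path
#' @return the path, invisibly
#' @export
writeImageCSV <- function(x, path) {
  v <- x@values
  hdr <- if (is(x, "TransmissionMap")) {
    c(sprintf("#pitch_y_um=%.10g", x@pitchY),
      sprintf("#pitch_z_um=%.10g", x@pitchZ),
      sprintf("#origin=%.10g,%.10g", x@origin[1], x@origin[2]))
  } else {
    c(sprintf("#pitch_y_um=%.10g", x@pitchY),
      sprintf("#pitch_z_um=%.10g", x@pitchZ),
      sprintf("#speed_cms=%.10g", x@speed))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(v, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an image as 32-bit float TIFF (requires the tiff package)
#'
#' Values are stored unscaled; transmissions above 1 are preserved.
#'
#' @param x a \linkS4class{TransmissionMap} or
#'   \linkS4class{ReconstructedImage}
#' @param path output TIFF path
#' @return the path, invisibly
#' @export
writeImageTIFF <- function(x, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export")
  }
  ## 32-bit float storage carries values above 1 (bright spots); the
  ## [0,1]-range warning only concerns integer formats
  suppressWarnings(tiff::writeTIFF(x@values, path, bits.per.sample = 32L,
                                   reduce = FALSE))
  invisible(path)
}

#' Write a sort report (plus provenance) as JSON
#'
#' @param report a \linkS4class{SortReport}
#' @param path output JSON path
#' @param meta optional named list of provenance fields (config hash,
#'   seed, ...)
#' @return the path, invisibly
#' @export
writeSortReportJSON <- function(report, path, meta = list()) {
  x <- c(list(
    target = report@target,
    counts = as.list(setNames(as.integer(report@counts),
                              names(report@counts))),
    purity_percent = report@purity,
    yield_percent = report@yield,
    enrichment = if (is.finite(report@enrichment)) report@enrichment else "Inf"
  ), meta)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize / restore a scene plan as JSON
#'
#' @param scene a \linkS4class{ScenePlan}
#' @param path JSON path
#' @return the path (write) or a \linkS4class{ScenePlan} (read)
#' @export
writeScenePlanJSON <- function(scene, path) {
  jsonlite::write_json(list(seed = scene@seed, objects = scene@objects),
                       path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' @rdname writeScenePlanJSON
#' @export
readScenePlanJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ob <- as.data.frame(x$objects)
  ob$objectSeed <- as.integer(ob$objectSeed)
  ob$nGranules <- as.integer(ob$nGranules)
  ob$nCells <- as.integer(ob$nCells)
  new("ScenePlan", objects = ob, seed = as.integer(x$seed))
}
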