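## Run configuration: defaults, YAML loading, validation, demo scenes.

#' Default run configuration
#'
#' The complete configuration tree with every default explicit. The beam
#' kr is left NULL, which means "match the 1.2 um main-lobe FWHM".
#'
#' @return nested list
#' @export
defaultConfig <- function() {
  list(
    beam = list(
      wavelength_um = 0.488, kr_rad_per_um = NULL, w0_um = 10,
      fwhm_um = 1.2, n0 = 1.33, sidelobe_span_um = 20
    ),
    acquisition = list(
      scan_period_us = 5, fov_um = 40, sample_rate = 25e6,
      slit_height_um = 1.5, magnification = 10,
      led_slit_separation_um = 200, noise_sigma = 0.01,
      background_amplitude = 0.02
    ),
    scene = list(
      classes = list()
    ),
    detection = list(threshold = 0.08, pad_scans = 3),
    features = list(k_sigma = 4),
    gate = list(method = "valley", axes = list("sizeProduct"),
                target = NULL, side = "above", bounds = NULL)
  )
}

## Recursive merge of user values over defaults, erroring on unknown keys
mergeConfig <- function(defaults, user, path = "") {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults) &&
        !path %in% c("scene", "gate.bounds")) {
      stop("unknown configuration key: ", here)
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !key %in% c("classes", "axes", "bounds")) {
      defaults[[key]] <- mergeConfig(defaults[[key]], user[[key]], here)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a YAML run configuration
#'
#' Values omitted from the file keep their defaults; unknown keys raise
#' an error naming the offending key.
#'
#' @param path YAML file
#' @return validated configuration list
#' @export
loadConfig <- function(path) {
  mergeConfig(defaultConfig(), yaml::read_yaml(path))
}

#' @rdname loadConfig
#' @param config a configuration list (possibly partial)
#' @export
normalizeConfig <- function(config) {
  mergeConfig(defaultConfig(), config)
}

## Builders from configuration sections
beamFromConfig <- function(config) {
  b <- config$beam
  BeamParameters(kr = b$kr_rad_per_um, w0 = b$w0_um, fwhm = b$fwhm_um,
                 wavelength = b$wavelength_um, n0 = b$n0,
                 sidelobeSpan = b$sidelobe_span_um)
}

acquisitionFromConfig <- function(config) {
  a <- config$acquisition
  AcquisitionParams(scanPeriod = a$scan_period_us, fovY = a$fov_um,
                    sampleRate = a$sample_rate,
                    slitHeight = a$slit_height_um,
                    magnification = a$magnification,
                    ledSlitSeparation = a$led_slit_separation_um,
                    noiseSigma = a$noise_sigma,
                    backgroundAmplitude = a$background_amplitude)
}

classesFromConfig <- function(config) {
  lapply(config$scene$classes, function(cl) {
    sceneClass(
      label = cl$label, kind = cl$kind, count = cl$count,
      diameter = cl$diameter_um %||% 10,
      sizeCV = cl$size_cv %||% if (cl$kind == "bead") 0.03 else 0.10,
      rimTransmission = cl$rim_transmission %||% 0.45,
      centerTransmission = cl$center_transmission %||% 1.25,
      nGranules = unlist(cl$n_granules %||% 0L),
      granuleDiameter = cl$granule_diameter_um %||% 2.5,
      granuleContrast = cl$granule_contrast %||% 0.3,
      nCells = cl$n_cells %||% 4L,
      cellWidth = cl$cell_width_um %||% 4
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Demo configurations replicating the sorting experiments in silico
#'
#' \describe{
#'   \item{beads_7_10}{1:1 mixture of 7 and 10 um beads (200 + 200,
#'     size CV 3\%), gated on the size product (T1 v)(T2 vScan) at the
#'     histogram valley; target = the 10 um class.}
#'   \item{beads_7_15}{1:1 mixture of 7 and 15 um beads (150 + 150),
#'     same gate; target = the 15 um class.}
#'   \item{leukemia}{1:50 spike of large granular cells (13 um, 10
#'     granules) into smaller smooth cells (9 um, 0-3 granules),
#'     gated jointly on L = T1 v and Nv = N v from the class-separated
#'     scatter.}
#'   \item{algae}{1:5 spike of elongated 4-cell algal colonies into
#'     small mixed micro-organisms, gated on L = T1 v.}
#' }
#'
#' @param name demo name
#' @return configuration list
#' @export
demoConfig <- function(name = c("beads_7_10", "beads_7_15", "leukemia",
                                "algae")) {
  name <- match.arg(name)
  cfg <- defaultConfig()
  if (name == "beads_7_10") {
    cfg$scene$classes <- list(
      list(label = "bead7", kind = "bead", count = 200L, diameter_um = 7),
      list(label = "bead10", kind = "bead", count = 200L, diameter_um = 10))
    cfg$gate <- list(method = "valley", axes = list("sizeProduct"),
                     target = "bead10", side = "above", bounds = NULL)
  } else if (name == "beads_7_15") {
    cfg$scene$classes <- list(
      list(label = "bead7", kind = "bead", count = 150L, diameter_um = 7),
      list(label = "bead15", kind = "bead", count = 150L, diameter_um = 15))
    cfg$gate <- list(method = "valley", axes = list("sizeProduct"),
                     target = "bead15", side = "above", bounds = NULL)
  } else if (name == "leukemia") {
    cfg$scene$classes <- list(
      list(label = "SKNO1", kind = "cell", count = 20L, diameter_um = 13,
           n_granules = 10L),
      list(label = "WBC", kind = "cell", count = 1000L, diameter_um = 9,
           n_granules = c(0L, 3L)))
    cfg$gate <- list(method = "scatter", axes = list("L", "Nv"),
                     target = "SKNO1", side = "above", bounds = NULL)
  } else {
    cfg$scene$classes <- list(
      list(label = "Scenedesmus", kind = "alga_colony", count = 50L,
           diameter_um = 10, n_cells = 4L, cell_width_um = 4),
      list(label = "other", kind = "cell", count = 250L, diameter_um = 5,
           size_cv = 0.2, n_granules = c(0L, 2L)))
    cfg$gate <- list(method = "valley", axes = list("L"),
                     target = "Scenedesmus", side = "above", bounds = NULL)
  }
  cfg
}
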