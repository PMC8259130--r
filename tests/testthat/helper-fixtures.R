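## Shared fixtures: default beam/comb/transfer matrix are built once per
## test file; single-object records are synthesized on demand.

.fx <- new.env(parent = emptyenv())

fxBeam <- function() {
  if (is.null(.fx$beam)) .fx$beam <- BeamParameters()
  .fx$beam
}

fxComb <- function() {
  if (is.null(.fx$comb)) .fx$comb <- combWeights(fxBeam())
  .fx$comb
}

fxParamsQuiet <- function() {
  if (is.null(.fx$pq)) {
    .fx$pq <- AcquisitionParams(noiseSigma = 0, backgroundAmplitude = 0)
  }
  .fx$pq
}

fxParamsNoisy <- function() {
  if (is.null(.fx$pn)) .fx$pn <- AcquisitionParams()
  .fx$pn
}

fxTM <- function() {
  if (is.null(.fx$tm)) .fx$tm <- buildTransferMatrix(fxComb(), fxParamsQuiet())
  .fx$tm
}

## Record with a single object of the given class description; speed can
## be pinned for parameterised sweeps.
singleObjectRecord <- function(class, params = fxParamsQuiet(), seed = 11L,
                               speed = NULL) {
  scene <- makeScene(list(class), params, seed = seed)
  if (!is.null(speed)) {
    ob <- sceneObjects(scene)
    ob$speed <- speed
    scene@objects <- ob
  }
  rec <- synthesizeWaveform(scene, fxComb(), params, seed = seed)
  list(scene = scene, record = subtractBackground(rec))
}

## A zero-object scene with the full column layout
emptyScene <- function() {
  ob <- data.frame(kind = character(0), label = character(0),
                   diameter = numeric(0), lengthY = numeric(0),
                   lengthZ = numeric(0), rimTransmission = numeric(0),
                   centerTransmission = numeric(0), nGranules = integer(0),
                   granuleDiameter = numeric(0), granuleContrast = numeric(0),
                   nCells = integer(0), cellLength = numeric(0),
                   cellWidth = numeric(0), speed = numeric(0),
                   lateralOffset = numeric(0), arrivalTime = numeric(0),
                   objectSeed = integer(0))
  new("ScenePlan", objects = ob, seed = 1L)
}
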