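## Forward model: temporal mapping, comb response, waveform synthesis,
## velocimetry channel.

test_that("temporal mapping sweeps the FOV per scan and advances with flow", {
  p <- fxParamsQuiet()
  expect_equal(temporalMapping(p@scanPeriod, 0, 20, p)[["y"]], 40)
  expect_equal(temporalMapping(0, 0, 20, p)[["y"]], 0)
  ## one full scan at 20 cm/s advances the object by 1 um
  z0 <- temporalMapping(0, 0, 20, p)[["z"]]
  z1 <- temporalMapping(0, 1, 20, p)[["z"]]
  expect_equal(z1 - z0, 1)
  ## the scan is far faster than any object (still-object approximation)
  expect_gte(scanSpeed(p) / (25 * 0.01), 30)
})

test_that("scan response: baseline, single-point dip, symmetry", {
  comb <- fxComb()
  p <- fxParamsQuiet()
  S <- sum(combWeightValues(comb))
  side <- 251L
  expect_equal(scanResponse(rep(1, side), comb, p), rep(S, 125),
               tolerance = 1e-12)
  ## one opaque grid point at the beam center position dips by a0^2 / S
  f <- rep(1, side)
  f[63 + 63] <- 0                      # in-FOV sample 63
  J <- scanResponse(f, comb, p) / S
  expect_equal(1 - J[63], 1 / S, tolerance = 1e-12)
  ## symmetric line -> symmetric response
  fs <- rep(1, side)
  fs[126 + (-20:20)] <- 0.6
  Js <- scanResponse(fs, comb, p)
  expect_equal(Js, rev(Js), tolerance = 1e-12)
  expect_error(scanResponse(rep(1, 200), comb, p), "padding")
})

test_that("T-matrix products reproduce the explicit shift-sum", {
  comb <- fxComb()
  p <- fxParamsQuiet()
  tm <- fxTM()
  set.seed(421)
  for (i in 1:50) {
    f <- runif(251, 0.4, 1.3)
    expect_equal((tmValues(tm) %*% f)[63 + 1:125],
                 scanResponse(f, comb, p), tolerance = 1e-12)
  }
})

test_that("an empty scene yields a flat unit baseline with noise off", {
  rec <- synthesizeWaveform(emptyScene(), fxComb(), fxParamsQuiet(), seed = 1)
  expect_true(all(waveTransmission(rec) == 1))
  expect_true(all(waveSpeedChannel(rec) == 1))
  expect_equal(nrow(waveTruth(rec)), 0L)
})

test_that("a bead's envelope spans (diameter + slit) / speed", {
  fx <- singleObjectRecord(sceneClass("b", "bead", 1, diameter = 15,
                                      sizeCV = 0), speed = 20)
  m <- scanMatrix(fx$record)
  mins <- apply(m, 2, min)
  dipping <- which(mins < 1 - 0.02)
  span <- (max(dipping) - min(dipping) + 1) * 5   # us
  expect_equal(span, (15 + 1.5) / 0.2, tolerance = 0.15)
})

test_that("waveform synthesis is deterministic and rejects overlaps", {
  cl <- list(sceneClass("b", "bead", 3, diameter = 10))
  scene <- makeScene(cl, fxParamsNoisy(), seed = 9)
  r1 <- synthesizeWaveform(scene, fxComb(), fxParamsNoisy(), seed = 9)
  r2 <- synthesizeWaveform(scene, fxComb(), fxParamsNoisy(), seed = 9)
  expect_identical(waveTransmission(r1), waveTransmission(r2))
  expect_identical(waveSpeedChannel(r1), waveSpeedChannel(r2))
  ## force two objects onto the same scans
  ob <- sceneObjects(scene)
  ob$arrivalTime[2] <- ob$arrivalTime[1] + 1
  scene@objects <- ob
  expect_error(synthesizeWaveform(scene, fxComb(), fxParamsNoisy(), seed = 9),
               "overlap")
})

test_that("velocimetry dips sit one slit separation apart in time", {
  p <- fxParamsQuiet()
  sepObj <- p@ledSlitSeparation / p@magnification
  for (v in c(10, 20)) {
    fx <- singleObjectRecord(sceneClass("b", "bead", 1, diameter = 10,
                                        sizeCV = 0), speed = v)
    x <- waveSpeedChannel(fx$record)
    rateUs <- p@sampleRate * 1e-6
    below <- which(x < 0.8)
    runs <- split(below, cumsum(c(1, diff(below) != 1)))
    expect_length(runs, 2L)
    mins <- vapply(runs, function(r) r[which.min(x[r])], numeric(1))
    dt <- diff(mins) / rateUs
    expect_equal(unname(dt), sepObj / (v * 0.01), tolerance = 0.01)
  }
  ## no objects -> flat channel
  expect_true(all(synthesizeSpeedChannel(emptyScene(), p, 1, 1000) == 1))
})
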