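## Transfer matrix, background subtraction, event detection, inversion
## and image assembly.

test_that("default transfer matrix: side 251, symmetric, dominant, well conditioned", {
  tm <- fxTM()
  v <- tmValues(tm)
  expect_equal(dim(v), c(251L, 251L))
  expect_true(all(diag(v) == 1))
  expect_equal(v, t(v), tolerance = 1e-15)
  ## strict diagonal dominance at the default beam
  offSums <- rowSums(v) - 1
  expect_true(all(offSums < 1))
  expect_false(tm@regularized)
  expect_lt(tmConditionNumber(tm), 100)
})

test_that("a central-lobe-only comb gives the identity matrix", {
  comb <- new("BesselComb", positions = 0, coefficients = 1, weights = 1,
              kr = fxBeam()@kr)
  tm <- buildTransferMatrix(comb, fxParamsQuiet())
  expect_identical(tmValues(tm), diag(251))
})

test_that("fixed per-scan ripple is removed; clean records pass through", {
  p <- AcquisitionParams(noiseSigma = 0, backgroundAmplitude = 0.05)
  rec <- synthesizeWaveform(emptyScene(), fxComb(), p, seed = 2)
  expect_gt(max(abs(waveTransmission(rec) - 1)), 0.02)  # ripple present
  sub <- subtractBackground(rec)
  expect_lt(max(abs(waveTransmission(sub) - 1)), 1e-10)
  ## ripple-free noise-free record is unchanged
  clean <- synthesizeWaveform(emptyScene(), fxComb(), fxParamsQuiet(), seed = 2)
  sub2 <- subtractBackground(clean)
  expect_lt(max(abs(waveTransmission(sub2) - waveTransmission(clean))), 1e-12)
})

test_that("background estimation excludes object scans and needs clean scans", {
  ## with an object present, the pattern is estimated from clean scans
  ## only, so the object's dip survives subtraction undiluted
  p <- AcquisitionParams(noiseSigma = 0, backgroundAmplitude = 0.04)
  fx0 <- singleObjectRecord(sceneClass("b", "bead", 1, diameter = 10,
                                       sizeCV = 0),
                            params = fxParamsQuiet(), speed = 20)
  fx1 <- singleObjectRecord(sceneClass("b", "bead", 1, diameter = 10,
                                       sizeCV = 0), params = p, speed = 20)
  expect_equal(min(waveTransmission(fx1$record)),
               min(waveTransmission(fx0$record)), tolerance = 0.01)
})

test_that("event detection finds isolated objects and respects thresholds", {
  fx <- singleObjectRecord(sceneClass("b", "bead", 2, diameter = 10,
                                      sizeCV = 0))
  ev <- detectEvents(fx$record)
  expect_equal(nrow(ev), 2L)
  tr <- waveTruth(fx$record)
  for (i in 1:2) {
    expect_lte(ev$firstScan[i], tr$firstScan[i])
    expect_gte(ev$lastScan[i], tr$lastScan[i])
  }
  ## a threshold above the deepest dip finds nothing
  expect_equal(nrow(detectEvents(fx$record, threshold = 0.9)), 0L)
  empty <- synthesizeWaveform(emptyScene(), fxComb(), fxParamsQuiet(), 1)
  expect_equal(nrow(detectEvents(empty)), 0L)
})

test_that("inversion restores baseline and round-trips arbitrary phantoms", {
  tm <- fxTM()
  comb <- fxComb()
  p <- fxParamsQuiet()
  S <- sum(combWeightValues(comb))
  expect_equal(invertScan(tm, rep(1, 125)), rep(1, 125), tolerance = 1e-9)
  set.seed(99)
  for (i in 1:20) {
    fext <- rep(1, 251)
    fext[63 + 1:125] <- runif(125, 0.5, 1.3)
    J <- scanResponse(fext, comb, p) / S
    expect_lt(max(abs(invertScan(tm, J) - fext[63 + 1:125])), 1e-9)
  }
})

test_that("noise is not pathologically amplified by the inversion", {
  tm <- fxTM()
  comb <- fxComb()
  p <- fxParamsQuiet()
  S <- sum(combWeightValues(comb))
  fext <- rep(1, 251)
  fext[63 + 30:90] <- 0.7
  J <- scanResponse(fext, comb, p) / S
  set.seed(4)
  sigma <- 0.01
  err <- replicate(100, {
    f <- invertScan(tm, J + rnorm(125, 0, sigma))
    sqrt(mean((f - fext[63 + 1:125])^2))
  })
  expect_lt(mean(err), 3 * sigma)
})

test_that("reconstruction is affine-linear in the scan samples", {
  tm <- fxTM()
  comb <- fxComb()
  p <- fxParamsQuiet()
  S <- sum(combWeightValues(comb))
  f1 <- rep(1, 251); f1[100:120] <- 0.6
  f2 <- rep(1, 251); f2[140:160] <- 1.2
  J1 <- scanResponse(f1, comb, p) / S
  J2 <- scanResponse(f2, comb, p) / S
  lhs <- invertScan(tm, J1 + J2 - 1)
  rhs <- invertScan(tm, J1) + invertScan(tm, J2) - 1
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("symmetric phantoms reconstruct symmetrically", {
  tm <- fxTM()
  comb <- fxComb()
  p <- fxParamsQuiet()
  S <- sum(combWeightValues(comb))
  fext <- rep(1, 251)
  fext[126 + (-25:25)] <- 0.5 + 0.3 * cos(seq(-1, 1, length.out = 51))
  J <- scanResponse(fext, comb, p) / S
  f <- invertScan(tm, J)
  expect_lt(max(abs(f - rev(f))), 1e-9)
})

test_that("2D images recover object extent and the bright center", {
  fx <- singleObjectRecord(sceneClass("b", "bead", 1, diameter = 15,
                                      sizeCV = 0), speed = 20)
  ev <- detectEvents(fx$record)
  img <- reconstructImage(fx$record, ev[1, ], speed = 20, tm = fxTM())
  v <- imageValues(img)
  ## scan-axis extent of the dark region at the widest line
  widest <- which.min(apply(v, 1, min))
  dark <- which(v[widest, ] < 0.9)
  expect_equal(diff(range(dark)) * img@pitchY, 15, tolerance = 1)
  ## flow-axis extent: rows whose minimum is dark; includes slit smear
  darkRows <- which(apply(v, 1, min) < 0.9)
  expect_equal(diff(range(darkRows)) * img@pitchZ, 15, tolerance = 2.5)
  ## restored bright forward-scattering spot exceeds the baseline
  expect_gt(max(v), 1)
  ## a mis-specified speed scales the z pitch proportionally
  img2 <- reconstructImage(fx$record, ev[1, ], speed = 40, tm = fxTM())
  expect_equal(img2@pitchZ, 2 * img@pitchZ)
  expect_error(reconstructImage(fx$record, ev[1, ], speed = NULL,
                                tm = fxTM()), "speed")
})
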