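## Waveform features and sort scoring.

test_that("two-slit velocimetry recovers speed to sub-sample precision", {
  p <- fxParamsQuiet()
  sepObj <- p@ledSlitSeparation / p@magnification
  for (v in c(10, 15, 20, 25)) {
    fx <- singleObjectRecord(sceneClass("b", "bead", 1, diameter = 10,
                                        sizeCV = 0), speed = v)
    ev <- detectEvents(fx$record)
    vhat <- estimateSpeed(fx$record, ev)
    ## one sample period over the dip separation, in relative terms
    dt <- sepObj / (v * 0.01)
    tol <- (1 / (p@sampleRate * 1e-6)) / dt
    expect_lt(abs(vhat - v) / v, tol)
  }
})

test_that("events without two dips are flagged instead of guessed", {
  fx <- singleObjectRecord(sceneClass("b", "bead", 1, diameter = 10,
                                      sizeCV = 0), speed = 20)
  rec <- fx$record
  rec@speedChannel <- rep(1, length(rec@speedChannel))
  ev <- detectEvents(rec)
  expect_true(is.na(estimateSpeed(rec, ev)))
  ft <- extractFeatures(rec, ev, fxTM())
  expect_identical(ft$flag, "noSpeed")
})

test_that("transit time tracks object length and inverse speed", {
  ## T1 ~ (diameter + slit) / v; halving the speed doubles it
  f20 <- singleObjectRecord(sceneClass("b", "bead", 1, diameter = 15,
                                       sizeCV = 0), speed = 20)
  f10 <- singleObjectRecord(sceneClass("b", "bead", 1, diameter = 15,
                                       sizeCV = 0), speed = 10)
  t20 <- extractFeatures(f20$record, detectEvents(f20$record), fxTM(),
                         speeds = 20)$T1
  t10 <- extractFeatures(f10$record, detectEvents(f10$record), fxTM(),
                         speeds = 10)$T1
  expect_equal(t20, (15 + 1.5) / 0.2, tolerance = 5 / 82.5)
  expect_equal(t10 / t20, 2, tolerance = 0.05)
  ## an empty window yields no qualifying peak
  quiet <- matrix(1, 125, 8)
  expect_true(is.na(computeT1(quiet, 1L, fxParamsQuiet())$T1))
})

test_that("size recovery holds across the diameter x speed grid", {
  p <- fxParamsQuiet()
  pitch <- scanPitch(p)
  for (D in c(7, 10, 15)) {
    Ws <- c()
    for (v in c(10, 20, 25)) {
      fx <- singleObjectRecord(sceneClass("b", "bead", 1, diameter = D,
                                          sizeCV = 0), speed = v)
      ft <- extractFeatures(fx$record, detectEvents(fx$record), fxTM(),
                            speeds = v)
      expect_lte(abs(ft$L - (D + p@slitHeight)), v * 0.01 * p@scanPeriod)
      expect_lte(abs(ft$W - D), 2 * pitch)
      Ws <- c(Ws, ft$W)
    }
  }
  ## width monotone in diameter at fixed speed
  W <- vapply(c(7, 10, 15), function(D) {
    fx <- singleObjectRecord(sceneClass("b", "bead", 1, diameter = D,
                                        sizeCV = 0), speed = 20)
    extractFeatures(fx$record, detectEvents(fx$record), fxTM(),
                    speeds = 20)$W
  }, numeric(1))
  expect_true(all(diff(W) > 0))
})

test_that("speed-corrected length is invariant to the flow speed", {
  Ls <- vapply(c(10, 15, 20, 25), function(v) {
    fx <- singleObjectRecord(sceneClass("b", "bead", 1, diameter = 10,
                                        sizeCV = 0), speed = v)
    extractFeatures(fx$record, detectEvents(fx$record), fxTM(),
                    speeds = v)$L
  }, numeric(1))
  expect_lt(diff(range(Ls)) / mean(Ls), 0.03)
})

test_that("positive peaks count bright structure, not smooth darkness", {
  ## a bead without a bright spot has no positive peaks
  fx0 <- singleObjectRecord(sceneClass("b", "bead", 1, diameter = 10,
                                       sizeCV = 0, centerTransmission = 1),
                            speed = 20)
  ft0 <- extractFeatures(fx0$record, detectEvents(fx0$record), fxTM(),
                         speeds = 20)
  expect_equal(ft0$nPosPeaks, 0L)
  ## the default bead's forward-scattering spot shows up (slow flow so
  ## scans sample the small spot densely along z)
  fx1 <- singleObjectRecord(sceneClass("b", "bead", 1, diameter = 15,
                                       sizeCV = 0), speed = 10)
  ft1 <- extractFeatures(fx1$record, detectEvents(fx1$record), fxTM(),
                         speeds = 10)
  expect_gte(ft1$nPosPeaks, 1L)
})

test_that("peak counts rise with granule number across seeded cells", {
  p <- fxParamsQuiet()
  ng <- rep(c(0L, 2L, 4L, 6L, 8L, 10L), each = 5)
  classes <- lapply(seq_along(ng), function(i) {
    sceneClass(sprintf("g%02d_%d", ng[i], i), "cell", 1, diameter = 12,
               sizeCV = 0, nGranules = ng[i])
  })
  scene <- makeScene(classes, p, seed = 31)
  rec <- subtractBackground(synthesizeWaveform(scene, fxComb(), p, seed = 31))
  ev <- detectEvents(rec)
  ft <- extractFeatures(rec, ev, fxTM())
  ftn <- as.integer(sub("^g(\\d+)_.*", "\\1", ft$truthLabel))
  rho <- cor(ftn, ft$Nv, method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("dropping the speed correction inflates within-class spread", {
  cl <- list(sceneClass("b", "bead", 12, diameter = 10, sizeCV = 0))
  scene <- makeScene(cl, fxParamsQuiet(), seed = 17)
  rec <- subtractBackground(synthesizeWaveform(scene, fxComb(),
                                               fxParamsQuiet(), seed = 17))
  ev <- detectEvents(rec)
  ft <- extractFeatures(rec, ev, fxTM())
  cvT1 <- sd(ft$T1) / mean(ft$T1)
  cvL <- sd(ft$L) / mean(ft$L)
  expect_gt(cvT1 / cvL, 1)
})

test_that("feature extraction is deterministic", {
  fx <- singleObjectRecord(sceneClass("b", "bead", 2, diameter = 10),
                           params = fxParamsNoisy(), seed = 23)
  ev <- detectEvents(fx$record)
  f1 <- extractFeatures(fx$record, ev, fxTM())
  f2 <- extractFeatures(fx$record, ev, fxTM())
  expect_identical(f1, f2)
})

test_that("gate scoring reproduces the purity identities", {
  mk <- function(nT, nF, tIn, fIn) {
    data.frame(x = c(rep(2, tIn), rep(0, nT - tIn),
                     rep(2, fIn), rep(0, nF - fIn)),
               flag = "ok",
               truthLabel = c(rep("t", nT), rep("b", nF)))
  }
  gate <- new("GateSpec", axes = list(x = c(1, Inf)), target = "t")
  ## printed counts of the leukemia sort: 124 of 128 sorted cells
  r1 <- applyGateAndScore(mk(150, 300, 124, 4), gate)
  expect_equal(round(sortPurity(r1)), 97)
  expect_equal(sortCounts(r1)[["sortedTarget"]], 124L)
  ## printed counts of the algae sort: 248 of 253
  r2 <- applyGateAndScore(mk(260, 1300, 248, 5), gate)
  expect_equal(round(sortPurity(r2)), 98)
  ## identities on an arbitrary table
  r3 <- applyGateAndScore(mk(50, 200, 40, 10), gate)
  expect_equal(sortPurity(r3), 100 * 40 / 50)
  expect_equal(sortYield(r3), 100 * 40 / 50)
  expect_equal(sortEnrichment(r3), (40 / 10) / (50 / 200))
  expect_equal(sum(sortCounts(r3)), 250L)
})

test_that("an all-pass gate returns the mixture proportion", {
  ft <- data.frame(x = rnorm(300), flag = "ok",
                   truthLabel = rep(c("t", "b"), c(60, 240)))
  gate <- new("GateSpec", axes = list(x = c(-Inf, Inf)), target = "t")
  expect_equal(sortPurity(applyGateAndScore(ft, gate)), 20)
})

test_that("gating is idempotent, order-independent and validates axes", {
  ft <- data.frame(sizeProduct = c(rep(60, 50), rep(250, 50)),
                   flag = "ok",
                   truthLabel = rep(c("s", "l"), each = 50))
  gate <- gateFromValley(ft, "sizeProduct", "l")
  m1 <- gateMembership(ft, gate)
  expect_identical(m1, gateMembership(ft, gate))
  perm <- sample(nrow(ft))
  r <- applyGateAndScore(ft, gate)
  rp <- applyGateAndScore(ft[perm, ], gate)
  expect_identical(sortCounts(r), sortCounts(rp))
  expect_equal(sortPurity(r), 100)
  bad <- new("GateSpec", axes = list(nope = c(0, 1)), target = "l")
  expect_error(applyGateAndScore(ft, bad), "available")
  expect_error(new("GateSpec", axes = list(x = c(2, 1)), target = "l"),
               "lo < hi")
})

test_that("scatter-derived gates sit between the labeled populations", {
  ft <- data.frame(L = c(rnorm(500, 10, 1), rnorm(20, 14.5, 1)),
                   Nv = c(rnorm(500, 30, 15), rnorm(20, 140, 12)),
                   flag = "ok",
                   truthLabel = rep(c("b", "t"), c(500, 20)))
  gate <- gateFromScatter(ft, c("L", "Nv"), "t")
  expect_gt(gate@axes$L[1], 10)
  expect_lt(gate@axes$L[1], 14.5)
  expect_gt(gate@axes$Nv[1], 60)
  expect_lt(gate@axes$Nv[1], 140)
})

test_that("purity from printed counts matches the reported percentages", {
  expect_equal(round(purityFromCounts(124, 128)), 97)
  expect_equal(round(purityFromCounts(248, 253)), 98)
  expect_error(purityFromCounts(5, 0))
})
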