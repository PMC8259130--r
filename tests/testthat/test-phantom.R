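## Synthetic phantoms and scene plans.

test_that("index-to-transmission map matches the closed form", {
  expect_identical(transmissionFromIndex(0, 1.33), 1)
  ## polystyrene bead (n = 1.6) in water: 4*1.33*1.60 / 2.93^2
  expect_equal(transmissionFromIndex(0.27, 1.33), 0.9915, tolerance = 1e-4)
  ## monotone decreasing and bounded in (0, 1]
  dn <- seq(0, 1, by = 0.01)
  f <- transmissionFromIndex(dn, 1.33)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0 & f <= 1))
  expect_gt(transmissionFromIndex(0.1), transmissionFromIndex(0.2))
  expect_error(transmissionFromIndex(-0.1), "non-negative")
})

test_that("bead phantoms have finite support, dark rim and bright spot", {
  for (D in c(7, 10, 15)) {
    map <- makeBead(D)
    v <- mapValues(map)
    n <- nrow(v)
    ax <- (seq_len(n) - (n + 1) / 2) * mapPitch(map)["y"]
    r <- sqrt(outer(ax^2, ax^2, "+"))
    ## support confined to the disk (anti-aliased boundary pixels aside)
    expect_true(all(v[r > D / 2 + mapPitch(map)["y"]] == 1))
    expect_lt(min(v), 1)
    expect_gt(max(v), 1)
    ## bright spot at the center, dark rim near the boundary
    expect_gt(v[(n + 1) / 2, (n + 1) / 2], 1)
  }
})

test_that("matched-level bead is invisible; integrated deficit grows with size", {
  flat <- makeBead(10, rimTransmission = 1, centerTransmission = 1)
  expect_true(all(mapValues(flat) == 1))
  deficit <- vapply(c(7, 10, 15), function(D) {
    sum(1 - mapValues(makeBead(D)))
  }, numeric(1))
  expect_true(all(diff(deficit) > 0))
  expect_error(makeBead(7, pitch = 2), "pitch")
})

## strict interior local extrema of a 2D map
countExtrema2D <- function(v) {
  n <- 0L
  for (i in 2:(nrow(v) - 1)) for (j in 2:(ncol(v) - 1)) {
    nb <- c(v[i - 1, j], v[i + 1, j], v[i, j - 1], v[i, j + 1])
    if (all(v[i, j] > nb) || all(v[i, j] < nb)) n <- n + 1L
  }
  n
}

test_that("cell phantoms are seeded, smooth without granules, bumpy with", {
  smooth <- makeCell(12, nGranules = 0L, seed = 5)
  expect_true(all(mapValues(smooth) <= 1))
  a <- makeCell(12, nGranules = 6L, seed = 5)
  b <- makeCell(12, nGranules = 6L, seed = 5)
  c6 <- makeCell(12, nGranules = 6L, seed = 6)
  expect_identical(mapValues(a), mapValues(b))
  expect_false(identical(mapValues(a), mapValues(c6)))
  ## each granule contributes at least one interior extremum
  expect_gte(countExtrema2D(mapValues(a)), 6L)
  ## bright and dark granules both present (half/half split)
  expect_gt(max(mapValues(a)), 1)
  expect_lt(min(mapValues(a)), min(mapValues(smooth)))
  expect_error(makeCell(3, nGranules = 2L, granuleDiameter = 2.5),
               "fit inside")
})

test_that("algal colonies are elongated along the flow axis", {
  one <- makeAlgaColony(1, cellLength = 10, cellWidth = 4)
  v1 <- mapValues(one)
  supp <- which(v1 < 1, arr.ind = TRUE)
  yExt <- diff(range(supp[, 1])) * mapPitch(one)["y"]
  zExt <- diff(range(supp[, 2])) * mapPitch(one)["z"]
  expect_equal(unname(yExt), 10, tolerance = 0.15)
  expect_equal(unname(zExt), 4, tolerance = 0.15)
  four <- makeAlgaColony(4, cellLength = 10, cellWidth = 4)
  v4 <- mapValues(four)
  supp4 <- which(v4 < 1, arr.ind = TRUE)
  zExt4 <- diff(range(supp4[, 2])) * mapPitch(four)["z"]
  yExt4 <- diff(range(supp4[, 1])) * mapPitch(four)["y"]
  expect_gt(zExt4 / yExt4, 1.5)
  ## footprint length ~ nCells * cellWidth, well beyond a small organism
  expect_equal(unname(zExt4), 16, tolerance = 0.3)
  expect_gt(zExt4, 5)
  expect_error(makeAlgaColony(3), "one of")
})

test_that("scene plans honor counts, ranges and determinism", {
  classes <- list(
    sceneClass("a", "bead", 20, diameter = 7),
    sceneClass("b", "bead", 20, diameter = 10))
  s1 <- makeScene(classes, fxParamsQuiet(), seed = 42)
  s2 <- makeScene(classes, fxParamsQuiet(), seed = 42)
  expect_identical(sceneObjects(s1), sceneObjects(s2))
  ob <- sceneObjects(s1)
  expect_equal(nrow(ob), 40L)
  expect_equal(as.integer(table(ob$label)[c("a", "b")]), c(20L, 20L))
  expect_true(all(diff(ob$arrivalTime) > 0))
  expect_true(all(ob$speed >= 10 & ob$speed <= 25))
  ## 1:50 spike arithmetic
  spike <- list(sceneClass("t", "cell", 20, diameter = 13),
                sceneClass("bg", "cell", 20 * 50, diameter = 9))
  expect_equal(nrow(sceneObjects(makeScene(spike, fxParamsQuiet(), 1))),
               1020L)
})

test_that("every phantom map keeps background exactly 1 and f in [0, 1.3]", {
  maps <- list(makeBead(7), makeCell(9, 3L, seed = 2), makeAlgaColony(2))
  for (m in maps) {
    v <- mapValues(m)
    expect_identical(max(v[1, ]), 1)    # border rows are background
    expect_true(all(v >= 0 & v <= 1.3 + 1e-12))
  }
})
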