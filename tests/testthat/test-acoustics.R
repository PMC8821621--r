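# Echo integration, dB-difference classification, kernel densities and
# layer detection.

test_that("binning averages in the linear domain", {
  rec <- data.frame(time = c(0.01, 0.02, 0.03, 0.04),
                    depth = c(10.2, 10.7, 10.4, 10.6),
                    sv = c(-70, -70, -60, -70))
  g <- binSv(rec, frequency = 38, depthRange = c(0, 20))
  # cell (depth 10-11, first time bin): mean of -70,-70,-60,-70 in linear
  oracle <- 10 * log10(mean(10^(c(-70, -70, -60, -70) / 10)))
  expect_equal(svMatrix(g)[11, 1], oracle, tolerance = 1e-9)
  # two equal samples stay put
  g2 <- binSv(data.frame(time = c(0.01, 0.02), depth = c(5.1, 5.2),
                         sv = c(-70, -70)), depthRange = c(0, 20))
  expect_equal(svMatrix(g2)[6, 1], -70)
  # worked two-sample case
  g3 <- binSv(data.frame(time = c(0.01, 0.02), depth = c(5.1, 5.2),
                         sv = c(-60, -70)), depthRange = c(0, 20))
  expect_equal(svMatrix(g3)[6, 1], 10 * log10((1e-6 + 1e-7) / 2),
               tolerance = 1e-9)
  expect_equal(svMatrix(g3)[6, 1], -62.60, tolerance = 1e-3)
})

test_that("linear-domain binning dominates dB-domain averaging (Jensen)", {
  set.seed(31)
  for (i in 1:20) {
    sv <- rnorm(5, -70, 6)
    g <- binSv(data.frame(time = rep(0.01, 5), depth = rep(3.5, 5), sv = sv),
               depthRange = c(0, 10))
    expect_gte(svMatrix(g)[4, 1], mean(sv) - 1e-12)
  }
  # equality iff samples equal
  g <- binSv(data.frame(time = rep(0.01, 3), depth = rep(3.5, 3),
                        sv = rep(-65, 3)), depthRange = c(0, 10))
  expect_equal(svMatrix(g)[4, 1], -65)
})

test_that("out-of-range records are dropped with a message", {
  expect_message(
    g <- binSv(data.frame(time = 0.01, depth = c(5, 900), sv = c(-70, -70)),
               depthRange = c(0, 800)),
    "dropped 1")
})

test_that("24-h composites fold days in the linear domain", {
  rec <- data.frame(time = c(0.05, 24.05), depth = c(5.5, 5.5),
                    sv = c(-60, -70))
  g <- binSv(rec, depthRange = c(0, 10), timeRange = c(0, 48))
  comp <- composite24h(g)
  expect_equal(svMatrix(comp)[6, 1], 10 * log10((1e-6 + 1e-7) / 2),
               tolerance = 1e-9)
  expect_equal(length(timeBins(comp)), 240L)
  # single-day identity
  g1 <- binSv(data.frame(time = 0.05, depth = 5.5, sv = -60),
              depthRange = c(0, 10), timeRange = c(0, 24))
  expect_equal(svMatrix(composite24h(g1)), svMatrix(g1))
  # invariance under day-order permutation
  recA <- data.frame(time = c(1.05, 25.05), depth = c(5.5, 5.5),
                     sv = c(-60, -70))
  recB <- data.frame(time = c(1.05, 25.05), depth = c(5.5, 5.5),
                     sv = c(-70, -60))
  cA <- composite24h(binSv(recA, depthRange = c(0, 10), timeRange = c(0, 48)))
  cB <- composite24h(binSv(recB, depthRange = c(0, 10), timeRange = c(0, 48)))
  expect_equal(svMatrix(cA), svMatrix(cB))
})

test_that("deltaSv subtracts aligned grids and rejects mismatches", {
  eg <- generateEchogram(oneLayerPreset(), seed = 1)
  d <- deltaSv(eg$sv18, eg$sv38)
  fin <- is.finite(svMatrix(eg$sv38))    # zero-noise grids are -Inf off-layer
  expect_equal(svMatrix(d)[fin],
               (svMatrix(eg$sv18) - svMatrix(eg$sv38))[fin])
  expect_true(all(abs(svMatrix(d)[fin] - 7) < 1e-9))
  d0 <- deltaSv(eg$sv38, eg$sv38)
  expect_true(all(svMatrix(d0)[fin] == 0))
  g2 <- eg$sv38
  g2@depth <- g2@depth + 1
  expect_error(deltaSv(eg$sv18, g2), "depth")
})

test_that("cell classification equals a brute-force per-cell oracle", {
  set.seed(17)
  nD <- 100; nT <- 100
  dv <- matrix(runif(nD * nT, -20, 20), nD, nT)
  gv <- matrix(runif(nD * nT, -95, -60), nD, nT)
  mk <- function(m, q, f) new("Echogram", sv = m, frequency = f,
                              quantity = q, time = (seq_len(nT) - 0.5) * 0.1,
                              depth = seq_len(nD) - 0.5, timeBin = 6,
                              depthBin = 1, timeOfDay = TRUE)
  tree <- defaultClassificationTree()
  got <- classifyCells(mk(dv, "deltaSv", NA_real_), mk(gv, "Sv", 38), tree)
  oracle <- matrix(NA_character_, nD, nT)
  for (i in seq_len(nD)) for (j in seq_len(nT)) {
    if (gv[i, j] < tree$gate) next
    x <- dv[i, j]
    oracle[i, j] <-
      if (x > -14 && x <= -3) "Sm.(N)SB/Crust."
      else if (x > -3 && x <= 0) "Lrg.NSB"
      else if (x > 0 && x <= 3) "FL"
      else if (x > 3 && x <= 12) "Lrg.SB"
      else NA_character_
  }
  expect_identical(got@classes, oracle)
  # idempotence / determinism
  expect_identical(
    classifyCells(mk(dv, "deltaSv", NA_real_), mk(gv, "Sv", 38))@classes,
    got@classes)
  # boundary convention: upper ends closed
  expect_identical(oracle[which(dv == 3)], got@classes[which(dv == 3)])
})

test_that("named example cells classify to the printed groups", {
  mk1 <- function(x, g) {
    e <- function(v, q, f) new("Echogram", sv = matrix(v), frequency = f,
                               quantity = q, time = 0.05, depth = 0.5,
                               timeBin = 6, depthBin = 1, timeOfDay = TRUE)
    classifyCells(e(x, "deltaSv", NA_real_), e(g, "Sv", 38))@classes[1, 1]
  }
  expect_identical(mk1(5, -70), "Lrg.SB")
  expect_identical(mk1(-10, -70), "Sm.(N)SB/Crust.")
  expect_identical(mk1(20, -70), NA_character_)     # outside all intervals
  expect_identical(mk1(5, -88), NA_character_)      # below the Sv gate
})

test_that("class density maps are max-normalized and wrap at midnight", {
  cells <- data.frame(class = "FL", time = c(23.95, 0.15),
                      depth = c(300, 300))
  cg <- makeClassGrid(cells)
  dm <- classKde(cg, bandwidth = c(time = 1, depth = 30))
  m <- densityMaps(dm)[["FL"]]
  expect_equal(max(m), 1)
  i <- which.min(abs(depthBins(dm) - 300))
  at0 <- m[i, which.min(abs(timeBins(dm) - 0.25))]
  at12 <- m[i, which.min(abs(timeBins(dm) - 12))]
  expect_gt(at0, at12 * 10)
})

test_that("a single occupied cell gives a monotonically decaying kernel", {
  cg <- makeClassGrid(data.frame(class = "Lrg.SB", time = 12, depth = 400))
  dm <- classKde(cg, bandwidth = c(time = 2, depth = 50))
  m <- densityMaps(dm)[["Lrg.SB"]]
  i <- which.min(abs(depthBins(dm) - 400))
  j <- which.min(abs(timeBins(dm) - 12))
  expect_equal(m[i, j], 1)
  expect_true(all(diff(m[i:(i + 10), j]) < 0))      # decay with depth
  expect_true(all(diff(m[i, j:(j + 10)]) < 0))      # decay with time
})

test_that("density argmax is invariant under a uniform dB offset", {
  eg <- generateEchogram(buildPreset("rockall"), seed = 2)
  shift <- function(g, off) { g@sv <- g@sv + off; g }
  mk <- function(off) {
    cg <- classifyCells(deltaSv(shift(eg$sv18, off), shift(eg$sv38, off)),
                        shift(eg$sv38, off))
    densityMaps(classKde(cg))
  }
  m0 <- mk(0); m5 <- mk(5)
  for (cl in names(m0))
    expect_identical(which.max(m0[[cl]]), which.max(m5[[cl]]))
})

test_that("FL density tracks the fluid-like layer at midday", {
  eg <- generateEchogram(buildPreset("rockall"), seed = 7)
  cg <- classifyCells(deltaSv(eg$sv18, eg$sv38), eg$sv38)
  dm <- classKde(cg)
  fl <- densityMaps(dm)[["FL"]]
  j <- which.min(abs(timeBins(dm) - 12))
  expect_lt(abs(depthBins(dm)[which.max(fl[, j])] - 200), 25)
})

test_that("a single stationary noise-free layer is recovered exactly", {
  eg <- generateEchogram(oneLayerPreset(sdThickness = 20), seed = 1)
  ls <- detectLayers(eg$sv38, eg$sunTimes)
  lt <- layerTable(ls)
  expect_equal(nrow(lt), 1L)
  expect_identical(lt$label, "stationary")
  expect_lt(abs(lt$dayCenter - 450), 2)
  expect_lt(abs(lt$nightCenter - 450), 2)
  # thickness recovered within half a generated sd
  expect_lt(abs(median(ls@tracks$thickness) - 20), 10)
})

test_that("rockall layers are labelled and located like the generator", {
  eg <- generateEchogram(buildPreset("rockall"), seed = 7)
  ls <- detectLayers(eg$sv38, eg$sunTimes)
  lt <- layerTable(ls)
  mig <- lt[lt$label == "migrating" & !is.na(lt$dayCenter) &
              !is.na(lt$nightCenter), ]
  expect_gte(nrow(mig), 1L)
  expect_true(all(mig$dayCenter > mig$nightCenter))
  tk <- ls@tracks
  sh <- mig$id[which.min((mig$dayCenter + mig$nightCenter) / 2)]
  midday <- mean(tk$center[tk$id == sh & tk$time >= 11 & tk$time <= 13])
  midnight <- mean(tk$center[tk$id == sh & (tk$time >= 23 | tk$time <= 1)])
  expect_lt(abs(midday - 200), 20)
  expect_lt(abs(midnight - 50), 20)
})

test_that("an empty grid warns and returns an empty layer set", {
  g <- new("Echogram", sv = matrix(-90, 100, 240), frequency = 38,
           quantity = "Sv", time = (1:240 - 0.5) * 0.1,
           depth = (1:100) - 0.5, timeBin = 6, depthBin = 1,
           timeOfDay = TRUE)
  expect_warning(ls <- detectLayers(g, c(6, 18)), "no peaks")
  expect_equal(nrow(layerTable(ls)), 0L)
})

test_that("echograms round-trip through the long-CSV format", {
  eg <- generateEchogram(buildPreset("azores"), seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  writeEchograms(list(sv18_db = eg$sv18, sv38_db = eg$sv38), f)
  r <- readEchograms(f)
  expect_equal(svMatrix(r$sv18_db), svMatrix(eg$sv18), tolerance = 1e-6)
  expect_equal(r$sv38_db@frequency, 38)
  expect_equal(depthBins(r$sv38_db), depthBins(eg$sv38))
})
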