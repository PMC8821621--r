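# Synthetic generators: tracks, tag series, echograms.

test_that("presets are populated and unknown names rejected", {
  expect_error(buildPreset("nope"), "paper_oceanic")
  r <- buildPreset("rockall")
  expect_equal(nrow(r@layers), 3L)
  expect_equal(sum(!r@layers$migrating), 1L)
  sec <- r@layers[r@layers$migrating & r@layers$dayCenter == 200, ]
  expect_equal(sec$nightCenter, 50)
  cst <- buildPreset("coastal")
  expect_identical(cst@regimes[[1]]$dayMixture,
                   cst@regimes[[1]]$nightMixture)
  az <- buildPreset("azores")
  expect_equal(nrow(az@layers), 2L)
})

test_that("track bathymetry follows the regime partition", {
  p <- buildPreset("paper_oceanic")
  p@regimes <- list(modifyList(p@regimes[[1]],
                               list(kind = "coastal", endFrac = 0.5,
                                    maxDepth = 100)),
                    modifyList(p@regimes[[1]], list(startFrac = 0.5)))
  tr <- generateTrack(p, 10, seed = 4)
  day <- floor(as.numeric(tr$timestamp - tr$timestamp[1], units = "days"))
  expect_true(all(tr$seabed[day == 1] < 100))
  expect_true(all(tr$seabed[day == 8] >= 1000))
  expect_true(all(tr$seabed > 0))
  # determinism
  expect_identical(tr, generateTrack(p, 10, seed = 4))
  # all-oceanic
  tr2 <- generateTrack(buildPreset("paper_oceanic"), 1, seed = 1)
  expect_true(all(tr2$seabed >= 1000))
})

test_that("zero-variance mixtures with no transition give exact plateaus", {
  day <- data.frame(weight = 1, mean = 500, sd = 1e-12)
  night <- data.frame(weight = 1, mean = 100, sd = 1e-12)
  p <- makeRegimePreset(day, night)
  tr <- makeFlatTrack(2, seabed = 2000)
  cal <- makeDielCalendar(tr)
  s <- labelDiel(generateTagSeries(p, tr, cal, seed = 1), cal)
  d <- tagData(s)
  expect_true(all(d$depth[d$diel == "day"] == 500))
  expect_true(all(d$depth[d$diel == "night"] == 100))
})

test_that("tag series are reproducible and respect the duty cycle", {
  p <- buildPreset("paper_oceanic")
  p@dutyCycle <- c(2, 1, 0)
  tr <- makeFlatTrack(9, seabed = 2000)
  cal <- makeDielCalendar(tr)
  s1 <- generateTagSeries(p, tr, cal, seed = 8)
  s2 <- generateTagSeries(p, tr, cal, seed = 8)
  expect_identical(tagData(s1), tagData(s2))
  d <- tagData(s1)
  day <- floor(as.numeric(d$timestamp - d$timestamp[1], units = "days"))
  onDays <- tapply(!d$gap, day, any)
  expect_equal(sum(onDays), 6L)             # 2 on / 1 off over 9 days
  expect_equal(sum(!onDays), 3L)
  # gap rows carry no depth
  expect_true(all(is.na(d$depth[d$gap])))
})

test_that("generated depths never exceed the seabed", {
  p <- buildPreset("coastal")
  tr <- generateTrack(p, 3, seed = 9)
  cal <- makeDielCalendar(tr)
  d <- tagData(generateTagSeries(p, tr, cal, seed = 9))
  seabed <- approx(as.numeric(tr$timestamp), tr$seabed,
                   xout = as.numeric(d$timestamp), rule = 2)$y
  expect_true(all(d$depth[!d$gap] <= seabed[!d$gap] + 1e-9))
  expect_true(all(d$depth[!d$gap] >= 0))
})

test_that("noise-free echogram reproduces layer deltaSv at the peak", {
  p <- oneLayerPreset(deltaSv = -8, class = "Sm.(N)SB/Crust.",
                      sv38Peak = -64)
  eg <- generateEchogram(p, seed = 1)
  i <- which.min(abs(depthBins(eg$sv38) - 450))
  dlt <- svMatrix(eg$sv18)[i, 17] - svMatrix(eg$sv38)[i, 17]
  expect_lt(abs(dlt - (-8)), 0.1)
})

test_that("column linear energy equals the analytic Gaussian integrals", {
  p <- oneLayerPreset()
  p@layers <- rbind(
    p@layers[0, ],
    data.frame(class = "Lrg.SB", deltaSv = 7, sv38Peak = -64,
               dayCenter = 200, nightCenter = 200, sdThickness = 15,
               migrating = FALSE),
    data.frame(class = "FL", deltaSv = 1.5, sv38Peak = -66,
               dayCenter = 600, nightCenter = 600, sdThickness = 25,
               migrating = FALSE))
  eg <- generateEchogram(p, seed = 1)
  colSum <- sum(10^(svMatrix(eg$sv38)[, 100] / 10))   # 1-m bins
  oracle <- 10^(-64 / 10) * 15 * sqrt(2 * pi) +
    10^(-66 / 10) * 25 * sqrt(2 * pi)
  expect_equal(colSum, oracle, tolerance = 0.01)
})

test_that("rockall midnight column shows the secondary layer near 50 m", {
  eg <- generateEchogram(buildPreset("rockall"), seed = 7)
  j <- which.min(abs(timeBins(eg$sv38) - 0.05))
  shallow <- depthBins(eg$sv38) < 120
  pk <- depthBins(eg$sv38)[shallow][which.max(svMatrix(eg$sv38)[shallow, j])]
  expect_lt(abs(pk - 50), 15)
})

test_that("echogram generation is deterministic and needs layers", {
  p <- buildPreset("rockall")
  e1 <- generateEchogram(p, seed = 3)
  e2 <- generateEchogram(p, seed = 3)
  expect_identical(svMatrix(e1$sv18), svMatrix(e2$sv18))
  p@layers <- p@layers[0, ]
  expect_error(generateEchogram(p, seed = 1), "no echo layers")
})

test_that("label-period marginals track the calibrated mixtures", {
  # property: TAD of generator-truth series reproduces analytic interval
  # masses of the mixtures within Monte-Carlo error
  # ~13 effectively independent draws per night under the 60-min AR
  # e-folding, so the Monte-Carlo standard error over 40 nights is ~0.02;
  # allow 3 SE plus the small crepuscular-ramp smearing
  p <- buildPreset("paper_oceanic")
  tr <- makeFlatTrack(40, seabed = 2000)
  cal <- makeDielCalendar(tr)
  s <- segmentPhases(labelDiel(generateTagSeries(p, tr, cal, seed = 5), cal),
                     tr)
  tad <- tadHistogram(s)
  st <- mixtureStats(p@regimes[[1]]$nightMixture)
  expect_lt(abs(tadFraction(tad, "oceanic", "night", 0, 150) -
                  st$prob(0, 150)), 0.08)
})
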