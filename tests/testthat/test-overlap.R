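# Overlap index between depth curves and class density maps.

uniformMap <- function() {
  tg <- seq(0.25, 23.75, by = 0.5)
  dg <- seq(5, 795, by = 10)
  new("ClassDensityMap",
      maps = list(U = matrix(1, length(dg), length(tg))),
      time = tg, depth = dg, bandwidth = c(time = 1, depth = 10),
      weighted = TRUE)
}

ridgeMap <- function(depth = 300) {
  tg <- seq(0.25, 23.75, by = 0.5)
  dg <- seq(5, 795, by = 10)
  m <- matrix(0, length(dg), length(tg))
  m[which.min(abs(dg - depth)), ] <- 1
  new("ClassDensityMap", maps = list(R = m), time = tg, depth = dg,
      bandwidth = c(time = 1, depth = 10), weighted = TRUE)
}

test_that("a curve on a flat ridge scores 1 and any depth shift scores less", {
  mp <- ridgeMap(305)                             # exact grid row
  on <- data.frame(hour = 0:24, depth = 305)      # the ridge row center
  off <- data.frame(hour = 0:24, depth = 355)
  rOn <- overlapIndex(on, mp, nPerm = 50, seed = 1)
  rOff <- overlapIndex(off, mp, nPerm = 50, seed = 1)
  expect_equal(rOn$index, 1)
  expect_lt(rOff$index, rOn$index)
})

test_that("a uniform map gives identical scores to every curve", {
  mp <- uniformMap()
  r <- overlapIndex(data.frame(hour = 0:24, depth = 400), mp,
                    nPerm = 100, seed = 2)
  expect_equal(r$index, 1)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)              # every permutation ties the observation
})

test_that("p-values are seeded-reproducible and properly bounded", {
  eg <- generateEchogram(buildPreset("azores"), seed = 3)
  dm <- classKde(classifyCells(deltaSv(eg$sv18, eg$sv38), eg$sv38))
  cv <- data.frame(hour = 0:24,
                   depth = 325 + 175 * cos(2 * pi * (0:24 - 13) / 24))
  r1 <- overlapIndex(cv, dm, nPerm = 99, seed = 9)
  r2 <- overlapIndex(cv, dm, nPerm = 99, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1$p >= 1 / 100 & r1$p <= 1))
})

test_that("the index is invariant under a joint cyclic shift", {
  eg <- generateEchogram(buildPreset("rockall"), seed = 5)
  dm <- classKde(classifyCells(deltaSv(eg$sv18, eg$sv38), eg$sv38))
  cv <- data.frame(hour = 0:24,
                   depth = 300 + 150 * cos(2 * pi * (0:24 - 13) / 24))
  r0 <- overlapIndex(cv, dm, nPerm = 10, seed = 1)
  shift <- 6
  dmS <- dm
  dmS@maps <- lapply(dm@maps, function(m) {
    k <- shift * 2                        # columns per 6 h at 0.5-h bins
    cbind(m[, (ncol(m) - k + 1):ncol(m)], m[, 1:(ncol(m) - k)])
  })
  cvS <- data.frame(hour = 0:24, depth = approx(
    c(cv$hour - 24, cv$hour, cv$hour + 24), rep(cv$depth, 3),
    xout = (0:24 - shift) %% 24, ties = "ordered")$y)
  cvS$depth[25] <- cvS$depth[1]
  rS <- overlapIndex(cvS, dmS, nPerm = 10, seed = 1)
  expect_equal(sort(rS$index), sort(r0$index), tolerance = 1e-6)
})

test_that("curves leaving the depth range are clipped with a warning", {
  mp <- ridgeMap(300)
  expect_warning(r <- overlapIndex(data.frame(hour = 0:24, depth = 900),
                                   mp, nPerm = 20, seed = 1), "clipped")
  expect_true(is.finite(r$index))
})

test_that("ranking is deterministic with documented tie-breaks", {
  r <- data.frame(class = c("B", "A", "C"), index = c(0.2, 0.9, 0.2),
                  z = c(1, 5, 1))
  expect_identical(rankClasses(r), c("A", "B", "C"))
  r2 <- data.frame(class = c("B", "A"), index = c(0.5, 0.5), z = c(2, 1))
  expect_identical(rankClasses(r2), c("B", "A"))
})

test_that("a curve tracking one layer ranks that layer's class first", {
  eg <- generateEchogram(buildPreset("rockall"), seed = 11)
  dm <- classKde(classifyCells(deltaSv(eg$sv18, eg$sv38), eg$sv38))
  ramp <- function(x, w = 2) {
    y <- pmin(1, pmax(0, x / w + 0.5)); (1 - cos(pi * y)) / 2
  }
  hrs <- 0:24
  a <- ramp(hrs - eg$sunTimes[1]) * (1 - ramp(hrs - eg$sunTimes[2]))
  cv <- data.frame(hour = hrs, depth = 150 + 300 * a)   # Lrg.SB trajectory
  r <- overlapIndex(cv, dm, nPerm = 199, seed = 2)
  expect_identical(rankClasses(r)[1], "Lrg.SB")
  expect_lt(r$p[r$class == "Lrg.SB"], 0.05)
})
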