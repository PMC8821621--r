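# Hourly resampling, periodicity and the cyclic depth-by-hour model.

makeCosineSeries <- function(nDays, dtMin = 6, mean = 300, amp = 150,
                             peakHour = 14, noiseSd = 0, rho = 0,
                             seed = 1) {
  set.seed(seed)
  n <- nDays * 24 * 60 / dtMin
  tms <- as.POSIXct("2019-03-01", tz = "UTC") + (seq_len(n) - 1) * dtMin * 60
  lt <- as.POSIXlt(tms, tz = "UTC")
  hr <- lt$hour + lt$min / 60
  depth <- mean + amp * cos(2 * pi * (hr - peakHour) / 24)
  if (noiseSd > 0)
    depth <- depth + as.numeric(filter(rnorm(n, 0, noiseSd * sqrt(1 - rho^2)),
                                       rho, method = "recursive"))
  makeTagSeries(pmin(pmax(depth, 0), 2000), intervalMin = dtMin)
}

test_that("hourly resampling averages in-hour samples exactly", {
  s <- makeTagSeries(rep(300, 480), intervalMin = 6)
  h <- resampleHourly(s)
  expect_true(all(h$depth == 300))
  expect_false(any(h$imputed))
  expect_equal(as.numeric(diff(h$hour), units = "hours"),
               rep(1, nrow(h) - 1))
})

test_that("a missing hour in a sinusoid is spline-imputed within 5%", {
  s <- makeCosineSeries(10)
  d <- tagData(s)
  drop <- d$timestamp >= as.POSIXct("2019-03-05 10:00", tz = "UTC") &
    d$timestamp < as.POSIXct("2019-03-05 11:00", tz = "UTC")
  d$depth[drop] <- NA; d$gap[drop] <- TRUE
  s@data <- d
  h <- resampleHourly(s)
  i <- which(h$imputed)
  expect_length(i, 1L)
  truth <- 300 + 150 * cos(2 * pi * (10.5 - 14) / 24)
  expect_lt(abs(h$depth[i] - truth) / truth, 0.05)
})

test_that("duty-cycled series impute roughly the off fraction", {
  p <- buildPreset("paper_oceanic")
  p@dutyCycle <- c(2, 1, 0)
  tr <- makeFlatTrack(9, seabed = 2000)
  s <- generateTagSeries(p, tr, makeDielCalendar(tr), seed = 3)
  h <- resampleHourly(s)
  # hourly grid runs to the last on-day, so 2 of 8 covered days are off
  expect_equal(mean(h$imputed), 0.25, tolerance = 0.02)
})

test_that("ACF finds the 24-h period of a pure sinusoid", {
  h <- data.frame(hour = seq_len(10 * 24),
                  depth = 300 + 100 * cos(2 * pi * seq_len(240) / 24))
  r <- acfPeriodicity(h, seed = 1)
  expect_equal(r$dominantPeriod, 24)
  # biased (n - k)/n estimator caps acf(24) at 0.9 for n = 240
  expect_gte(r$acf[25], 0.9 - 1e-12)
  expect_equal(r$acf[1], 1)            # lag 0
  expect_true(r$significant)
})

test_that("white noise is not significantly periodic", {
  set.seed(99)
  h <- data.frame(hour = seq_len(10 * 24), depth = rnorm(240, 300, 50))
  r <- acfPeriodicity(h, seed = 5)
  expect_false(r$significant)
})

test_that("constant series are rejected", {
  h <- data.frame(hour = seq_len(240), depth = rep(300, 240))
  expect_error(acfPeriodicity(h), "zero variance")
  expect_error(waveletPower(h), "zero variance")
})

test_that("wavelet global power peaks at the sinusoid period", {
  h <- data.frame(hour = seq_len(10 * 24),
                  depth = 300 + 100 * cos(2 * pi * seq_len(240) / 24))
  w <- waveletPower(h)
  expect_lt(abs(w$peakPeriod - 24), 2)
})

test_that("wavelet resolves two superimposed periods", {
  n <- 20 * 24
  h <- data.frame(hour = seq_len(n),
                  depth = 100 * cos(2 * pi * seq_len(n) / 24) +
                    100 * cos(2 * pi * seq_len(n) / 12))
  w <- waveletPower(h)
  gp <- w$globalPower
  loc <- which(diff(sign(diff(gp))) < 0) + 1
  pks <- w$period[loc]
  expect_true(any(abs(pks - 24) < 2))
  expect_true(any(abs(pks - 12) < 1.5))
})

test_that("wavelet power localizes a regime change in time", {
  n <- 20 * 24
  x <- c(rnorm(n / 2, 0, 1),
         100 * cos(2 * pi * seq_len(n / 2) / 24) + rnorm(n / 2, 0, 1))
  w <- waveletPower(data.frame(hour = seq_len(n), depth = x))
  j <- which.min(abs(w$period - 24))
  flat <- mean(w$power[j, 1:(n / 2 - 24)])
  dvm <- mean(w$power[j, (n / 2 + 24):n])
  expect_gt(dvm, 10 * flat)
})

test_that("ACF and wavelet agree on the dominant period of DVM series", {
  for (sd_ in 1:3) {
    s <- makeCosineSeries(10, dtMin = 60, noiseSd = 60, rho = 0.4,
                          seed = sd_)
    h <- data.frame(hour = seq_len(240), depth = tagData(s)$depth)
    a <- acfPeriodicity(h, seed = sd_)
    w <- waveletPower(h)
    expect_lt(abs(a$dominantPeriod - w$peakPeriod), 2)
  }
})

test_that("the cyclic model recovers a cosine signal with AR(1) noise", {
  s <- makeCosineSeries(5, dtMin = 12, mean = 300, amp = 150,
                        noiseSd = 40, rho = 0.5, seed = 21)
  m <- suppressMessages(fitHourlyDepthModel(s, phase = NULL))
  cv <- predictDepthCurve(m)
  truth <- 300 + 150 * cos(2 * pi * (cv$hour - 14) / 24)
  expect_lt(sqrt(mean((cv$depth - truth)^2)), 20)
  expect_lt(abs(m@rho - 0.5), 0.15)
  expect_lt(abs(cv$depth[cv$hour == 14] - 450), 20)
  expect_lt(m@pvalue, 0.01)
})

test_that("the predicted curve is periodic at the endpoints", {
  s <- makeCosineSeries(4, dtMin = 12, noiseSd = 30, rho = 0.3, seed = 2)
  m <- suppressMessages(fitHourlyDepthModel(s, phase = NULL))
  cv <- predictDepthCurve(m, hours = c(0, 12, 24))
  expect_equal(cv$depth[1], cv$depth[3], tolerance = 1e-8)
  expect_equal(cv$se[1], cv$se[3], tolerance = 1e-6)
})

test_that("phase-restricted fits demand phase labels and enough samples", {
  s <- makeCosineSeries(3, dtMin = 12)
  expect_error(fitHourlyDepthModel(s, phase = "oceanic"), "phase labels")
  expect_error(suppressMessages(
    fitHourlyDepthModel(makeTagSeries(rep(100, 50), intervalMin = 6),
                        phase = NULL)), "at least")
})

test_that("two tags get a shared curve with per-tag intercepts", {
  s1 <- makeCosineSeries(4, dtMin = 12, mean = 280, noiseSd = 30,
                         rho = 0.3, seed = 4)
  s2 <- makeCosineSeries(4, dtMin = 12, mean = 340, noiseSd = 30,
                         rho = 0.3, seed = 5)
  s2@ptt <- "T2"
  m <- fitHourlyDepthModel(list(s1, s2), phase = NULL)
  expect_identical(m@tags, c("T1", "T2"))
  cv <- predictDepthCurve(m)
  truth <- 310 + 150 * cos(2 * pi * (cv$hour - 14) / 24)
  expect_lt(sqrt(mean((cv$depth - truth)^2)), 25)
  sc <- modelScore(m)
  expect_true(all(c("r2", "df", "seMin", "seMax", "p") %in% names(sc)))
})
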