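# Fixtures built in code: tiny tag series, bare-bones presets, and small
# classification grids used across the test files.

makeTagSeries <- function(depth, startTime = as.POSIXct("2019-03-01",
                                                        tz = "UTC"),
                          intervalMin = 6, ptt = "T1", gap = NULL,
                          diel = NA_character_, phase = NA_character_) {
  n <- length(depth)
  if (is.null(gap)) gap <- is.na(depth)
  new("TagSeries", ptt = ptt,
      data = data.frame(timestamp = startTime + (seq_len(n) - 1) *
                          intervalMin * 60,
                        depth = depth, temperature = NA_real_,
                        light = NA_real_, gap = gap, diel = diel,
                        phase = phase),
      sampleInterval = intervalMin)
}

# flat-bathymetry track at a fixed position
makeFlatTrack <- function(nDays, seabed, lat = 52, lon = -15,
                          start = as.POSIXct("2019-03-01", tz = "UTC")) {
  n <- nDays * 24
  data.frame(timestamp = start + 3600 * (seq_len(n) - 1),
             lat = lat, lon = lon, seabed = seabed)
}

# single-regime preset with explicit mixtures (defaults: no layers, no noise)
makeRegimePreset <- function(dayMixture, nightMixture,
                             transitionMinutes = 0, maxDepth = 800,
                             sampleInterval = 6, dutyCycle = numeric(0),
                             arMinutes = 60, kind = "oceanic",
                             yoYo = NULL, layers = NULL,
                             noiseFloor = c(sv18 = -Inf, sv38 = -Inf)) {
  if (is.null(layers))
    layers <- data.frame(class = character(0), deltaSv = numeric(0),
                         sv38Peak = numeric(0), dayCenter = numeric(0),
                         nightCenter = numeric(0), sdThickness = numeric(0),
                         migrating = logical(0))
  new("GeneratorPreset", name = "test", regimes = list(list(
        kind = kind, startFrac = 0, endFrac = 1, dayMixture = dayMixture,
        nightMixture = nightMixture, transitionMinutes = transitionMinutes,
        maxDepth = maxDepth, yoYo = yoYo)),
      sampleInterval = sampleInterval, dutyCycle = dutyCycle,
      layers = layers, noiseFloor = noiseFloor, lat = 52, lon = -15,
      depthRange = c(0, 800), arDecorrelationMinutes = arMinutes)
}

oneLayerPreset <- function(class = "Lrg.SB", deltaSv = 7, sv38Peak = -64,
                           dayCenter = 450, nightCenter = 450,
                           sdThickness = 20, migrating = FALSE,
                           noiseFloor = c(sv18 = -Inf, sv38 = -Inf)) {
  mx <- data.frame(weight = 1, mean = 100, sd = 20)
  p <- makeRegimePreset(mx, mx, noiseFloor = noiseFloor)
  p@layers <- data.frame(class = class, deltaSv = deltaSv,
                         sv38Peak = sv38Peak, dayCenter = dayCenter,
                         nightCenter = nightCenter,
                         sdThickness = sdThickness, migrating = migrating)
  p
}

# Monte-Carlo sampler for a truncated-normal mixture, independent of the
# package's quantile-transform path (component draw + rejection)
sampleMixtureMC <- function(mixture, n, range = c(0, 800), seed = 1) {
  set.seed(seed)
  comp <- sample.int(nrow(mixture), n, replace = TRUE,
                     prob = mixture$weight)
  x <- rnorm(n, mixture$mean[comp], mixture$sd[comp])
  bad <- x < range[1] | x > range[2]
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mixture$mean[comp[bad]],
                    mixture$sd[comp[bad]])
    bad <- x < range[1] | x > range[2]
  }
  x
}

# minimal ClassGrid on the standard 6-min x 1-m rockall-like grid
makeClassGrid <- function(cells, nDepth = 800, nTime = 240,
                          weight = 1e-7) {
  tod <- (seq_len(nTime) - 0.5) * 0.1
  dep <- seq_len(nDepth) - 0.5
  cls <- matrix(NA_character_, nrow = nDepth, ncol = nTime)
  w <- matrix(weight, nrow = nDepth, ncol = nTime)
  for (i in seq_len(nrow(cells))) {
    di <- which.min(abs(dep - cells$depth[i]))
    ti <- which.min(abs(tod - cells$time[i]))
    cls[di, ti] <- cells$class[i]
    if (!is.null(cells$weight)) w[di, ti] <- cells$weight[i]
  }
  new("ClassGrid", classes = cls, weight = w, time = tod, depth = dep,
      tree = defaultClassificationTree()$tree)
}
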