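# Synthetic two-frequency echograms: Gaussian depth-profile layers on diel
# trajectories (smoothed square wave with cosine twilight ramps), summed in
# the linear domain over an exponential noise background.

# diel center trajectory: nightCenter on the night plateau, dayCenter on
# the day plateau, cosine ramps of `rampHours` centered on sunrise/sunset
.layerCenter <- function(tod, dayCenter, nightCenter, sunriseH, sunsetH,
                         rampHours = 2) {
  ramp <- function(x) {           # 0 before, 1 after, cosine in between
    y <- (x / rampHours + 0.5)
    y <- pmin(1, pmax(0, y))
    (1 - cos(pi * y)) / 2
  }
  a <- ramp(tod - sunriseH) * (1 - ramp(tod - sunsetH))
  nightCenter + (dayCenter - nightCenter) * a
}

#' Generate a synthetic two-frequency echogram pair
#'
#' Builds 24-h composite grids (default 6 min x 1 m over the preset depth
#' range) at 18 and 38 kHz. Each layer contributes a Gaussian depth profile
#' in the linear domain, centered on its diel trajectory (stationary, or
#' moving between night and day centers with cosine ramps at the preset
#' location's sunrise/sunset); the 38-kHz peak is \code{sv38Peak} dB and
#' the 18-kHz profile is offset by the layer's \code{deltaSv}. Exponential
#' background noise with mean at the preset noise floor is added per cell
#' (none when the floor is \code{-Inf}); summation is linear, output in dB.
#'
#' @param preset a \code{\link{GeneratorPreset}} with at least one layer.
#' @param seed integer RNG seed.
#' @param date reference date for sunrise/sunset at the preset location,
#'   default \code{"2019-03-25"}.
#' @param rampHours twilight ramp duration (h), default 2.
#' @return list with elements \code{sv18} and \code{sv38}
#'   (\code{\link{Echogram}}s) and \code{sunTimes} (numeric sunrise/sunset
#'   hours used).
#' @examples
#' eg <- generateEchogram(buildPreset("azores"), seed = 7)
#' eg$sv38
#' @export
generateEchogram <- function(preset, seed, date = "2019-03-25",
                             rampHours = 2) {
  stopifnot(is(preset, "GeneratorPreset"))
  if (!nrow(preset@layers)) stop("preset has no echo layers")
  tree <- defaultClassificationTree()
  for (i in seq_len(nrow(preset@layers))) {
    L <- preset@layers[i, ]
    row <- tree$tree[tree$tree$class == L$class, ]
    if (nrow(row) && !(L$deltaSv > row$lower && L$deltaSv < row$upper))
      stop("layer ", i, " deltaSv ", L$deltaSv,
           " dB is not strictly inside the ", L$class, " interval (",
           row$lower, ", ", row$upper, ")")
  }
  st <- .sunTimes(as.Date(date), preset@lat, preset@lon)
  mid <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  sunH <- as.numeric(st - mid, units = "hours")

  tb <- 6 / 60
  tod <- seq(tb / 2, 24 - tb / 2, by = tb)
  dep <- seq(preset@depthRange[1] + 0.5, preset@depthRange[2] - 0.5, by = 1)
  lin38 <- matrix(0, nrow = length(dep), ncol = length(tod))
  lin18 <- matrix(0, nrow = length(dep), ncol = length(tod))
  for (i in seq_len(nrow(preset@layers))) {
    L <- preset@layers[i, ]
    ctr <- if (L$migrating)
      .layerCenter(tod, L$dayCenter, L$nightCenter, sunH[1], sunH[2],
                   rampHours)
    else rep(L$dayCenter, length(tod))
    prof <- exp(-outer(dep, ctr, function(d, c) (d - c)^2) /
                  (2 * L$sdThickness^2))
    lin38 <- lin38 + .toLinear(L$sv38Peak) * prof
    lin18 <- lin18 + .toLinear(L$sv38Peak + L$deltaSv) * prof
  }
  .withSeed(seed, {
    nf <- preset@noiseFloor
    ncell <- length(lin38)
    if (is.finite(nf[["sv38"]]))
      lin38 <- lin38 + matrix(rexp(ncell, 1 / .toLinear(nf[["sv38"]])),
                              nrow = nrow(lin38))
    if (is.finite(nf[["sv18"]]))
      lin18 <- lin18 + matrix(rexp(ncell, 1 / .toLinear(nf[["sv18"]])),
                              nrow = nrow(lin18))
  })
  mk <- function(lin, fq) new("Echogram", sv = .toDb(lin), frequency = fq,
                              quantity = "Sv", time = tod, depth = dep,
                              timeBin = 6, depthBin = 1, timeOfDay = TRUE)
  list(sv18 = mk(lin18, 18), sv38 = mk(lin38, 38), sunTimes = sunH)
}
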