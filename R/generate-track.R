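# Parametric track/bathymetry generator: a stand-in for state-space
# geolocation output (hourly positions with seabed depth along the path).

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a synthetic track with bathymetry
#'
#' Hourly positions at (or slowly drifting from) the preset location, with
#' a piecewise seabed profile: a shallow shelf (20-100 m) under coastal
#' regimes, a monotone slope crossing at each coastal-to-oceanic regime
#' boundary, and deep oceanic water (>= 1000 m) under oceanic regimes.
#'
#' @param preset a \code{\link{GeneratorPreset}} (its regime fractions set
#'   where the shelf break falls).
#' @param nDays integer >= 1, track duration in days.
#' @param seed integer, RNG seed; identical inputs give identical tracks.
#' @param start POSIXct, first timestamp (default 2019-03-01 00:00 UTC).
#' @return data.frame with columns \code{timestamp} (POSIXct UTC, hourly),
#'   \code{lat}, \code{lon} (degrees), \code{seabed} (m, positive down).
#' @examples
#' tr <- generateTrack(buildPreset("paper_oceanic"), nDays = 2, seed = 1)
#' range(tr$seabed)
#' @export
generateTrack <- function(preset, nDays, seed,
                          start = as.POSIXct("2019-03-01 00:00:00",
                                             tz = "UTC")) {
  stopifnot(is(preset, "GeneratorPreset"), nDays >= 1)
  .withSeed(seed, {
    n <- as.integer(nDays * 24)
    ts <- start + 3600 * (seq_len(n) - 1L)
    frac <- (seq_len(n) - 0.5) / n
    kinds <- vapply(preset@regimes, `[[`, "", "kind")
    fr <- t(vapply(preset@regimes,
                   function(r) c(r$startFrac, r$endFrac), numeric(2)))
    reg <- kinds[pmin(findInterval(frac, fr[, 1]), length(kinds))]
    # smooth shelf wobble + deep plateau, blended over the regime boundary
    shelf <- 60 + 30 * sin(2 * pi * frac * 3) + cumsum(rnorm(n, 0, 1))
    shelf <- pmin(pmax(shelf, 25), 95)
    deep <- 1500 + 400 * sin(2 * pi * frac * 2) + cumsum(rnorm(n, 0, 5))
    deep <- pmax(deep, 1000)
    seabed <- ifelse(reg == "coastal", shelf, deep)
    # monotone ramp across each coastal->oceanic boundary (half-day wide)
    bnd <- which(reg[-1] != reg[-n])
    for (b in bnd) {
      w <- max(1L, as.integer(12))            # 12 h transition
      i0 <- max(1L, b - w %/% 2); i1 <- min(n, b + w %/% 2)
      seabed[i0:i1] <- seq(seabed[i0], seabed[i1], length.out = i1 - i0 + 1)
    }
    drift <- 0.05 * (seq_len(n) - 1) / 24     # slow westward drift, deg/day
    data.frame(timestamp = ts,
               lat = preset@lat + cumsum(rnorm(n, 0, 0.002)),
               lon = preset@lon - drift + cumsum(rnorm(n, 0, 0.002)),
               seabed = seabed)
  })
}
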