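# Synthetic PSAT depth series. Depths are produced by a Gaussian-copula
# AR(1) process mapped through the active diel period's truncated-mixture
# quantile function; crepuscular transitions blend the day and night
# quantile functions linearly over the regime's transition window. Each
# plateau sample is therefore marginally distributed exactly as the
# calibrated mixture, while consecutive samples stay autocorrelated.

# blend weight toward the day distribution: 0 = night plateau, 1 = day
# plateau, linear ramps of `transMin` minutes centered on sunrise/sunset
.dayWeight <- function(time, sunrise, sunset, transMin) {
  h <- as.numeric(time)
  up <- (h - as.numeric(sunrise)) / 60    # minutes since sunrise
  dn <- (h - as.numeric(sunset)) / 60     # minutes since sunset
  if (transMin <= 0) return(as.numeric(up >= 0 & dn < 0))
  ramp <- function(x) pmin(1, pmax(0, x / transMin + 0.5))
  ramp(up) * (1 - ramp(dn))
}

#' Generate a synthetic tag depth series
#'
#' Samples depth every \code{preset@sampleInterval} minutes over the track
#' span. Within each diel period the depth is drawn from the active
#' regime's day or night mixture via a first-order autocorrelated Gaussian
#' copula (e-folding time \code{preset@arDecorrelationMinutes}); linear
#' crepuscular ramps of the regime's \code{transitionMinutes} blend the two
#' quantile functions around sunrise and sunset. Coastal regimes add
#' sinusoidal yo-yo bouts. Depths are clipped to
#' [0, min(regime maxDepth, seabed)]. Duty-cycle off days are emitted as
#' gap rows (depth \code{NA}).
#'
#' Temperature is a deterministic thermocline profile plus noise; light is
#' surface irradiance from solar elevation attenuated exponentially with
#' depth (coefficient 0.1 per m).
#'
#' @param preset a \code{\link{GeneratorPreset}}.
#' @param track a track data.frame from \code{\link{generateTrack}}.
#' @param calendar a \code{\link{DielCalendar}} covering the track span.
#' @param seed integer RNG seed.
#' @param ptt tag identifier for the series (default derived from the seed).
#' @param light logical, emit the light channel (default FALSE).
#' @return a \code{\link{TagSeries}}.
#' @examples
#' p <- buildPreset("coastal")
#' tr <- generateTrack(p, nDays = 2, seed = 3)
#' s <- generateTagSeries(p, tr, makeDielCalendar(tr), seed = 3)
#' summary(tagData(s)$depth)
#' @export
generateTagSeries <- function(preset, track, calendar, seed,
                              ptt = paste0("SYN", seed), light = FALSE) {
  stopifnot(is(preset, "GeneratorPreset"), is.data.frame(track),
            is(calendar, "DielCalendar"))
  ct <- calendar@table
  t0 <- track$timestamp[1]
  t1 <- track$timestamp[nrow(track)]
  dt <- preset@sampleInterval * 60
  ts <- seq(t0, t1, by = dt)
  dates <- as.Date(ts, tz = "UTC")
  ci <- match(dates, ct$date)
  if (anyNA(ci))
    stop("calendar does not cover the track span (missing ",
         paste(unique(format(dates[is.na(ci)])), collapse = ", "), ")")

  .withSeed(seed, {
    n <- length(ts)
    phi <- exp(-preset@sampleInterval / preset@arDecorrelationMinutes)
    u <- numeric(n)
    u[1] <- rnorm(1)
    innov <- rnorm(n - 1, 0, sqrt(1 - phi^2))
    for (i in seq_len(n - 1)) u[i + 1] <- phi * u[i] + innov[i]
    p <- pnorm(u)

    frac <- (as.numeric(ts) - as.numeric(t0)) /
      max(as.numeric(t1) - as.numeric(t0), 1)
    kinds <- vapply(preset@regimes, `[[`, "", "kind")
    fr <- vapply(preset@regimes, `[[`, numeric(1), "startFrac")
    regIdx <- pmin(findInterval(frac, fr), length(kinds))

    depth <- numeric(n)
    for (ri in unique(regIdx)) {
      r <- preset@regimes[[ri]]
      sel <- regIdx == ri
      rng <- c(0, r$maxDepth)
      Qd <- .mixtureQuantileFun(r$dayMixture, rng)
      Qn <- .mixtureQuantileFun(r$nightMixture, rng)
      a <- .dayWeight(ts[sel], ct$sunrise[ci[sel]], ct$sunset[ci[sel]],
                      r$transitionMinutes)
      depth[sel] <- (1 - a) * Qn(p[sel]) + a * Qd(p[sel])
      if (!is.null(r$yoYo)) {
        # sinusoidal yo-yo bouts: exponentially distributed on/off spells
        hrs <- as.numeric(ts[sel] - t0, units = "hours")
        spell <- rexp(ceiling(2 * max(hrs) / 3) + 4, rate = 1 / 1.5)
        edges <- cumsum(spell)
        on <- (findInterval(hrs, edges) %% 2) == 0
        yo <- r$yoYo$amplitude *
          sin(2 * pi * hrs * 60 / r$yoYo$period + runif(1, 0, 2 * pi))
        depth[sel] <- depth[sel] + ifelse(on, yo, 0)
      }
      depth[sel] <- pmin(pmax(depth[sel], 0), r$maxDepth)
    }
    seabed <- approx(as.numeric(track$timestamp), track$seabed,
                     xout = as.numeric(ts), rule = 2)$y
    depth <- pmin(depth, seabed)

    gap <- rep(FALSE, n)
    if (length(preset@dutyCycle) == 3L) {
      day <- floor(as.numeric(ts - t0, units = "days"))
      dc <- preset@dutyCycle
      rel <- day - dc[3]
      gap <- rel >= 0 & (rel %% (dc[1] + dc[2])) >= dc[1]
    }
    depth[gap] <- NA_real_

    temp <- 18 - 12 * (1 - exp(-ifelse(gap, 0, depth) / 150)) +
      rnorm(n, 0, 0.2)
    temp[gap] <- NA_real_
    lightv <- rep(NA_real_, n)
    if (light) {
      elev <- solarElevation(ts, preset@lat, preset@lon)
      surf <- pmax(sin(pmax(elev, 0) * pi / 180), 1e-6)
      lightv <- log(surf) - 0.1 * depth
      lightv[gap] <- NA_real_
    }
    new("TagSeries", ptt = ptt,
        data = data.frame(timestamp = ts, depth = depth, temperature = temp,
                          light = lightv, gap = gap,
                          diel = NA_character_, phase = NA_character_),
        sampleInterval = preset@sampleInterval)
  })
}
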