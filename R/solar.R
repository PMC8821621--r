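# Solar geometry: NOAA-style low-precision algorithm, adequate to ~1-2 min
# for sunrise/sunset at the study's mid-latitudes.

# fractional year (radians) at a given UTC instant
.fracYear <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  2 * pi / 365 * (lt$yday + (lt$hour + lt$min / 60 + lt$sec / 3600 - 12) / 24)
}

# equation of time (minutes) and solar declination (radians)
.eqTime <- function(g)
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
              0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))

.declination <- function(g)
  0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) - 0.006758 * cos(2 * g) +
    0.000907 * sin(2 * g) - 0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)

#' Solar elevation angle
#'
#' Elevation of the sun (degrees above the horizon) at given UTC instants
#' and a fixed position. Used for diel labelling fall-backs and the
#' synthetic light channel.
#'
#' @param time POSIXct (UTC).
#' @param lat,lon position in degrees (north/east positive).
#' @return numeric vector of elevations (degrees).
#' @examples
#' solarElevation(as.POSIXct("2019-03-20 12:00", tz = "UTC"), 0, 0)
#' @export
solarElevation <- function(time, lat, lon) {
  g <- .fracYear(time)
  decl <- .declination(g)
  lt <- as.POSIXlt(time, tz = "UTC")
  tst <- (lt$hour * 60 + lt$min + lt$sec / 60 + .eqTime(g) + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * pi / 180
  latr <- lat * pi / 180
  cosz <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  90 - acos(pmin(1, pmax(-1, cosz))) * 180 / pi
}

# geometric sunrise/sunset (solar elevation 0 deg) for one UTC date;
# returns POSIXct c(sunrise, sunset); errors on polar day/night
.sunTimes <- function(date, lat, lon) {
  noonGuess <- as.POSIXct(paste(format(date), "12:00:00"), tz = "UTC")
  g <- .fracYear(noonGuess)
  decl <- .declination(g)
  latr <- lat * pi / 180
  cosha <- -tan(latr) * tan(decl)
  if (cosha > 1 || cosha < -1)
    stop("polar day or night at lat ", lat, " on ", format(date),
         ": no geometric sunrise/sunset")
  haDeg <- acos(cosha) * 180 / pi
  sunrise <- 720 - 4 * (lon + haDeg) - .eqTime(g)
  sunset <- 720 - 4 * (lon - haDeg) - .eqTime(g)
  midnight <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  midnight + 60 * c(sunrise, sunset)
}

#' Build a diel calendar from a track
#'
#' Computes geometric sunrise and sunset (solar elevation crossing 0
#' degrees) for every UTC date covered by the track, at the date's
#' representative position (the daily median latitude and longitude).
#'
#' @param track data.frame with columns \code{timestamp} (POSIXct UTC),
#'   \code{lat}, \code{lon} (degrees) and optionally \code{seabed} (m);
#'   see \code{\link{generateTrack}}.
#' @param pad integer, extra days appended before and after the track span
#'   (at the edge dates' positions) so tag samples just outside the track
#'   are still coverable. Default 1.
#' @return a \code{\link{DielCalendar}}.
#' @examples
#' tr <- generateTrack(buildPreset("paper_oceanic"), nDays = 3, seed = 1)
#' makeDielCalendar(tr)
#' @export
makeDielCalendar <- function(track, pad = 1L) {
  stopifnot(is.data.frame(track), nrow(track) >= 1,
            all(c("timestamp", "lat", "lon") %in% names(track)))
  dates <- as.Date(track$timestamp, tz = "UTC")
  uq <- sort(unique(dates))
  pos <- do.call(rbind, lapply(uq, function(d) {
    i <- dates == d
    data.frame(date = d, lat = median(track$lat[i]),
               lon = median(track$lon[i]))
  }))
  if (pad > 0) {
    before <- pos[rep(1L, pad), , drop = FALSE]
    before$date <- min(uq) - seq_len(pad)
    after <- pos[rep(nrow(pos), pad), , drop = FALSE]
    after$date <- max(uq) + seq_len(pad)
    pos <- rbind(before, pos, after)
    pos <- pos[order(pos$date), , drop = FALSE]
  }
  st <- t(mapply(function(d, la, lo) as.numeric(.sunTimes(as.Date(d), la, lo)),
                 pos$date, pos$lat, pos$lon))
  tab <- data.frame(date = pos$date,
                    sunrise = as.POSIXct(st[, 1], origin = "1970-01-01",
                                         tz = "UTC"),
                    sunset = as.POSIXct(st[, 2], origin = "1970-01-01",
                                        tz = "UTC"),
                    lat = pos$lat, lon = pos$lon, row.names = NULL)
  new("DielCalendar", table = tab)
}

#' Label tag samples day or night
#'
#' A sample is \code{"day"} when sunrise <= t < sunset on the sample's UTC
#' date, else \code{"night"} (half-open convention: the sunrise instant is
#' day, the sunset instant night).
#'
#' @param series a \code{\link{TagSeries}}.
#' @param calendar a \code{\link{DielCalendar}} covering every date in the
#'   series (error otherwise).
#' @return the series with its \code{diel} column filled.
#' @export
labelDiel <- function(series, calendar) {
  stopifnot(is(series, "TagSeries"), is(calendar, "DielCalendar"))
  d <- series@data
  ct <- calendar@table
  dates <- as.Date(d$timestamp, tz = "UTC")
  i <- match(dates, ct$date)
  if (anyNA(i))
    stop("calendar does not cover date(s): ",
         paste(unique(format(dates[is.na(i)])), collapse = ", "))
  d$diel <- ifelse(d$timestamp >= ct$sunrise[i] & d$timestamp < ct$sunset[i],
                   "day", "night")
  series@data <- d
  series
}
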