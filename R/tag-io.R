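# Tag CSV dialect: columns Ptt, DateTimeUTC (ISO-8601), Depth_m, Temp_C,
# Light (optional); '#' starts a comment; gap rows have an empty Depth_m.

#' Read and write tag depth series
#'
#' \code{readTagSeries} parses the documented tag CSV dialect into a
#' \code{\link{TagSeries}}; \code{writeTagSeries} writes one back so that
#' \code{write(read(f))} round-trips every field. Rows whose depth does not
#' parse become gap rows. If more than half of the parsed depths exceed
#' 2000, the column is assumed to be in decimeters (a common tag-export
#' dialect) and rescaled to m; set \code{unit} to override.
#'
#' @param path file path.
#' @param sampleInterval nominal sampling interval (minutes); if \code{NA}
#'   (default) it is inferred from the median timestamp step.
#' @param unit \code{"auto"} (default), \code{"m"} or \code{"dm"}.
#' @return \code{readTagSeries}: a \code{\link{TagSeries}};
#'   \code{writeTagSeries}: \code{path}, invisibly.
#' @examples
#' p <- buildPreset("coastal")
#' tr <- generateTrack(p, 1, seed = 2)
#' s <- generateTagSeries(p, tr, makeDielCalendar(tr), seed = 2)
#' f <- tempfile(fileext = ".csv")
#' writeTagSeries(s, f)
#' identical(tagData(readTagSeries(f))$depth, tagData(s)$depth)
#' @export
readTagSeries <- function(path, sampleInterval = NA, unit = "auto") {
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("Ptt", "DateTimeUTC", "Depth_m")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(raw$DateTimeUTC, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(ts))
    stop("unparseable DateTimeUTC at row ", which(is.na(ts))[1])
  if (is.unsorted(as.numeric(ts), strictly = TRUE))
    stop("timestamps not increasing: first offending row ",
         which(diff(as.numeric(ts)) <= 0)[1] + 1L)
  depth <- suppressWarnings(as.numeric(raw$Depth_m))
  gap <- is.na(depth)
  if (identical(unit, "auto")) {
    parsed <- depth[!gap]
    if (length(parsed) && mean(parsed > 2000) > 0.5) unit <- "dm" else unit <- "m"
  }
  if (identical(unit, "dm")) depth <- depth / 10
  temp <- if ("Temp_C" %in% names(raw))
    suppressWarnings(as.numeric(raw$Temp_C)) else rep(NA_real_, nrow(raw))
  lightv <- if ("Light" %in% names(raw))
    suppressWarnings(as.numeric(raw$Light)) else rep(NA_real_, nrow(raw))
  if (is.na(sampleInterval)) {
    sampleInterval <- if (nrow(raw) > 1)
      median(diff(as.numeric(ts))) / 60 else 6
  }
  new("TagSeries", ptt = raw$Ptt[1],
      data = data.frame(timestamp = ts, depth = depth, temperature = temp,
                        light = lightv, gap = gap, diel = NA_character_,
                        phase = NA_character_),
      sampleInterval = sampleInterval)
}

#' @param series a \code{\link{TagSeries}}.
#' @rdname readTagSeries
#' @export
writeTagSeries <- function(series, path) {
  stopifnot(is(series, "TagSeries"))
  d <- series@data
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 15,
                                                 scientific = FALSE))
  out <- data.frame(Ptt = series@ptt,
                    DateTimeUTC = format(d$timestamp, "%Y-%m-%dT%H:%M:%S",
                                         tz = "UTC"),
                    Depth_m = fmt(d$depth), Temp_C = fmt(d$temperature),
                    Light = fmt(d$light))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write a track table
#'
#' Plain CSV with columns \code{timestamp} (ISO-8601 UTC), \code{lat},
#' \code{lon}, \code{seabed}.
#'
#' @param track a track data.frame (see \code{\link{generateTrack}}).
#' @param path file path.
#' @return \code{readTrack}: the track data.frame; \code{writeTrack}:
#'   \code{path}, invisibly.
#' @export
readTrack <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  t$timestamp <- as.POSIXct(t$timestamp, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                           "%Y-%m-%d %H:%M:%OS"))
  t
}

#' @rdname readTrack
#' @export
writeTrack <- function(track, path) {
  out <- track
  out$timestamp <- format(track$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
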