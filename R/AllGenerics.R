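#' Accessors for mesotrack classes
#'
#' \code{tagData} returns the sample table of a \code{\link{TagSeries}};
#' \code{ptt} its tag identifier; \code{svMatrix} the dB matrix of an
#' \code{\link{Echogram}}; \code{timeBins} and \code{depthBins} the bin
#' centers of a gridded object; \code{calendarTable} the sunrise/sunset
#' table of a \code{\link{DielCalendar}}; \code{layerTable} the per-layer
#' summary of a \code{\link{LayerSet}}; \code{densityMaps} the per-class
#' matrices of a \code{\link{ClassDensityMap}}.
#'
#' @param x the object.
#' @return See the individual descriptions above.
#' @examples
#' cal <- makeDielCalendar(generateTrack(buildPreset("paper_oceanic"), 2, seed = 1))
#' head(calendarTable(cal))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tagData", function(x) standardGeneric("tagData"))
#' @rdname accessors
#' @export
setGeneric("ptt", function(x) standardGeneric("ptt"))
#' @rdname accessors
#' @export
setGeneric("svMatrix", function(x) standardGeneric("svMatrix"))
#' @rdname accessors
#' @export
setGeneric("timeBins", function(x) standardGeneric("timeBins"))
#' @rdname accessors
#' @export
setGeneric("depthBins", function(x) standardGeneric("depthBins"))
#' @rdname accessors
#' @export
setGeneric("calendarTable", function(x) standardGeneric("calendarTable"))
#' @rdname accessors
#' @export
setGeneric("layerTable", function(x) standardGeneric("layerTable"))
#' @rdname accessors
#' @export
setGeneric("densityMaps", function(x) standardGeneric("densityMaps"))

#' @rdname accessors
setMethod("tagData", "TagSeries", function(x) x@data)
#' @rdname accessors
setMethod("ptt", "TagSeries", function(x) x@ptt)
#' @rdname accessors
setMethod("svMatrix", "Echogram", function(x) x@sv)
#' @rdname accessors
setMethod("timeBins", "Echogram", function(x) x@time)
#' @rdname accessors
setMethod("depthBins", "Echogram", function(x) x@depth)
#' @rdname accessors
setMethod("timeBins", "ClassGrid", function(x) x@time)
#' @rdname accessors
setMethod("depthBins", "ClassGrid", function(x) x@depth)
#' @rdname accessors
setMethod("timeBins", "ClassDensityMap", function(x) x@time)
#' @rdname accessors
setMethod("depthBins", "ClassDensityMap", function(x) x@depth)
#' @rdname accessors
setMethod("calendarTable", "DielCalendar", function(x) x@table)
#' @rdname accessors
setMethod("layerTable", "LayerSet", function(x) x@layers)
#' @rdname accessors
setMethod("densityMaps", "ClassDensityMap", function(x) x@maps)

setMethod("show", "TagSeries", function(object) {
  d <- object@data
  n <- nrow(d); ngap <- sum(d$gap)
  cat("TagSeries: ptt", object@ptt, "\n")
  cat("  ", n, " samples at ", object@sampleInterval, " min (",
      ngap, " gap rows)\n", sep = "")
  if (n) cat("  span:", format(d$timestamp[1], "%Y-%m-%d %H:%M", tz = "UTC"),
             "to", format(d$timestamp[n], "%Y-%m-%d %H:%M", tz = "UTC"),
             "UTC\n")
  if (any(!d$gap))
    cat("  depth: ", round(min(d$depth[!d$gap]), 1), "-",
        round(max(d$depth[!d$gap]), 1), " m\n", sep = "")
  lab <- c(diel = !all(is.na(d$diel)), phase = !all(is.na(d$phase)))
  cat("  labelled:", if (any(lab)) paste(names(lab)[lab], collapse = ", ")
      else "none", "\n")
})

setMethod("show", "DielCalendar", function(object) {
  t <- object@table
  cat("DielCalendar:", nrow(t), "dates\n")
  if (nrow(t))
    cat("  ", format(min(t$date)), "to", format(max(t$date)),
        " (lat ", round(mean(t$lat), 2), ", lon ",
        round(mean(t$lon), 2), ")\n", sep = "")
})

setMethod("show", "Echogram", function(object) {
  cat("Echogram [", object@quantity, "]",
      if (!is.na(object@frequency)) paste0(" @ ", object@frequency, " kHz"),
      "\n", sep = "")
  cat("  ", length(object@depth), " depth bins x ", length(object@time),
      " time bins (", object@depthBin, " m x ", object@timeBin, " min)\n",
      sep = "")
  cat("  time axis:", if (object@timeOfDay) "time-of-day (circular 24 h)"
      else "absolute hours", "\n")
  v <- object@sv[is.finite(object@sv)]
  if (length(v))
    cat("  range: ", round(min(v), 1), " to ", round(max(v), 1), " dB (",
        sum(is.na(object@sv)), " masked cells)\n", sep = "")
})

setMethod("show", "ClassGrid", function(object) {
  tab <- table(object@classes)
  cat("ClassGrid: ", length(object@depth), " x ", length(object@time),
      " cells, ", sum(tab), " classified\n", sep = "")
  for (k in names(tab)) cat("  ", k, ": ", tab[[k]], "\n", sep = "")
})

setMethod("show", "ClassDensityMap", function(object) {
  cat("ClassDensityMap:", length(object@maps), "classes",
      if (object@weighted) "(backscatter-weighted)" else "(unweighted)", "\n")
  cat("  classes:", paste(names(object@maps), collapse = ", "), "\n")
  cat("  bandwidth:", round(object@bandwidth[["time"]], 2), "h x",
      round(object@bandwidth[["depth"]], 1), "m\n")
})

setMethod("show", "LayerSet", function(object) {
  cat("LayerSet:", nrow(object@layers), "layers\n")
  if (nrow(object@layers)) print(object@layers, row.names = FALSE)
})

setMethod("show", "HourlyDepthModel", function(object) {
  cat("HourlyDepthModel: cyclic depth-by-hour fit\n")
  cat("  tags:", paste(object@tags, collapse = ", "),
      " (n =", object@n, "samples)\n")
  cat("  R2 =", round(object@r2, 2), " edf =", round(object@edf, 2),
      " rho =", round(object@rho, 2), "\n")
  cat("  smooth p", if (object@pvalue < 1e-3) "< 0.001"
      else paste("=", signif(object@pvalue, 2)),
      "; SE range", paste(round(object@seRange, 2), collapse = "-"), "m\n")
})

setMethod("show", "GeneratorPreset", function(object) {
  cat("GeneratorPreset:", object@name, "\n")
  cat("  regimes:", paste(vapply(object@regimes, `[[`, "", "kind"),
                          collapse = " -> "), "\n")
  cat("  sampling:", object@sampleInterval, "min",
      if (length(object@dutyCycle))
        paste0("(duty cycle ", object@dutyCycle[1], " on / ",
               object@dutyCycle[2], " off after day ", object@dutyCycle[3], ")"),
      "\n")
  cat("  echo layers:", nrow(object@layers), "\n")
})
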