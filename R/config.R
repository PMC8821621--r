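# Run configuration and the end-to-end demo pipeline. One manifest JSON
# aggregates every summary statistic so downstream consumers never parse
# logs.

.configDefaults <- function() list(
  preset = "paper_oceanic",
  echoPreset = "rockall",
  nDays = 40,
  seed = 11,
  shelfSeabed = 200,
  depthTrigger = 250,
  binWidth = 50,
  maxDepth = 750,
  svGate = -85,
  kdeTimeStep = 0.5,
  kdeDepthStep = 10,
  kdeWeighted = TRUE,
  migrationThreshold = 100,
  modelK = 5,
  fitModel = FALSE,
  nPerm = 500,
  outputDir = NULL)

#' Build a run configuration
#'
#' Every default equals the documented value used throughout the package
#' (50-m TAD bins to 750 m, shelf break at 200 m seabed, 250 m depth
#' trigger, -85 dB Sv gate, 100 m migration threshold, cyclic basis k = 5).
#' Unknown keys are rejected by name.
#'
#' @param ... overrides of the defaults; see
#'   \code{names(runConfig())} for the full key set.
#' @return a named list with class \code{"mesotrackConfig"}.
#' @seealso \code{\link{readRunConfig}}, \code{\link{runDemo}}
#' @export
runConfig <- function(...) {
  cfg <- .configDefaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "mesotrackConfig")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys are \code{\link{runConfig}} arguments;
#'   unknown keys are rejected by name.
#' @return a \code{"mesotrackConfig"} list.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(runConfig, vals)
}

#' Run the end-to-end synthetic demo pipeline
#'
#' Simulates a track, tag series and two-frequency echogram from the
#' configured presets, then runs the full analysis: diel labelling, phase
#' segmentation, TAD and depth summaries, hourly resampling, ACF
#' periodicity, echogram classification, class kernel densities, layer
#' detection, and the curve-density overlap. Optionally
#' (\code{fitModel = TRUE}) fits the cyclic depth-by-hour model and uses
#' its predicted curve for the overlap; otherwise the hourly-mean depth
#' profile by hour of day is used as the curve.
#'
#' When \code{outputDir} is set, intermediate tables (tag CSV, track CSV,
#' echogram CSV, TAD, layers, curve) and \code{manifest.json} are written
#' there.
#'
#' @param config a \code{\link{runConfig}}.
#' @return the manifest, a named list of every summary statistic,
#'   invisibly when written to disk.
#' @export
runDemo <- function(config = runConfig()) {
  stopifnot(inherits(config, "mesotrackConfig"))
  stage <- "simulate"
  result <- tryCatch({
    preset <- buildPreset(config$preset)
    track <- generateTrack(preset, config$nDays, seed = config$seed)
    calendar <- makeDielCalendar(track)
    series <- generateTagSeries(preset, track, calendar,
                                seed = config$seed + 1)

    stage <- "tag-report"
    series <- labelDiel(series, calendar)
    series <- segmentPhases(series, track,
                            shelfSeabed = config$shelfSeabed,
                            depthTrigger = config$depthTrigger)
    tad <- tadHistogram(series, binWidth = config$binWidth,
                        maxDepth = config$maxDepth)
    ds <- depthSummary(series)

    stage <- "dvm"
    hourly <- resampleHourly(series)
    per <- acfPeriodicity(hourly, seed = config$seed + 2)
    if (isTRUE(config$fitModel)) {
      model <- fitHourlyDepthModel(series, phase = "oceanic",
                                   k = config$modelK)
      curve <- predictDepthCurve(model)
    } else {
      d <- series@data
      keep <- !d$gap & !is.na(d$depth) & !is.na(d$phase) &
        d$phase == "oceanic"
      hr <- as.POSIXlt(d$timestamp[keep], tz = "UTC")$hour
      prof <- tapply(d$depth[keep], hr, mean)
      curve <- data.frame(hour = as.numeric(names(prof)) + 0.5,
                          depth = as.numeric(prof))
      model <- NULL
    }

    stage <- "acoustics"
    echoPreset <- buildPreset(config$echoPreset)
    eg <- generateEchogram(echoPreset, seed = config$seed + 3)
    delta <- deltaSv(eg$sv18, eg$sv38)
    tree <- defaultClassificationTree(gate = config$svGate)
    cg <- classifyCells(delta, eg$sv38, tree)
    dens <- classKde(cg, timeStep = config$kdeTimeStep,
                     depthStep = config$kdeDepthStep,
                     weighted = config$kdeWeighted)
    layers <- detectLayers(eg$sv38, eg$sunTimes,
                           migrationThreshold = config$migrationThreshold)

    stage <- "overlap"
    ov <- overlapIndex(curve, dens, nPerm = config$nPerm,
                       seed = config$seed + 4)

    stage <- "manifest"
    manifest <- list(
      package = as.character(utils::packageVersion("mesotrack")),
      seed = config$seed,
      config = unclass(config),
      depthSummary = ds,
      tadFractions = list(
        oceanicNight0to150 = tadFraction(tad, "oceanic", "night", 0, 150),
        oceanicDay400to600 = tadFraction(tad, "oceanic", "day", 400, 600),
        oceanicDay100to150 = tadFraction(tad, "oceanic", "day", 100, 150)),
      dominantPeriodHours = per$dominantPeriod,
      periodicitySignificant = per$significant,
      model = if (!is.null(model)) modelScore(model),
      layers = layerTable(layers),
      overlap = ov,
      classRanking = rankClasses(ov))

    if (!is.null(config$outputDir)) {
      dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
      out <- function(f) file.path(config$outputDir, f)
      writeTagSeries(series, out("tag.csv"))
      writeTrack(track, out("track.csv"))
      writeEchograms(list(sv18_db = eg$sv18, sv38_db = eg$sv38),
                     out("echogram.csv"))
      utils::write.csv(tad, out("tad.csv"), row.names = FALSE)
      utils::write.csv(curve, out("curve.csv"), row.names = FALSE)
      utils::write.csv(layerTable(layers), out("layers.csv"),
                       row.names = FALSE)
      jsonlite::write_json(manifest, out("manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows", null = "null")
      return(invisible(manifest))
    }
    manifest
  }, error = function(e)
    stop("demo pipeline failed at stage '", stage, "': ",
         conditionMessage(e)))
  result
}
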