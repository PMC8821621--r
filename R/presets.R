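# Named generator presets. paper_oceanic is pinned by calibration to the
# five printed marginal depth statistics of the oceanic phase; rockall and
# azores echo presets encode the layer structure reported for the two
# survey regions.

.oceanicDayTargets <- list(
  c("mean", 412, 10), c("sd", 150, 15),
  c("prob", 400, 600, 0.60, 0.05), c("prob", 100, 150, 0.10, 0.03))

.oceanicNightTargets <- list(
  c("mean", 174, 10), c("sd", 121, 15), c("prob", 0, 150, 0.60, 0.05))

# deterministic optimizer starts (rough moment-matched guesses):
# weights, then (mean, sd) per component
.oceanicDayStarts <- list(c(0.8, 0.2, 480, 85, 140, 40),
                          c(0.75, 0.25, 489, 75, 150, 50))
.oceanicNightStarts <- list(c(0.6, 0.4, 80, 50, 300, 120),
                            c(0.65, 0.35, 90, 60, 320, 100))

.oceanicRegime <- function() {
  day <- calibrateDepthMixture(.oceanicDayTargets, k = 2,
                               starts = .oceanicDayStarts)
  night <- calibrateDepthMixture(.oceanicNightTargets, k = 2,
                                 starts = .oceanicNightStarts)
  list(kind = "oceanic", startFrac = 0, endFrac = 1,
       dayMixture = day, nightMixture = night,
       transitionMinutes = 30, maxDepth = 800, yoYo = NULL)
}

.coastalRegime <- function() {
  # diel-symmetric full-water-column use over a shallow shelf
  mx <- data.frame(weight = c(0.7, 0.3), mean = c(30, 70), sd = c(20, 15))
  list(kind = "coastal", startFrac = 0, endFrac = 1,
       dayMixture = mx, nightMixture = mx,
       transitionMinutes = 0, maxDepth = 100,
       yoYo = list(amplitude = 25, period = 60))
}

.layerRow <- function(class, deltaSv, sv38Peak, dayCenter, nightCenter,
                      sdThickness, migrating)
  data.frame(class = class, deltaSv = deltaSv, sv38Peak = sv38Peak,
             dayCenter = dayCenter, nightCenter = nightCenter,
             sdThickness = sdThickness, migrating = migrating,
             stringsAsFactors = FALSE)

#' Build a named generator preset
#'
#' Four presets are provided. \code{"paper_oceanic"}: a single oceanic diel
#' regime whose day and night depth mixtures are calibrated analytically to
#' the printed oceanic marginals (day mean 412 m, sd 150 m, 60 percent of
#' daytime in 400-600 m, 10 percent in 100-150 m; night mean 174 m, sd
#' 121 m, 60 percent of night in 0-150 m). \code{"coastal"}: diel-symmetric
#' shallow-shelf use with yo-yo bouts. \code{"rockall"}: a northern-survey
#' echogram with a stationary deep scattering layer at 450 m, a primary
#' migrating layer (day 450 m / night 150 m) and a secondary migrating
#' layer (day 200 m / night 50 m). \code{"azores"}: a southern-survey
#' echogram with a stationary layer at 500 m and one migrating layer (day
#' 500 m / night 150 m).
#'
#' @param name one of \code{"paper_oceanic"}, \code{"coastal"},
#'   \code{"rockall"}, \code{"azores"}.
#' @return a \code{\link{GeneratorPreset}}.
#' @examples
#' buildPreset("rockall")
#' @export
buildPreset <- function(name) {
  valid <- c("paper_oceanic", "coastal", "rockall", "azores")
  if (!is.character(name) || length(name) != 1L || !name %in% valid)
    stop("unknown preset '", name, "'; valid presets: ",
         paste(valid, collapse = ", "))
  base <- list(name = name, sampleInterval = 6, dutyCycle = numeric(0),
               layers = .layerRow(character(0), numeric(0), numeric(0),
                                  numeric(0), numeric(0), numeric(0),
                                  logical(0)),
               noiseFloor = c(sv18 = -90, sv38 = -90),
               lat = 52, lon = -15, depthRange = c(0, 800),
               arDecorrelationMinutes = 60, regimes = list())
  p <- switch(name,
    paper_oceanic = within(base, {
      regimes <- list(.oceanicRegime())
      dutyCycle <- c(2, 1, 70)  # 2 days on, 1 day off after 70 days
    }),
    coastal = within(base, {
      regimes <- list(.coastalRegime()); lat <- 54; lon <- 6
    }),
    rockall = within(base, {
      lat <- 58; lon <- -14
      layers <- rbind(
        .layerRow("Sm.(N)SB/Crust.", -6, -68, 450, 450, 25, FALSE),
        .layerRow("Lrg.SB", 7, -64, 450, 150, 20, TRUE),
        .layerRow("FL", 1.5, -66, 200, 50, 15, TRUE))
    }),
    azores = within(base, {
      lat <- 38; lon <- -20
      layers <- rbind(
        .layerRow("Sm.(N)SB/Crust.", -8, -66, 500, 500, 30, FALSE),
        .layerRow("Lrg.SB", 6, -65, 500, 150, 20, TRUE))
    }))
  new("GeneratorPreset", name = p$name, regimes = p$regimes,
      sampleInterval = p$sampleInterval, dutyCycle = p$dutyCycle,
      layers = p$layers, noiseFloor = p$noiseFloor, lat = p$lat,
      lon = p$lon, depthRange = p$depthRange,
      arDecorrelationMinutes = p$arDecorrelationMinutes)
}
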