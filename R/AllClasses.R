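#' @import methods
#' @importFrom stats acf approx coef dnorm fft filter fitted median optim
#'   plogis pnorm predict qlogis qnorm quantile rexp rnorm runif runmed sd
#'   setNames smooth.spline var cor
NULL

setClassUnion("POSIXctOrNULL", c("POSIXct", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' TagSeries: an archival-tag depth time series
#'
#' Container for one pop-up satellite archival tag (PSAT) deployment: a
#' regularly sampled series of depth (m, positive down) with optional
#' temperature and light channels. Rows flagged \code{gap} carry no depth
#' (duty-cycle off periods or unparseable records) and are excluded from all
#' statistics. The \code{diel} and \code{phase} columns are filled in by
#' \code{\link{labelDiel}} and \code{\link{segmentPhases}}.
#'
#' @slot ptt character(1), tag (platform transmitter terminal) identifier.
#' @slot data data.frame with columns \code{timestamp} (POSIXct, UTC,
#'   strictly increasing), \code{depth} (m, \code{NA} on gap rows),
#'   \code{temperature}, \code{light} (optional, may be \code{NA}),
#'   \code{gap} (logical), \code{diel} (\code{"day"}/\code{"night"} or
#'   \code{NA}), \code{phase} (\code{"coastal"}/\code{"oceanic"}/
#'   \code{"excluded"} or \code{NA}).
#' @slot sampleInterval numeric(1), nominal sampling interval in minutes.
#'
#' @seealso \code{\link{readTagSeries}}, \code{\link{generateTagSeries}}
#' @export
setClass("TagSeries",
  representation(ptt = "character", data = "data.frame",
                 sampleInterval = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- object@data
    need <- c("timestamp", "depth", "gap")
    if (!all(need %in% names(d)))
      msg <- c(msg, paste("data must contain columns:",
                          paste(setdiff(need, names(d)), collapse = ", ")))
    else {
      if (is.unsorted(as.numeric(d$timestamp), strictly = TRUE))
        msg <- c(msg, "timestamps must be strictly increasing")
      dep <- d$depth[!d$gap]
      if (length(dep) && any(!is.na(dep) & (dep < 0 | dep > 2000)))
        msg <- c(msg, "depths must lie in [0, 2000] m")
    }
    if (length(object@sampleInterval) != 1L || object@sampleInterval <= 0)
      msg <- c(msg, "sampleInterval must be a positive scalar (minutes)")
    if (is.null(msg)) TRUE else msg
  })

#' DielCalendar: per-date sunrise and sunset times
#'
#' One row per civil (UTC) date with geometric sunrise and sunset (solar
#' elevation crossing 0 degrees) at that date's representative position.
#'
#' @slot table data.frame with columns \code{date} (Date), \code{sunrise},
#'   \code{sunset} (POSIXct UTC), \code{lat}, \code{lon} (degrees).
#' @seealso \code{\link{makeDielCalendar}}, \code{\link{labelDiel}}
#' @export
setClass("DielCalendar",
  representation(table = "data.frame"),
  validity = function(object) {
    t <- object@table
    need <- c("date", "sunrise", "sunset", "lat", "lon")
    if (!all(need %in% names(t)))
      return(paste("table must contain columns:",
                   paste(setdiff(need, names(t)), collapse = ", ")))
    if (nrow(t) && any(t$sunrise >= t$sunset))
      return("sunrise must precede sunset on every covered date")
    TRUE
  })

#' Echogram: gridded volume-backscattering strength
#'
#' A rectangular grid of mean volume-backscattering strength Sv (dB re m^-1)
#' over time x depth cells, produced by echo integration (linear-domain
#' averaging) of backscatter samples. Rows are depth bins (shallow to deep),
#' columns are time bins. The same class holds a frequency-difference grid
#' (\code{quantity = "deltaSv"}, Sv18 - Sv38 in dB).
#'
#' @slot sv numeric matrix (depth bins x time bins), dB; \code{NA} where
#'   masked.
#' @slot frequency numeric(1), acoustic frequency in kHz (\code{NA} for a
#'   difference grid).
#' @slot quantity character(1), \code{"Sv"} or \code{"deltaSv"}.
#' @slot time numeric, time-bin centers in hours.
#' @slot depth numeric, depth-bin centers in m.
#' @slot timeBin,depthBin numeric(1), bin widths (minutes and m).
#' @slot timeOfDay logical(1), TRUE when the time axis is time-of-day
#'   (0-24 h, circular), as in a 24-h composite.
#' @seealso \code{\link{binSv}}, \code{\link{generateEchogram}},
#'   \code{\link{deltaSv}}
#' @export
setClass("Echogram",
  representation(sv = "matrix", frequency = "numeric", quantity = "character",
                 time = "numeric", depth = "numeric", timeBin = "numeric",
                 depthBin = "numeric", timeOfDay = "logical"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@sv) != length(object@depth))
      msg <- c(msg, "nrow(sv) must equal length(depth)")
    if (ncol(object@sv) != length(object@time))
      msg <- c(msg, "ncol(sv) must equal length(time)")
    if (object@timeBin <= 0 || object@depthBin <= 0)
      msg <- c(msg, "bin widths must be positive")
    if (!object@quantity %in% c("Sv", "deltaSv"))
      msg <- c(msg, "quantity must be 'Sv' or 'deltaSv'")
    if (is.null(msg)) TRUE else msg
  })

#' ClassGrid: per-cell functional-group classification
#'
#' Result of applying a dB-difference classification tree to a pair of
#' echograms: each jointly valid cell is assigned a functional scatterer
#' class (or left unclassified) and carries its linear 38-kHz backscatter as
#' a weight for downstream density estimation.
#'
#' @slot classes character matrix (depth x time), class name or \code{NA}.
#' @slot weight numeric matrix, linear-domain sv at 38 kHz per cell.
#' @slot time,depth numeric, bin centers as in \code{\link{Echogram}}.
#' @slot tree data.frame, the classification tree used (columns
#'   \code{class}, \code{lower}, \code{upper}).
#' @seealso \code{\link{classifyCells}}, \code{\link{classKde}}
#' @export
setClass("ClassGrid",
  representation(classes = "matrix", weight = "matrix", time = "numeric",
                 depth = "numeric", tree = "data.frame"),
  validity = function(object) {
    if (!identical(dim(object@classes), dim(object@weight)))
      return("classes and weight must have identical dimensions")
    TRUE
  })

#' ClassDensityMap: per-class 2D kernel densities
#'
#' For each functional class, a 2D kernel density over (time of day, depth),
#' max-normalized so the largest value per class is exactly 1. The time
#' dimension is circular with period 24 h.
#'
#' @slot maps named list of numeric matrices (depth x time), each in [0, 1].
#' @slot time,depth numeric, evaluation-grid centers (hours, m).
#' @slot bandwidth named numeric(2): kernel sd in hours (\code{time}) and m
#'   (\code{depth}).
#' @slot weighted logical(1), whether cells were weighted by linear
#'   backscatter.
#' @seealso \code{\link{classKde}}, \code{\link{overlapIndex}}
#' @export
setClass("ClassDensityMap",
  representation(maps = "list", time = "numeric", depth = "numeric",
                 bandwidth = "numeric", weighted = "logical"),
  validity = function(object) {
    ok <- vapply(object@maps, function(m)
      is.matrix(m) && nrow(m) == length(object@depth) &&
        ncol(m) == length(object@time), logical(1))
    if (!all(ok)) return("every map must be a depth x time matrix")
    TRUE
  })

#' LayerSet: scattering layers extracted from an echogram
#'
#' Layers are tracked across time columns of a 24-h composite echogram and
#' labelled stationary (non-migrating deep scattering layer, NMDSL) or
#' migrating (MDSL) according to the separation of their mean day and night
#' center depths.
#'
#' @slot layers data.frame, one row per retained layer: \code{id},
#'   \code{label} ("stationary"/"migrating"), \code{dayCenter},
#'   \code{nightCenter} (m), \code{meanPeakSv} (dB), \code{nBins}.
#' @slot tracks data.frame, per (layer, time bin): \code{id}, \code{time}
#'   (h), \code{center} (m), \code{thickness} (m, Gaussian-moment sd),
#'   \code{peakSv} (dB).
#' @seealso \code{\link{detectLayers}}
#' @export
setClass("LayerSet",
  representation(layers = "data.frame", tracks = "data.frame"))

#' HourlyDepthModel: cyclic depth-by-hour mixed model
#'
#' A penalized cyclic cubic spline fit of depth on hour of day (basis
#' dimension k = 5, period 24 h), with a per-tag random intercept when more
#' than one tag is supplied and residual AR(1) autocorrelation at the native
#' sample spacing.
#'
#' @slot fit the underlying \code{mgcv::gamm} fit (list with \code{$gam} and
#'   \code{$lme}).
#' @slot rho numeric(1), estimated AR(1) coefficient.
#' @slot r2 numeric(1), squared correlation of fitted and observed depths.
#' @slot edf numeric(1), effective degrees of freedom of the smooth.
#' @slot pvalue numeric(1), approximate p-value of the smooth term.
#' @slot residSD numeric(1), residual standard deviation (m).
#' @slot seRange numeric(2), min and max pointwise standard error of the
#'   predicted depth curve (m).
#' @slot tags character, tag identifiers used in the fit.
#' @slot n integer(1), number of samples fitted.
#' @seealso \code{\link{fitHourlyDepthModel}}, \code{\link{predictDepthCurve}}
#' @export
setClass("HourlyDepthModel",
  representation(fit = "ANY", rho = "numeric", r2 = "numeric",
                 edf = "numeric", pvalue = "numeric", residSD = "numeric",
                 seRange = "numeric", tags = "character", n = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!is.na(object@rho) && (object@rho <= -1 || object@rho >= 1))
      msg <- c(msg, "rho must lie in (-1, 1)")
    if (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1))
      msg <- c(msg, "r2 must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' GeneratorPreset: parametric description of a synthetic study system
#'
#' Bundles everything the synthetic generators need: one or more diel depth
#' regimes for the tag series (with their start/end as fractions of the
#' deployment), the sampling schedule, scattering-layer specifications for
#' the two-frequency echogram, and a fixed location for solar geometry.
#'
#' @slot name character(1), preset identifier.
#' @slot regimes list of depth regimes; each a list with elements
#'   \code{kind} ("coastal"/"oceanic"), \code{startFrac}, \code{endFrac},
#'   \code{dayMixture}, \code{nightMixture} (data.frames with columns
#'   \code{weight}, \code{mean}, \code{sd}), \code{transitionMinutes},
#'   \code{maxDepth}, and optional \code{yoYo} (list: \code{amplitude} m,
#'   \code{period} min).
#' @slot sampleInterval numeric(1), tag sampling interval in minutes.
#' @slot dutyCycle numeric, \code{c(daysOn, daysOff, startDay)} or
#'   length 0 for continuous sampling.
#' @slot layers data.frame of echogram layers: \code{class},
#'   \code{deltaSv} (dB), \code{sv38Peak} (dB), \code{dayCenter},
#'   \code{nightCenter}, \code{sdThickness} (m), \code{migrating} (logical).
#' @slot noiseFloor named numeric(2), background Sv (dB) per frequency
#'   (\code{sv18}, \code{sv38}); \code{-Inf} for noise-free grids.
#' @slot lat,lon numeric(1), fixed location (degrees) for solar geometry.
#' @slot depthRange numeric(2), echogram depth span (m).
#' @slot arDecorrelationMinutes numeric(1), e-folding time of the AR(1)
#'   depth-smoothness process (minutes).
#' @seealso \code{\link{buildPreset}}, \code{\link{generateTagSeries}},
#'   \code{\link{generateEchogram}}
#' @export
setClass("GeneratorPreset",
  representation(name = "character", regimes = "list",
                 sampleInterval = "numeric", dutyCycle = "numeric",
                 layers = "data.frame", noiseFloor = "numeric",
                 lat = "numeric", lon = "numeric", depthRange = "numeric",
                 arDecorrelationMinutes = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@sampleInterval <= 0)
      msg <- c(msg, "sampleInterval must be positive")
    if (length(object@dutyCycle) && length(object@dutyCycle) != 3L)
      msg <- c(msg, "dutyCycle must be c(daysOn, daysOff, startDay) or empty")
    if (length(object@regimes)) {
      fr <- t(vapply(object@regimes,
                     function(r) c(r$startFrac, r$endFrac), numeric(2)))
      if (abs(fr[1, 1]) > 1e-9 || abs(fr[nrow(fr), 2] - 1) > 1e-9 ||
          (nrow(fr) > 1 && any(abs(fr[-1, 1] - fr[-nrow(fr), 2]) > 1e-9)))
        msg <- c(msg, "regime fractions must partition [0, 1]")
      for (r in object@regimes) for (mx in list(r$dayMixture, r$nightMixture)) {
        if (abs(sum(mx$weight) - 1) > 1e-9)
          msg <- c(msg, "mixture weights must sum to 1")
        if (any(mx$sd <= 0)) msg <- c(msg, "mixture sds must be positive")
        if (any(mx$mean < 0 | mx$mean > r$maxDepth))
          msg <- c(msg, "mixture means must lie in [0, maxDepth]")
      }
    }
    if (nrow(object@layers)) {
      dr <- object@depthRange
      ctr <- c(object@layers$dayCenter, object@layers$nightCenter)
      if (any(ctr < dr[1] | ctr > dr[2]))
        msg <- c(msg, "layer centers must lie within depthRange")
      st <- !object@layers$migrating
      if (any(object@layers$dayCenter[st] != object@layers$nightCenter[st]))
        msg <- c(msg, "stationary layers must have dayCenter == nightCenter")
    }
    if (is.null(msg)) TRUE else unique(msg)
  })
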