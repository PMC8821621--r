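#' Segment a deployment into coastal and oceanic phases
#'
#' The oceanic phase begins at the first sample where the seabed under the
#' animal (interpolated from the track) exceeds the shelf-break threshold
#' AND the measured depth exceeds the depth trigger — i.e. the animal has
#' crossed the continental shelf break and made its first deep
#' (> \code{depthTrigger}) excursion. All earlier samples are coastal, all
#' later ones oceanic. If no sample satisfies the rule the whole series is
#' coastal (\code{oceanicStart = NULL}, not an error). An optional terminal
#' window (end-of-deployment residency with unreliable positions) can be
#' marked \code{"excluded"}.
#'
#' @param series a \code{\link{TagSeries}}.
#' @param track a track data.frame overlapping the series in time.
#' @param shelfSeabed seabed depth (m) defining the shelf break, default
#'   200.
#' @param depthTrigger depth (m) a sample must exceed, default 250.
#' @param excludeWindow optional POSIXct length-2 vector; samples inside it
#'   are marked excluded.
#' @return the series with its \code{phase} column filled, plus attribute
#'   \code{oceanicStart} (POSIXct or NULL) on the returned object's data.
#' @seealso \code{\link{depthSummary}}, \code{\link{tadHistogram}}
#' @export
segmentPhases <- function(series, track, shelfSeabed = 200,
                          depthTrigger = 250, excludeWindow = NULL) {
  stopifnot(is(series, "TagSeries"), is.data.frame(track))
  d <- series@data
  seabed <- approx(as.numeric(track$timestamp), track$seabed,
                   xout = as.numeric(d$timestamp), rule = 2)$y
  hit <- !d$gap & !is.na(d$depth) & seabed > shelfSeabed &
    d$depth > depthTrigger
  phase <- rep("coastal", nrow(d))
  oceanicStart <- NULL
  if (any(hit)) {
    first <- which(hit)[1]
    phase[first:nrow(d)] <- "oceanic"
    oceanicStart <- d$timestamp[first]
  }
  if (!is.null(excludeWindow)) {
    stopifnot(length(excludeWindow) == 2L)
    phase[d$timestamp >= excludeWindow[1] &
            d$timestamp <= excludeWindow[2]] <- "excluded"
  }
  d$phase <- phase
  attr(d, "oceanicStart") <- oceanicStart
  series@data <- d
  series
}

#' Oceanic-phase start time
#'
#' @param series a phase-labelled \code{\link{TagSeries}}.
#' @return POSIXct or NULL when the series never left the shelf.
#' @export
oceanicStart <- function(series) attr(series@data, "oceanicStart")

.strata <- function(d) {
  keep <- !d$gap & !is.na(d$depth) & !is.na(d$diel) & !is.na(d$phase) &
    d$phase != "excluded"
  d[keep, , drop = FALSE]
}

#' Time-at-depth histogram
#'
#' Fraction of (non-gap, non-excluded) samples per depth bin, stratified by
#' phase and diel period. Bins are [lower, upper) of width \code{binWidth}
#' from 0 to \code{maxDepth}, with the last bin closed; the few samples
#' deeper than \code{maxDepth} are counted in the last bin.
#'
#' @param series a \code{\link{TagSeries}} labelled by
#'   \code{\link{labelDiel}} and \code{\link{segmentPhases}}.
#' @param binWidth bin width (m), default 50.
#' @param maxDepth histogram ceiling (m), default 750.
#' @return data.frame with columns \code{phase}, \code{diel},
#'   \code{binLower}, \code{binUpper}, \code{fraction}, \code{n}. Strata
#'   with no samples are absent. Fractions sum to 1 within each stratum.
#' @export
tadHistogram <- function(series, binWidth = 50, maxDepth = 750) {
  stopifnot(is(series, "TagSeries"))
  d <- .strata(series@data)
  if (!nrow(d)) return(data.frame(phase = character(0), diel = character(0),
                                  binLower = numeric(0), binUpper = numeric(0),
                                  fraction = numeric(0), n = integer(0)))
  edges <- seq(0, maxDepth, by = binWidth)
  nb <- length(edges) - 1L
  bin <- pmin(findInterval(d$depth, edges, rightmost.closed = TRUE), nb)
  out <- do.call(rbind, lapply(split(seq_len(nrow(d)),
                                     list(d$phase, d$diel), drop = TRUE),
    function(i) {
      cnt <- tabulate(bin[i], nbins = nb)
      data.frame(phase = d$phase[i[1]], diel = d$diel[i[1]],
                 binLower = edges[-length(edges)], binUpper = edges[-1],
                 fraction = cnt / length(i), n = cnt)
    }))
  rownames(out) <- NULL
  out[order(out$phase, out$diel, out$binLower), ]
}

#' Fraction of time in a depth layer
#'
#' Convenience: sums \code{\link{tadHistogram}} fractions over the bins
#' spanning [\code{lo}, \code{hi}) for one (phase, diel) stratum.
#'
#' @param tad a \code{\link{tadHistogram}} result.
#' @param phase,diel the stratum.
#' @param lo,hi layer bounds (m); must align with bin edges.
#' @return numeric(1) fraction.
#' @export
tadFraction <- function(tad, phase, diel, lo, hi) {
  i <- tad$phase == phase & tad$diel == diel &
    tad$binLower >= lo & tad$binUpper <= hi
  sum(tad$fraction[i])
}

#' Depth summary per phase and diel period
#'
#' @param series a labelled \code{\link{TagSeries}}.
#' @return data.frame with columns \code{phase}, \code{diel}, \code{mean},
#'   \code{sd} (sample sd, n-1), \code{max}, \code{n}.
#' @examples
#' # constant-depth series summarises to mean = value, sd = 0
#' @export
depthSummary <- function(series) {
  stopifnot(is(series, "TagSeries"))
  d <- .strata(series@data)
  out <- do.call(rbind, lapply(split(d$depth, list(d$phase, d$diel),
                                     drop = TRUE),
    function(x) data.frame(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
                           max = max(x), n = length(x))))
  key <- do.call(rbind, strsplit(rownames(out), ".", fixed = TRUE))
  out <- cbind(data.frame(phase = key[, 1], diel = key[, 2]), out)
  rownames(out) <- NULL
  out[order(out$phase, out$diel), ]
}
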