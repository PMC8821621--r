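# Scattering-layer extraction from a 24-h composite echogram: per-column
# peak finding on a median-smoothed profile, Gaussian-moment center and
# thickness per peak, nearest-center track linking across columns (with
# midnight wrap-around), and stationary/migrating labelling from mean day
# vs night centers.

# peaks in one smoothed dB profile: local maxima at least `prominence` dB
# above the column background (median); returns center/thickness/peak by
# linear-domain Gaussian moments over the contiguous half-prominence region
.columnPeaks <- function(sv, depth, prominence, minThickness = 2) {
  ok <- is.finite(sv)
  if (!any(ok)) return(NULL)
  prof <- sv
  prof[!ok] <- min(sv[ok]) - 30
  sm <- as.numeric(stats::runmed(prof, 5))
  bg <- median(sm[ok])
  n <- length(sm)
  isMax <- c(FALSE, diff(sm) > 0) & c(diff(sm) <= 0, FALSE)
  cand <- which(isMax & sm >= bg + prominence)
  if (!length(cand)) return(NULL)
  out <- NULL
  used <- rep(FALSE, n)
  for (pk in cand[order(-sm[cand])]) {
    if (used[pk]) next
    thr <- max(sm[pk] - 6, bg + prominence / 2)   # half-prominence region
    lo <- pk; while (lo > 1 && sm[lo - 1] >= thr) lo <- lo - 1
    hi <- pk; while (hi < n && sm[hi + 1] >= thr) hi <- hi + 1
    used[max(1, lo - 10):min(n, hi + 10)] <- TRUE   # margin kills shadows
    w <- .toLinear(sm[lo:hi]) - .toLinear(bg)
    w <- pmax(w, 0)
    if (sum(w) <= 0) next
    d <- depth[lo:hi]
    ctr <- sum(w * d) / sum(w)
    thick <- sqrt(max(sum(w * (d - ctr)^2) / sum(w), minThickness^2))
    out <- rbind(out, data.frame(center = ctr, thickness = thick,
                                 peakSv = sv[pk]))
  }
  out
}

# order-preserving minimal-cost matching of sorted track centers to sorted
# peak centers (sequence alignment; skipping either side costs `skip`,
# matching beyond the per-track allowance is forbidden). Returns, per
# track, the matched peak index or 0.
.monotoneMatch <- function(tc, pc, allow, skip, pen = rep(0, length(tc))) {
  m <- length(tc); n <- length(pc)
  if (m == 0L) return(integer(0))
  D <- matrix(Inf, m + 1, n + 1)
  D[1, ] <- (0:n) * skip
  D[, 1] <- (0:m) * skip
  for (i in seq_len(m)) for (j in seq_len(n)) {
    d <- abs(tc[i] - pc[j])
    mcost <- if (d <= allow[i]) D[i, j] + d + pen[i] else Inf
    D[i + 1, j + 1] <- min(mcost, D[i, j + 1] + skip, D[i + 1, j] + skip)
  }
  asg <- integer(m)
  i <- m; j <- n
  while (i > 0 && j > 0) {
    d <- abs(tc[i] - pc[j])
    if (d <= allow[i] &&
        isTRUE(all.equal(D[i + 1, j + 1], D[i, j] + d + pen[i]))) {
      asg[i] <- j; i <- i - 1; j <- j - 1
    } else if (isTRUE(all.equal(D[i + 1, j + 1], D[i, j + 1] + skip))) {
      i <- i - 1
    } else j <- j - 1
  }
  asg
}

#' Detect scattering layers on a 24-h composite echogram
#'
#' Per time column, peaks with at least \code{prominence} dB above the
#' column background (median of the median-smoothed profile) are reduced to
#' Gaussian-moment centers and thicknesses, then linked across adjacent
#' columns to the nearest active track within \code{linkTolerance} m (the
#' time axis wraps at midnight). Tracks persisting at least
#' \code{minHours} are kept and labelled \code{"migrating"} when their mean
#' day and night centers differ by more than \code{migrationThreshold} m,
#' else \code{"stationary"}.
#'
#' @param grid a composite \code{\link{Echogram}} (Sv, time-of-day axis).
#' @param sunTimes numeric(2), sunrise and sunset hours used to split day
#'   and night columns; alternatively a \code{\link{DielCalendar}} whose
#'   mean sunrise/sunset hours are used.
#' @param migrationThreshold m, default 100.
#' @param prominence dB, default 6.
#' @param linkTolerance m per 6-min column, default 50.
#' @param minHours minimum track persistence (h), default 2.
#' @return a \code{\link{LayerSet}}; empty (with a warning) when no peaks
#'   are found anywhere.
#' @export
detectLayers <- function(grid, sunTimes, migrationThreshold = 100,
                         prominence = 6, linkTolerance = 50, minHours = 2) {
  stopifnot(is(grid, "Echogram"))
  if (is(sunTimes, "DielCalendar")) {
    ct <- sunTimes@table
    frac <- function(t) {
      lt <- as.POSIXlt(t, tz = "UTC"); lt$hour + lt$min / 60 + lt$sec / 3600
    }
    sunTimes <- c(mean(frac(ct$sunrise)), mean(frac(ct$sunset)))
  }
  stopifnot(length(sunTimes) == 2L)
  nT <- length(grid@time)
  # pre-smooth along time (5-column running mean in the linear domain,
  # circular for a 24-h composite) so background noise cannot seed peaks
  lin <- 10^(grid@sv / 10)
  lin[!is.finite(lin)] <- 0
  sm <- if (nT >= 5) {
    idx <- if (grid@timeOfDay)
      function(j) ((j - 3):(j + 1)) %% nT + 1L
    else function(j) pmin(pmax((j - 2):(j + 2), 1L), nT)
    vapply(seq_len(nT), function(j) rowMeans(lin[, idx(j), drop = FALSE]),
           numeric(nrow(lin)))
  } else lin
  svSm <- 10 * log10(sm)
  svSm[!is.finite(svSm)] <- NA_real_
  peaks <- lapply(seq_len(nT), function(j)
    .columnPeaks(svSm[, j], grid@depth, prominence))
  if (all(vapply(peaks, is.null, logical(1)))) {
    warning("no peaks found anywhere on the grid")
    return(new("LayerSet",
               layers = data.frame(id = integer(0), label = character(0),
                                   dayCenter = numeric(0),
                                   nightCenter = numeric(0),
                                   meanPeakSv = numeric(0),
                                   nBins = integer(0)),
               tracks = data.frame(id = integer(0), time = numeric(0),
                                   center = numeric(0),
                                   thickness = numeric(0),
                                   peakSv = numeric(0))))
  }
  # link column peaks into tracks, left to right. Scattering layers do not
  # cross in depth (they merge instead), so the per-column association is
  # the order-preserving matching of active-track centers to peak centers
  # that minimizes total center displacement; unmatched peaks open new
  # tracks, unmatched tracks stay active for up to maxGapBins columns
  # (their peak may be absorbed by a stronger neighbouring layer), with
  # the tolerance growing with the gap up to a cap.
  maxGapBins <- 10L
  tracks <- list()   # each: list(cols, centers, thicks, peaks, last, lastCol)
  for (j in seq_len(nT)) {
    pj <- peaks[[j]]
    if (is.null(pj)) next
    pj <- pj[order(pj$center), , drop = FALSE]
    cand <- which(vapply(tracks, function(t) j - t$lastCol <= maxGapBins,
                         logical(1)))
    cand <- cand[order(vapply(cand, function(ti) tracks[[ti]]$last,
                              numeric(1)))]
    tc <- vapply(cand, function(ti) tracks[[ti]]$last, numeric(1))
    gap <- vapply(cand, function(ti) j - tracks[[ti]]$lastCol, numeric(1))
    allow <- linkTolerance * pmin(gap, 3)
    # continuous tracks outrank stale ones parked on a crossing path
    asg <- .monotoneMatch(tc, pj$center, allow, skip = linkTolerance,
                          pen = 15 * (gap - 1))
    matched <- logical(nrow(pj))
    for (m in seq_along(asg)) {
      r <- asg[m]
      if (r == 0L) next
      matched[r] <- TRUE
      ti <- cand[m]
      tracks[[ti]]$cols <- c(tracks[[ti]]$cols, j)
      tracks[[ti]]$centers <- c(tracks[[ti]]$centers, pj$center[r])
      tracks[[ti]]$thicks <- c(tracks[[ti]]$thicks, pj$thickness[r])
      tracks[[ti]]$peaks <- c(tracks[[ti]]$peaks, pj$peakSv[r])
      tracks[[ti]]$last <- pj$center[r]
      tracks[[ti]]$lastCol <- j
    }
    for (r in which(!matched))
      tracks[[length(tracks) + 1L]] <-
        list(cols = j, centers = pj$center[r], thicks = pj$thickness[r],
             peaks = pj$peakSv[r], last = pj$center[r], lastCol = j)
  }
  # merge fragments of one layer: track B continues track A when B starts
  # within maxGapBins of A's end (small overlaps allowed; duplicate
  # columns are dropped from B) at a compatible center; the time axis
  # wraps at midnight for a 24-h composite
  mergeInto <- function(a, b) {
    keep <- !(b$cols %in% a$cols)
    a$cols <- c(a$cols, b$cols[keep])
    a$centers <- c(a$centers, b$centers[keep])
    a$thicks <- c(a$thicks, b$thicks[keep])
    a$peaks <- c(a$peaks, b$peaks[keep])
    a
  }
  # predicted continuation of track a, gapCols ahead of its end, from the
  # slope of its last few columns
  predictEnd <- function(a, gapCols) {
    o <- order(a$cols)
    k <- min(5L, length(o))
    tail <- o[(length(o) - k + 1):length(o)]
    slope <- if (k >= 2)
      (a$centers[tail[k]] - a$centers[tail[1]]) /
        max(a$cols[tail[k]] - a$cols[tail[1]], 1) else 0
    a$centers[tail[k]] + slope * max(gapCols, 0)
  }
  repeat {
    alive <- which(!vapply(tracks, is.null, logical(1)))
    best <- NULL; bestDist <- Inf
    for (e in alive) for (s in setdiff(alive, e)) {
      a <- tracks[[e]]; b <- tracks[[s]]
      gapCols <- min(b$cols) - max(a$cols)
      if (grid@timeOfDay && gapCols < -nT / 2) gapCols <- gapCols + nT
      if (gapCols < -3 || gapCols > maxGapBins) next
      d <- abs(predictEnd(a, gapCols) - b$centers[which.min(b$cols)])
      if (d > 25 + 10 * max(gapCols, 0)) next
      if (d < bestDist) { bestDist <- d; best <- c(e, s) }
    }
    if (is.null(best)) break
    tracks[[best[1]]] <- mergeInto(tracks[[best[1]]], tracks[[best[2]]])
    tracks[best[2]] <- list(NULL)
  }
  tracks <- Filter(Negate(is.null), tracks)
  binsPerHour <- 60 / grid@timeBin
  keep <- vapply(tracks, function(t) length(t$cols) >= minHours * binsPerHour,
                 logical(1))
  tracks <- tracks[keep]
  tod <- grid@time
  trackDf <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    t <- tracks[[i]]
    data.frame(id = i, time = tod[t$cols], center = t$centers,
               thickness = t$thicks, peakSv = t$peaks)
  }))
  layerDf <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    t <- tracks[[i]]
    isDay <- tod[t$cols] >= sunTimes[1] & tod[t$cols] < sunTimes[2]
    # medians: robust to a few twilight bins claimed from a neighbour
    dayC <- if (any(isDay)) median(t$centers[isDay]) else NA_real_
    nightC <- if (any(!isDay)) median(t$centers[!isDay]) else NA_real_
    mig <- !is.na(dayC) && !is.na(nightC) &&
      abs(dayC - nightC) > migrationThreshold
    data.frame(id = i, label = if (mig) "migrating" else "stationary",
               dayCenter = dayC, nightCenter = nightC,
               meanPeakSv = mean(t$peaks), nBins = length(t$cols))
  }))
  if (is.null(trackDf)) {
    warning("no track persisted for at least ", minHours, " h")
    trackDf <- data.frame(id = integer(0), time = numeric(0),
                          center = numeric(0), thickness = numeric(0),
                          peakSv = numeric(0))
    layerDf <- data.frame(id = integer(0), label = character(0),
                          dayCenter = numeric(0), nightCenter = numeric(0),
                          meanPeakSv = numeric(0), nBins = integer(0))
  }
  new("LayerSet", layers = layerDf, tracks = trackDf)
}
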