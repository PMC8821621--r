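# Echo integration and grid algebra. All averaging happens in the linear
# domain (sv = 10^(Sv/10)); dB values are only a display/storage scale.

.toLinear <- function(db) 10^(db / 10)
.toDb <- function(lin) 10 * log10(lin)

#' Echo-integrate backscatter samples onto a regular grid
#'
#' Bins irregular (time, depth, Sv) samples into regular time x depth
#' cells. The per-cell value is the linear-domain mean back-converted to
#' dB; empty cells are masked (\code{NA}). Samples outside the depth range
#' are dropped (a message reports how many).
#'
#' @param records data.frame with columns \code{time} (hours), \code{depth}
#'   (m) and \code{sv} (dB).
#' @param frequency frequency in kHz (metadata).
#' @param timeBin time bin width in minutes, default 6.
#' @param depthBin depth bin width in m, default 1.
#' @param depthRange numeric(2), grid depth span (m), default c(0, 800).
#' @param timeRange numeric(2), grid time span (hours); default spans the
#'   data rounded to whole bins.
#' @param timeOfDay logical, mark the time axis as circular time-of-day.
#' @return an \code{\link{Echogram}}.
#' @export
binSv <- function(records, frequency = NA_real_, timeBin = 6, depthBin = 1,
                  depthRange = c(0, 800), timeRange = NULL,
                  timeOfDay = FALSE) {
  stopifnot(all(c("time", "depth", "sv") %in% names(records)))
  drop <- records$depth < depthRange[1] | records$depth >= depthRange[2]
  if (any(drop)) {
    message("binSv: dropped ", sum(drop), " record(s) outside depth range")
    records <- records[!drop, , drop = FALSE]
  }
  tb <- timeBin / 60
  if (is.null(timeRange))
    timeRange <- c(floor(min(records$time) / tb),
                   ceiling(max(records$time) / tb)) * tb
  nT <- max(1L, round((timeRange[2] - timeRange[1]) / tb))
  nD <- round((depthRange[2] - depthRange[1]) / depthBin)
  ti <- pmin(pmax(floor((records$time - timeRange[1]) / tb) + 1L, 1L), nT)
  di <- floor((records$depth - depthRange[1]) / depthBin) + 1L
  cell <- (ti - 1L) * nD + di
  lin <- tapply(.toLinear(records$sv), cell, mean)
  sv <- matrix(NA_real_, nrow = nD, ncol = nT)
  sv[as.integer(names(lin))] <- .toDb(lin)
  new("Echogram", sv = sv, frequency = frequency, quantity = "Sv",
      time = timeRange[1] + (seq_len(nT) - 0.5) * tb,
      depth = depthRange[1] + (seq_len(nD) - 0.5) * depthBin,
      timeBin = timeBin, depthBin = depthBin, timeOfDay = timeOfDay)
}

#' Fold a multi-day echogram onto a 24-h composite
#'
#' Columns are folded onto time-of-day bins; cells observed on several days
#' are averaged in the linear domain. Time-of-day bins never observed stay
#' masked. A single-day grid already on [0, 24) is returned unchanged
#' (apart from the time-of-day flag).
#'
#' @param grid an \code{\link{Echogram}} with an absolute time axis.
#' @return an \code{\link{Echogram}} on time-of-day bins (circular 24 h).
#' @export
composite24h <- function(grid) {
  stopifnot(is(grid, "Echogram"))
  tb <- grid@timeBin / 60
  nT <- round(24 / tb)
  tod <- grid@time %% 24
  bin <- pmin(floor(tod / tb) + 1L, nT)
  lin <- .toLinear(grid@sv)
  out <- matrix(NA_real_, nrow = nrow(lin), ncol = nT)
  for (b in unique(bin)) {
    cols <- which(bin == b)
    m <- lin[, cols, drop = FALSE]
    v <- rowMeans(m, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    out[, b] <- v
  }
  new("Echogram", sv = .toDb(out), frequency = grid@frequency,
      quantity = grid@quantity,
      time = (seq_len(nT) - 0.5) * tb, depth = grid@depth,
      timeBin = grid@timeBin, depthBin = grid@depthBin, timeOfDay = TRUE)
}

#' Frequency-difference grid
#'
#' Delta Sv = Sv(18 kHz) - Sv(38 kHz) per jointly valid cell (equivalent to
#' a backscatter ratio in linear space). Both grids must share their
#' binning exactly.
#'
#' @param grid18,grid38 \code{\link{Echogram}}s at 18 and 38 kHz.
#' @return an \code{\link{Echogram}} with \code{quantity = "deltaSv"}.
#' @export
deltaSv <- function(grid18, grid38) {
  stopifnot(is(grid18, "Echogram"), is(grid38, "Echogram"))
  bad <- character(0)
  if (!isTRUE(all.equal(grid18@time, grid38@time))) bad <- c(bad, "time")
  if (!isTRUE(all.equal(grid18@depth, grid38@depth))) bad <- c(bad, "depth")
  if (length(bad))
    stop("grids differ on axis/axes: ", paste(bad, collapse = ", "))
  new("Echogram", sv = grid18@sv - grid38@sv, frequency = NA_real_,
      quantity = "deltaSv", time = grid18@time, depth = grid18@depth,
      timeBin = grid18@timeBin, depthBin = grid18@depthBin,
      timeOfDay = grid18@timeOfDay)
}

#' Read and write echograms as long CSV
#'
#' Long format with columns \code{time} (h), \code{depth} (m) and one Sv
#' column per grid (e.g. \code{sv18_db}, \code{sv38_db}); masked cells are
#' empty. This is the text twin of the gridded NetCDF layout.
#'
#' @param grids a named list of \code{\link{Echogram}}s sharing one
#'   binning, e.g. \code{list(sv18_db = g18, sv38_db = g38)}.
#' @param path file path.
#' @return \code{writeEchograms}: \code{path} invisibly;
#'   \code{readEchograms}: a named list of \code{\link{Echogram}}s.
#' @export
writeEchograms <- function(grids, path) {
  stopifnot(is.list(grids), length(grids) >= 1)
  g1 <- grids[[1]]
  out <- data.frame(time = rep(g1@time, each = length(g1@depth)),
                    depth = rep(g1@depth, length(g1@time)))
  for (nm in names(grids)) out[[nm]] <- as.vector(grids[[nm]]@sv)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @param frequencies named numeric, kHz per Sv column; guessed from
#'   column names like \code{sv18_db} when NULL.
#' @rdname writeEchograms
#' @export
readEchograms <- function(path, frequencies = NULL) {
  d <- utils::read.csv(path)
  tvals <- sort(unique(d$time)); dvals <- sort(unique(d$depth))
  tb <- if (length(tvals) > 1) round(diff(tvals)[1] * 60, 6) else 6
  db <- if (length(dvals) > 1) diff(dvals)[1] else 1
  svCols <- setdiff(names(d), c("time", "depth"))
  ti <- match(d$time, tvals); di <- match(d$depth, dvals)
  lapply(setNames(svCols, svCols), function(nm) {
    sv <- matrix(NA_real_, nrow = length(dvals), ncol = length(tvals))
    sv[cbind(di, ti)] <- d[[nm]]
    fq <- if (!is.null(frequencies) && nm %in% names(frequencies))
      frequencies[[nm]]
    else suppressWarnings(as.numeric(gsub("\\D", "", nm)))
    new("Echogram", sv = sv, frequency = fq,
        quantity = if (grepl("delta", nm)) "deltaSv" else "Sv",
        time = tvals, depth = dvals, timeBin = tb, depthBin = db,
        timeOfDay = max(tvals) <= 24)
  })
}
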