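#' Resample a tag series to hourly resolution
#'
#' Hourly depth means of in-hour (non-gap) samples on a regular hourly
#' grid. Hours with no samples (duty-cycle off days) are filled by a
#' smoothing spline fitted to the observed hourly means within +/- 72 h of
#' the gap and flagged \code{imputed}; gaps wider than twice the fitting
#' window are left missing with a warning.
#'
#' @param series a \code{\link{TagSeries}}.
#' @param windowHours half-width of the spline fitting window (h),
#'   default 72.
#' @return data.frame with columns \code{hour} (POSIXct, regular 1-h grid),
#'   \code{depth} (m) and \code{imputed} (logical).
#' @seealso \code{\link{acfPeriodicity}}, \code{\link{waveletPower}}
#' @export
resampleHourly <- function(series, windowHours = 72) {
  stopifnot(is(series, "TagSeries"))
  d <- series@data[!series@data$gap & !is.na(series@data$depth), ]
  if (!nrow(d)) stop("series has no non-gap samples")
  h0 <- trunc(d$timestamp[1], "hours")
  h1 <- trunc(d$timestamp[nrow(d)], "hours")
  grid <- seq(h0, h1, by = 3600)
  idx <- as.integer(floor(as.numeric(d$timestamp - h0, units = "hours"))) + 1L
  depth <- rep(NA_real_, length(grid))
  agg <- tapply(d$depth, idx, mean)
  depth[as.integer(names(agg))] <- agg
  imputed <- is.na(depth)
  if (any(imputed)) {
    hnum <- as.numeric(grid - h0, units = "hours")
    obs <- which(!imputed)
    for (i in which(imputed)) {
      near <- obs[abs(hnum[obs] - hnum[i]) <= windowHours]
      gapw <- if (length(near)) min(abs(hnum[near] - hnum[i])) else Inf
      if (gapw > 2 * windowHours || length(near) < 8) {
        warning("gap at ", format(grid[i]), " wider than the fitting ",
                "window; left missing")
        next
      }
      fit <- smooth.spline(hnum[near], depth[near])
      depth[i] <- predict(fit, hnum[i])$y
    }
  }
  data.frame(hour = grid, depth = depth, imputed = imputed)
}
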