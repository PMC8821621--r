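# Class-specific 2D kernel densities over (time of day, depth), circular
# in time with period 24 h. Implemented as a binned KDE: classified cells
# (weighted by linear backscatter, or unweighted) are aggregated onto the
# evaluation grid and blurred with a separable Gaussian kernel - circular
# convolution along time, truncated convolution along depth. Each class
# map is rescaled so its maximum is exactly 1.

# circular (weighted) standard deviation of hours, in hours
.circularSdHours <- function(h, w) {
  th <- h * 2 * pi / 24
  C <- sum(w * cos(th)) / sum(w)
  S <- sum(w * sin(th)) / sum(w)
  R <- sqrt(C^2 + S^2)
  if (R >= 1) return(0)
  sqrt(-2 * log(R)) * 24 / (2 * pi)
}

.silverman <- function(sd, nEff) 1.06 * sd * nEff^(-1 / 5)

#' Class-specific 2D kernel density maps
#'
#' For each functional class in a \code{\link{ClassGrid}}, estimates a 2D
#' Gaussian kernel density over (time of day, depth). The time dimension is
#' circular (period 24 h, wrap-around kernel). Bandwidths follow a
#' Silverman-type rule per dimension (1.06 sigma n_eff^(-1/5), with the
#' weighted circular sd in time, the weighted sd in depth, and the
#' effective sample size (sum w)^2 / sum w^2). Each map is rescaled to a
#' maximum of exactly 1. Classes with no classified cell are dropped with
#' a notice.
#'
#' @param classGrid a \code{\link{ClassGrid}}.
#' @param timeStep,depthStep evaluation-grid resolution (h, m); defaults
#'   0.5 h and 10 m.
#' @param weighted weight cells by linear 38-kHz backscatter (default
#'   TRUE); FALSE counts classified cells equally.
#' @param bandwidth optional named numeric(2) \code{c(time = , depth = )}
#'   overriding the rule (h, m).
#' @return a \code{\link{ClassDensityMap}}.
#' @export
classKde <- function(classGrid, timeStep = 0.5, depthStep = 10,
                     weighted = TRUE, bandwidth = NULL) {
  stopifnot(is(classGrid, "ClassGrid"))
  tGrid <- seq(timeStep / 2, 24 - timeStep / 2, by = timeStep)
  dRange <- range(classGrid@depth) + c(-0.5, 0.5) * diff(classGrid@depth[1:2])
  dEdges <- seq(dRange[1], dRange[2], by = depthStep)
  dGrid <- dEdges[-length(dEdges)] + depthStep / 2
  nT <- length(tGrid); nD <- length(dGrid)

  cellT <- rep(classGrid@time, each = length(classGrid@depth))
  cellD <- rep(classGrid@depth, length(classGrid@time))
  present <- sort(unique(as.vector(classGrid@classes)))
  maps <- list(); bws <- c(time = NA_real_, depth = NA_real_)
  for (cl in present) {
    sel <- which(classGrid@classes == cl)
    w <- if (weighted) classGrid@weight[sel] else rep(1, length(sel))
    h <- cellT[sel]; d <- cellD[sel]
    nEff <- sum(w)^2 / sum(w^2)
    if (is.null(bandwidth)) {
      sdT <- .circularSdHours(h, w)
      mW <- sum(w * d) / sum(w)
      sdD <- sqrt(sum(w * (d - mW)^2) / sum(w))
      bw <- c(time = max(.silverman(sdT, nEff), timeStep),
              depth = max(.silverman(sdD, nEff), depthStep))
    } else bw <- bandwidth
    bws <- bw
    # aggregate weights onto the evaluation grid
    ti <- pmin(floor(h / timeStep) + 1L, nT)
    di <- pmin(pmax(floor((d - dRange[1]) / depthStep) + 1L, 1L), nD)
    H <- matrix(0, nrow = nD, ncol = nT)
    for (k in seq_along(sel)) H[di[k], ti[k]] <- H[di[k], ti[k]] + w[k]
    # separable Gaussian blur: circular in time, truncated in depth
    lagT <- outer(tGrid, tGrid, function(a, b) {
      dd <- abs(a - b); pmin(dd, 24 - dd)
    })
    KT <- exp(-lagT^2 / (2 * bw[["time"]]^2))
    KD <- exp(-outer(dGrid, dGrid, "-")^2 / (2 * bw[["depth"]]^2))
    dens <- KD %*% H %*% KT
    mx <- max(dens)
    maps[[cl]] <- if (mx > 0) dens / mx else dens
    attr(maps[[cl]], "bandwidth") <- bw
  }
  empty <- setdiff(classGrid@tree$class, present)
  if (length(empty))
    message("classKde: no cells for class(es) ",
            paste(empty, collapse = ", "), "; map(s) absent")
  new("ClassDensityMap", maps = maps, time = tGrid, depth = dGrid,
      bandwidth = bws, weighted = weighted)
}
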