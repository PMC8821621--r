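# Overlap between a predicted diel depth curve and the class density maps:
# the mean scaled density sampled along the curve, with a permutation null
# (random cyclic hour shifts plus uniform depth offsets of the curve).

# bilinear sample of a density map (circular in time) at (hour, depth)
.sampleMap <- function(map, tGrid, dGrid, hour, depth) {
  nT <- length(tGrid); nD <- length(dGrid)
  tStep <- 24 / nT
  ht <- (hour %% 24) / tStep - 0.5
  i0 <- floor(ht); ft <- ht - i0
  iA <- (i0 %% nT) + 1L; iB <- ((i0 + 1) %% nT) + 1L
  dStep <- dGrid[2] - dGrid[1]
  depth <- pmin(pmax(depth, dGrid[1]), dGrid[nD])   # clip to grid
  hd <- (depth - dGrid[1]) / dStep
  j0 <- pmin(pmax(floor(hd), 0), nD - 2); fd <- hd - j0
  jA <- j0 + 1L; jB <- j0 + 2L
  (1 - ft) * ((1 - fd) * map[cbind(jA, iA)] + fd * map[cbind(jB, iA)]) +
    ft * ((1 - fd) * map[cbind(jA, iB)] + fd * map[cbind(jB, iB)])
}

#' Overlap of a diel depth curve with acoustic class densities
#'
#' For each class, the overlap index is the mean of the class's scaled
#' (max = 1) density sampled along the depth curve over a 24-h hourly
#' grid. Significance is assessed against a permutation null built from
#' \code{nPerm} transformed curves (random cyclic hour shift plus a
#' uniform depth offset keeping the curve inside the map's depth range):
#' the one-sided p-value is the fraction of null curves scoring at least
#' as high (with the +1 correction), and z is the standardized exceedance.
#'
#' If parts of the curve leave the map's depth range they are clipped to
#' it, with a warning.
#'
#' @param curve data.frame with columns \code{hour}, \code{depth} (from
#'   \code{\link{predictDepthCurve}} or generator truth).
#' @param maps a \code{\link{ClassDensityMap}}.
#' @param nPerm number of permutations, default 500.
#' @param seed integer RNG seed.
#' @return data.frame, one row per class: \code{class}, \code{index},
#'   \code{z}, \code{p}, \code{rank} (1 = strongest overlap; ties broken
#'   by z then class name).
#' @export
overlapIndex <- function(curve, maps, nPerm = 500, seed = 1) {
  stopifnot(is(maps, "ClassDensityMap"),
            all(c("hour", "depth") %in% names(curve)))
  hours <- seq(0, 23, by = 1)
  cd <- approx(curve$hour, curve$depth, xout = hours, rule = 2)$y
  dGrid <- maps@depth
  if (any(cd < dGrid[1] | cd > dGrid[length(dGrid)])) {
    warning("curve leaves the map depth range; clipped")
    cd <- pmin(pmax(cd, dGrid[1]), dGrid[length(dGrid)])
  }
  idx <- vapply(maps@maps, function(m)
    mean(.sampleMap(m, maps@time, dGrid, hours, cd)), numeric(1))
  # permutation null: cyclic hour shift + uniform depth offset within grid
  lo <- dGrid[1] - min(cd); hi <- dGrid[length(dGrid)] - max(cd)
  null <- .withSeed(seed, {
    shifts <- runif(nPerm, 0, 24)
    offs <- runif(nPerm, min(lo, 0), max(hi, 0))
    vapply(seq_len(nPerm), function(b) {
      db <- pmin(pmax(cd + offs[b], dGrid[1]), dGrid[length(dGrid)])
      vapply(maps@maps, function(m)
        mean(.sampleMap(m, maps@time, dGrid, hours + shifts[b], db)),
        numeric(1))
    }, numeric(length(maps@maps)))
  })
  null <- matrix(null, nrow = length(maps@maps))
  nullSd <- apply(null, 1, sd)
  z <- ifelse(nullSd > 0, (idx - rowMeans(null)) / nullSd, 0)
  p <- (1 + rowSums(null >= idx)) / (nPerm + 1)
  out <- data.frame(class = names(maps@maps), index = unname(idx),
                    z = unname(z), p = unname(p))
  ord <- order(-out$index, -out$z, out$class)
  out$rank[ord] <- seq_along(ord)
  out[ord, ]
}

#' Rank classes by overlap
#'
#' @param result an \code{\link{overlapIndex}} result.
#' @return character vector of class names, strongest overlap first
#'   (descending index; ties broken by z-score, then alphabetically).
#' @export
rankClasses <- function(result) {
  stopifnot(all(c("class", "index", "z") %in% names(result)))
  result$class[order(-result$index, -result$z, result$class)]
}
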