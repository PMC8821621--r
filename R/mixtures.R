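# Truncated-normal mixtures: the parametric family used for synthetic
# day/night depth distributions. Standard closed forms for moments and
# interval masses of a normal truncated to [a, b].

.tnZ <- function(mu, sd, a, b) pnorm((b - mu) / sd) - pnorm((a - mu) / sd)

.tnMean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  Z <- pnorm(be) - pnorm(al)
  mu + sd * (dnorm(al) - dnorm(be)) / Z
}

.tnVar <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  Z <- pnorm(be) - pnorm(al)
  r <- (dnorm(al) - dnorm(be)) / Z
  sd^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / Z - r^2)
}

.tnP <- function(mu, sd, lo, hi, a, b) {
  lo <- pmax(lo, a); hi <- pmin(hi, b)
  (pnorm((hi - mu) / sd) - pnorm((lo - mu) / sd)) / .tnZ(mu, sd, a, b)
}

#' Analytic statistics of a truncated-normal mixture
#'
#' @param mixture data.frame with columns \code{weight}, \code{mean},
#'   \code{sd} (component parameters before truncation).
#' @param range numeric(2), truncation bounds (m).
#' @return list with \code{mean}, \code{sd}, and \code{prob(lo, hi)}, a
#'   function giving the mixture mass on an interval.
#' @examples
#' mx <- data.frame(weight = 1, mean = 100, sd = 20)
#' mixtureStats(mx, c(0, 800))$mean
#' @export
mixtureStats <- function(mixture, range = c(0, 800)) {
  w <- mixture$weight; m <- mixture$mean; s <- mixture$sd
  a <- range[1]; b <- range[2]
  mm <- mapply(.tnMean, m, s, MoreArgs = list(a = a, b = b))
  vv <- mapply(.tnVar, m, s, MoreArgs = list(a = a, b = b))
  mean <- sum(w * mm)
  v <- sum(w * (vv + mm^2)) - mean^2
  list(mean = mean, sd = sqrt(max(v, 0)),
       prob = function(lo, hi)
         sum(w * mapply(.tnP, m, s, MoreArgs = list(lo = lo, hi = hi,
                                                    a = a, b = b))))
}

# mixture CDF on a depth grid, and its (comonotone) quantile function
.mixtureQuantileFun <- function(mixture, range = c(0, 800), nGrid = 2048L) {
  if (nrow(mixture) == 1L) {
    # analytic truncated-normal quantile
    mu <- mixture$mean[1]; s <- mixture$sd[1]
    if (s < 1e-9) return(function(p) rep(mu, length(p)))
    Fa <- pnorm((range[1] - mu) / s); Fb <- pnorm((range[2] - mu) / s)
    return(function(p) mu + s * qnorm(Fa + p * (Fb - Fa)))
  }
  dgrid <- seq(range[1], range[2], length.out = nGrid)
  w <- mixture$weight; m <- mixture$mean; s <- mixture$sd
  F <- rowSums(mapply(function(wi, mi, si)
    wi * (pnorm((dgrid - mi) / si) - pnorm((range[1] - mi) / si)) /
      .tnZ(mi, si, range[1], range[2]), w, m, s))
  F[1] <- 0; F[nGrid] <- 1
  F <- cummax(F)  # guard monotonicity against rounding
  function(p) approx(F, dgrid, xout = p, rule = 2, ties = "ordered")$y
}

# parse a target spec: list(c("mean", value, tol), c("sd", ...),
# c("prob", lo, hi, value, tol)) or a data.frame with columns
# statistic, lo, hi, value, tolerance
.normalizeTargets <- function(targets) {
  if (is.data.frame(targets)) {
    return(lapply(seq_len(nrow(targets)), function(i) as.list(targets[i, ])))
  }
  lapply(targets, function(t) {
    if (is.list(t)) return(t)
    if (t[[1]] %in% c("mean", "sd"))
      list(statistic = t[[1]], lo = NA, hi = NA,
           value = as.numeric(t[[2]]), tolerance = as.numeric(t[[3]]))
    else
      list(statistic = "prob", lo = as.numeric(t[[2]]), hi = as.numeric(t[[3]]),
           value = as.numeric(t[[4]]), tolerance = as.numeric(t[[5]]))
  })
}

.targetResiduals <- function(mixture, targets, range) {
  st <- mixtureStats(mixture, range)
  vapply(targets, function(t) {
    got <- switch(t$statistic, mean = st$mean, sd = st$sd,
                  prob = st$prob(t$lo, t$hi),
                  stop("unknown target statistic: ", t$statistic))
    (got - t$value) / t$tolerance
  }, numeric(1))
}

#' Calibrate a truncated-normal depth mixture to target statistics
#'
#' Finds a K-component truncated-normal mixture whose analytic mean,
#' standard deviation and interval masses match the supplied targets. This
#' is how the synthetic oceanic preset is pinned to a study's printed
#' marginal depth statistics. Deterministic: a fixed set of Nelder-Mead
#' starts, no randomness.
#'
#' @param targets a list of targets, each either
#'   \code{c("mean", value, tolerance)}, \code{c("sd", value, tolerance)} or
#'   \code{c("prob", lo, hi, value, tolerance)} (depth interval mass), or an
#'   equivalent data.frame with columns \code{statistic, lo, hi, value,
#'   tolerance}.
#' @param k integer, number of mixture components (default 2).
#' @param range numeric(2), truncation bounds in m (default \code{c(0, 800)}).
#' @param starts optional list of numeric start vectors
#'   (\code{w_1..w_{k-1}, mean_1, sd_1, ..., mean_k, sd_k}); sensible
#'   defaults otherwise.
#' @return data.frame with columns \code{weight}, \code{mean}, \code{sd}.
#'   Errors (reporting the worst residual) if no mixture satisfies every
#'   target within its tolerance.
#' @examples
#' calibrateDepthMixture(list(c("mean", 100, 1)), k = 1)
#' @export
calibrateDepthMixture <- function(targets, k = 2L, range = c(0, 800),
                                  starts = NULL) {
  targets <- .normalizeTargets(targets)
  a <- range[1]; b <- range[2]

  unpack <- function(p) {
    if (k == 1L) w <- 1
    else {
      # logistic weights, last component takes the remainder
      e <- exp(p[seq_len(k - 1)])
      w <- c(e, 1) / (sum(e) + 1)
    }
    q <- if (k > 1) p[-seq_len(k - 1)] else p
    data.frame(weight = w,
               mean = a + (b - a) * plogis(q[seq(1, 2 * k, 2)]),
               sd = exp(q[seq(2, 2 * k, 2)]))
  }
  obj <- function(p) {
    mx <- unpack(p)
    if (any(mx$sd < 1) || any(mx$sd > (b - a))) return(1e8)
    sum(.targetResiduals(mx, targets, range)^2)
  }
  pack <- function(w, m, s)
    c(if (k > 1) log(w[-k] / w[k]),
      as.vector(rbind(qlogis(pmin(pmax((m - a) / (b - a), 0.01), 0.99)),
                      log(s))))
  if (is.null(starts)) {
    spread <- seq(a + 0.15 * (b - a), a + 0.7 * (b - a), length.out = max(k, 2))
    starts <- list(
      pack(rep(1 / k, k), spread[seq_len(k)], rep(0.1 * (b - a), k)),
      pack(seq(2, 1, length.out = k) / sum(seq(2, 1, length.out = k)),
           rev(spread)[seq_len(k)], rep(0.05 * (b - a), k)))
  } else {
    starts <- lapply(starts, function(s)
      pack(s[seq_len(k)] ,
           s[k + seq(1, 2 * k, 2)], s[k + seq(2, 2 * k, 2)]))
  }
  fits <- lapply(starts, function(s)
    optim(s, obj, method = "Nelder-Mead",
          control = list(maxit = 20000, reltol = 1e-14)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  mx <- unpack(best$par)
  res <- .targetResiduals(mx, targets, range)
  if (max(abs(res)) > 1) {
    worst <- which.max(abs(res))
    t <- targets[[worst]]
    stop("infeasible calibration targets: worst residual is ",
         signif(abs(res[worst]), 3), " tolerances for statistic '",
         t$statistic, "' (target ", t$value, " +/- ", t$tolerance, ")")
  }
  mx[order(-mx$weight), , drop = FALSE]
}
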