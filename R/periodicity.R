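# Periodicity of the vertical-migration signal: sample autocorrelation with
# a phase-randomized surrogate null, and a Morlet continuous wavelet
# transform (time-resolved and global power).

.fillNA <- function(x) {
  if (!anyNA(x)) return(x)
  i <- seq_along(x)
  approx(i[!is.na(x)], x[!is.na(x)], xout = i, rule = 2)$y
}

# phase-randomized surrogate preserving the power spectrum
.phaseSurrogate <- function(x) {
  n <- length(x)
  X <- fft(x)
  half <- seq(2, floor((n + 1) / 2))      # positive frequencies, no Nyquist
  ph <- runif(length(half), 0, 2 * pi)
  X[half] <- Mod(X[half]) * exp(1i * ph)
  X[n + 2 - half] <- Conj(X[half])        # Hermitian symmetry
  Re(fft(X, inverse = TRUE)) / n
}

# value and lag of the highest local ACF maximum at lags >= minLag
.acfDominant <- function(a, minLag) {
  n <- length(a) - 1L                     # a[1] is lag 0
  v <- a[-1]
  loc <- which(diff(sign(diff(c(v[1], v, v[n])))) < 0)
  loc <- loc[loc >= minLag]
  if (!length(loc)) loc <- which.max(replace(v, seq_len(minLag - 1), -Inf))
  best <- loc[which.max(v[loc])]
  c(lag = best, value = v[best])
}

#' Autocorrelation periodicity of an hourly depth series
#'
#' Mean-removed sample autocorrelation to \code{maxLag} hours. The dominant
#' period is the lag (>= \code{minLag}) of the highest local ACF maximum;
#' its significance is assessed against the same statistic computed on
#' surrogate series. The default null (\code{"ar1"}) simulates AR(1) series
#' matched to the observed lag-1 autocorrelation and variance, so the test
#' asks for periodicity beyond short-range autocorrelation; \code{"shuffle"}
#' permutes the series (white null); \code{"phase"} (spectrum-preserving
#' phase randomization) is provided for completeness but has essentially no
#' power against periodicity, since the ACF is a function of the spectrum.
#'
#' @param hourly a data.frame from \code{\link{resampleHourly}} (columns
#'   \code{hour}, \code{depth}); remaining missing values are linearly
#'   interpolated.
#' @param maxLag maximum lag (h), default 96.
#' @param minLag smallest admissible dominant period (h), default 6.
#' @param nSurrogate number of surrogates, default 200.
#' @param seed integer seed for the surrogate draw.
#' @param null surrogate type: \code{"ar1"} (default), \code{"shuffle"} or
#'   \code{"phase"}.
#' @return list with \code{lag}, \code{acf} (lag 0..maxLag),
#'   \code{dominantPeriod} (h), \code{dominantValue}, \code{significant}
#'   (logical), \code{surrogateQ95}.
#' @examples
#' h <- data.frame(hour = seq_len(240),
#'                 depth = 300 + 100 * cos(2 * pi * seq_len(240) / 24))
#' acfPeriodicity(h, seed = 1)$dominantPeriod
#' @export
acfPeriodicity <- function(hourly, maxLag = 96, minLag = 6,
                           nSurrogate = 200, seed = 1,
                           null = c("ar1", "shuffle", "phase")) {
  null <- match.arg(null)
  x <- .fillNA(hourly$depth)
  if (length(x) < 5 * 24) stop("need at least 5 days of hourly data")
  if (var(x) < 1e-12) stop("zero variance: constant depth series")
  x <- x - mean(x)
  a <- as.numeric(acf(x, lag.max = maxLag, plot = FALSE,
                      demean = FALSE)$acf)
  dom <- .acfDominant(a, minLag)
  n <- length(x)
  phi <- max(min(a[2], 0.999), 0)
  sdInnov <- sd(x) * sqrt(1 - phi^2)
  q95 <- .withSeed(seed, {
    stat <- vapply(seq_len(nSurrogate), function(i) {
      s <- switch(null,
        ar1 = as.numeric(filter(rnorm(n, 0, sdInnov), phi,
                                method = "recursive")),
        shuffle = sample(x),
        phase = .phaseSurrogate(x))
      as <- as.numeric(acf(s - mean(s), lag.max = maxLag, plot = FALSE,
                           demean = FALSE)$acf)
      .acfDominant(as, minLag)[["value"]]
    }, numeric(1))
    quantile(stat, 0.95, names = FALSE)
  })
  list(lag = 0:maxLag, acf = a, dominantPeriod = unname(dom[["lag"]]),
       dominantValue = unname(dom[["value"]]),
       significant = dom[["value"]] > q95, surrogateQ95 = q95)
}

#' Morlet wavelet power of an hourly depth series
#'
#' Continuous wavelet transform (Morlet, omega0 = 6) over periods
#' \code{periodRange}, following the standard FFT implementation with
#' zero padding. Returns the time-resolved power and the global
#' (time-averaged) spectrum with its peak period.
#'
#' @param hourly as in \code{\link{acfPeriodicity}}.
#' @param periodRange numeric(2), period span in hours, default
#'   \code{c(2, 64)}.
#' @param dj scale resolution in octaves, default 1/12.
#' @return list with \code{period} (h), \code{globalPower},
#'   \code{peakPeriod} (h), \code{power} (period x time matrix),
#'   \code{time} (h since series start).
#' @export
waveletPower <- function(hourly, periodRange = c(2, 64), dj = 1 / 12) {
  x <- .fillNA(hourly$depth)
  if (length(x) < 5 * 24) stop("need at least 5 days of hourly data")
  if (var(x) < 1e-12) stop("zero variance: constant depth series")
  x <- x - mean(x)
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  xp <- c(x, rep(0, npad - n))
  omega0 <- 6
  fourierFactor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  s0 <- periodRange[1] / fourierFactor
  J <- ceiling(log2(periodRange[2] / periodRange[1]) / dj)
  scales <- s0 * 2^(dj * (0:J))
  k <- c(0:(npad / 2), -((npad / 2 - 1):1)) * 2 * pi / npad  # dt = 1 h
  fx <- fft(xp)
  power <- matrix(NA_real_, nrow = length(scales), ncol = n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- pi^(-0.25) * sqrt(2 * pi * s) * exp(-(s * k - omega0)^2 / 2) *
      (k > 0)
    w <- fft(fx * psi, inverse = TRUE) / npad
    power[j, ] <- Mod(w[seq_len(n)])^2
  }
  gp <- rowMeans(power)
  period <- fourierFactor * scales
  list(period = period, globalPower = gp,
       peakPeriod = period[which.max(gp)], power = power,
       time = seq_len(n) - 1)
}
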