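# Cyclic depth-by-hour model: depth ~ s(hour, k = 5, bs = "cc") (+ per-tag
# random intercept) with residual AR(1) at the native sample spacing,
# fitted with mgcv::gamm / nlme.

.modelFrame <- function(series, phase) {
  if (is(series, "TagSeries")) series <- list(series)
  do.call(rbind, lapply(series, function(s) {
    d <- s@data
    keep <- !d$gap & !is.na(d$depth)
    if (!is.null(phase)) {
      if (all(is.na(d$phase)))
        stop("series ", s@ptt, " has no phase labels; run segmentPhases() ",
             "or pass phase = NULL")
      keep <- keep & !is.na(d$phase) & d$phase == phase
    }
    d <- d[keep, , drop = FALSE]
    lt <- as.POSIXlt(d$timestamp, tz = "UTC")
    data.frame(ptt = s@ptt, hour = lt$hour + lt$min / 60 + lt$sec / 3600,
               depth = d$depth, idx = seq_len(nrow(d)))
  }))
}

#' Fit the cyclic depth-by-hour mixed model
#'
#' Fits depth on hour of day with a penalized cyclic cubic spline (basis
#' dimension k = 5, period 24 h, evenly spaced knots), a per-tag random
#' intercept when more than one tag is supplied, and an AR(1) residual
#' correlation structure at the native sample spacing (continuous samples
#' indexed within tag). Smoothing parameter by REML.
#'
#' @param series one \code{\link{TagSeries}} or a list of them, labelled by
#'   \code{\link{segmentPhases}} when \code{phase} is not NULL.
#' @param phase restrict to this phase (default \code{"oceanic"}); NULL
#'   uses every non-gap sample.
#' @param k cyclic basis dimension, default 5.
#' @param minSamples minimum samples per tag, default 200.
#' @return an \code{\link{HourlyDepthModel}}.
#' @references Wood, S.N. (2017) Generalized Additive Models: An
#'   Introduction with R, 2nd ed. CRC Press.
#' @seealso \code{\link{predictDepthCurve}}
#' @export
fitHourlyDepthModel <- function(series, phase = "oceanic", k = 5,
                                minSamples = 200) {
  df <- .modelFrame(series, phase)
  cnt <- table(df$ptt)
  if (any(cnt < minSamples))
    stop("need at least ", minSamples, " samples per tag; got ",
         paste(names(cnt)[cnt < minSamples], collapse = ", "))
  df$ptt <- factor(df$ptt)
  multiTag <- nlevels(df$ptt) > 1
  if (!multiTag)
    message("single tag: per-tag intercept (Ptt term) dropped")
  knots <- list(hour = seq(0, 24, length.out = k))
  fit <- tryCatch({
    if (multiTag)
      mgcv::gamm(depth ~ s(hour, k = k, bs = "cc"), data = df,
                 knots = knots, random = list(ptt = ~1),
                 correlation = nlme::corAR1(form = ~idx | ptt),
                 method = "REML")
    else
      mgcv::gamm(depth ~ s(hour, k = k, bs = "cc"), data = df,
                 knots = knots,
                 correlation = nlme::corAR1(form = ~idx | ptt),
                 method = "REML")
  }, error = function(e)
    stop("cyclic depth model failed to converge: ", conditionMessage(e)))
  g <- fit$gam
  rho <- as.numeric(coef(fit$lme$modelStruct$corStruct,
                         unconstrained = FALSE))
  stab <- summary(g)$s.table
  grid <- data.frame(hour = seq(0, 24, by = 0.25))
  pr <- predict(g, newdata = grid, se.fit = TRUE)
  new("HourlyDepthModel", fit = fit, rho = rho,
      r2 = cor(fitted(g), df$depth)^2,
      edf = unname(stab[1, "edf"]), pvalue = unname(stab[1, "p-value"]),
      residSD = sqrt(g$sig2), seRange = range(pr$se.fit),
      tags = levels(df$ptt), n = nrow(df))
}

#' Predict the diel depth curve
#'
#' Population-level predicted depth (marginal to any per-tag intercepts)
#' with pointwise standard errors on an hour-of-day grid. The curve is
#' periodic: predictions at 0 h and 24 h coincide.
#'
#' @param model an \code{\link{HourlyDepthModel}}.
#' @param hours numeric grid of hours in [0, 24], default every 15 min.
#' @return data.frame with columns \code{hour}, \code{depth}, \code{se}.
#' @export
predictDepthCurve <- function(model, hours = seq(0, 24, by = 0.25)) {
  stopifnot(is(model, "HourlyDepthModel"))
  pr <- predict(model@fit$gam, newdata = data.frame(hour = hours %% 24),
                se.fit = TRUE)
  data.frame(hour = hours, depth = as.numeric(pr$fit),
             se = as.numeric(pr$se.fit))
}

#' Table-style summary of an hourly depth model
#'
#' One row per fit in the reporting shape used for diel depth GAMMs: tag
#' set, R-squared, effective degrees of freedom, the min-max range of the
#' pointwise standard error of the predicted curve, and the smooth-term
#' p-value.
#'
#' @param model an \code{\link{HourlyDepthModel}}.
#' @return a one-row data.frame.
#' @export
modelScore <- function(model) {
  stopifnot(is(model, "HourlyDepthModel"))
  data.frame(ptt = paste(model@tags, collapse = "+"),
             r2 = model@r2, df = model@edf,
             seMin = model@seRange[1], seMax = model@seRange[2],
             rho = model@rho, p = model@pvalue, n = model@n)
}
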