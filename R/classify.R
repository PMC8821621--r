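# dB-difference classification of echogram cells into functional
# scatterer groups.

#' Default Delta-Sv classification tree
#'
#' The four-group classification of mesopelagic scatterers by the 18-38 kHz
#' dB difference: small swimbladdered/non-swimbladdered fishes and
#' crustaceans (Sm.(N)SB/Crust.) for -14 dB < Delta < -3 dB; large
#' non-swimbladdered fishes (Lrg.NSB) for -3 dB < Delta < 0 dB; fluid-like
#' scatterers - gelatinous zooplankton, cephalopods, pteropods (FL) - for
#' 0 dB < Delta < 3 dB; large swimbladdered fishes (Lrg.SB) for
#' 3 dB < Delta < 12 dB. Intervals are implemented half-open, closed at
#' the upper end: (lower, upper]. Cells with 38-kHz Sv below the gate are
#' left unclassified (noise-floor suppression).
#'
#' @param gate minimum Sv at 38 kHz (dB), default -85.
#' @return list with elements \code{tree} (data.frame \code{class},
#'   \code{lower}, \code{upper}) and \code{gate}.
#' @export
defaultClassificationTree <- function(gate = -85) {
  list(tree = data.frame(
         class = c("Sm.(N)SB/Crust.", "Lrg.NSB", "FL", "Lrg.SB"),
         lower = c(-14, -3, 0, 3), upper = c(-3, 0, 3, 12),
         stringsAsFactors = FALSE),
       gate = gate)
}

#' Classify echogram cells into functional groups
#'
#' Applies a Delta-Sv interval tree to every jointly valid cell: cells
#' whose 38-kHz Sv is below the gate, or whose Delta-Sv falls outside
#' every interval, stay unclassified. Each classified cell carries its
#' linear-domain 38-kHz backscatter as weight.
#'
#' @param delta a \code{quantity = "deltaSv"} \code{\link{Echogram}}.
#' @param sv38 the matching 38-kHz \code{\link{Echogram}}.
#' @param tree a classification tree from
#'   \code{\link{defaultClassificationTree}} (the default).
#' @return a \code{\link{ClassGrid}}.
#' @export
classifyCells <- function(delta, sv38, tree = defaultClassificationTree()) {
  stopifnot(is(delta, "Echogram"), identical(delta@quantity, "deltaSv"),
            is(sv38, "Echogram"))
  if (!isTRUE(all.equal(delta@time, sv38@time)) ||
      !isTRUE(all.equal(delta@depth, sv38@depth)))
    stop("delta and sv38 grids are not aligned")
  dv <- delta@sv
  gv <- sv38@sv
  cls <- matrix(NA_character_, nrow = nrow(dv), ncol = ncol(dv))
  ok <- !is.na(dv) & !is.na(gv) & gv >= tree$gate
  tr <- tree$tree
  for (i in seq_len(nrow(tr))) {
    sel <- ok & dv > tr$lower[i] & dv <= tr$upper[i]
    cls[sel] <- tr$class[i]
  }
  new("ClassGrid", classes = cls, weight = .toLinear(gv),
      time = delta@time, depth = delta@depth, tree = tr)
}
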