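#' @include AllClasses.R
NULL

#' Kept value range after extreme-value exclusion
#'
#' Extreme lab values carried by too few patients give unstable outcome
#' proportions, so a small total fraction of the sample (default 5%) is
#' excluded before profiling — split symmetrically, `fraction/2` per
#' tail, using the linear-interpolation quantile convention. An
#' asymmetric split can be given as a length-2 vector of per-tail
#' fractions.
#'
#' @param values non-empty numeric vector (NAs removed).
#' @param fraction total excluded mass (default 0.05), or `c(low, high)`
#'   per-tail fractions.
#' @return Named numeric `c(low, high)` — the kept range.
#' @export
trimExtremeSupport <- function(values, fraction = 0.05) {
  values <- values[!is.na(values)]
  if (!length(values)) stopf("trimExtremeSupport requires a non-empty sample")
  tails <- if (length(fraction) == 2L) fraction else rep(fraction / 2, 2)
  assertFraction(tails[1], "lower tail fraction")
  assertFraction(tails[2], "upper tail fraction")
  if (sum(tails) >= 1) stopf("cannot exclude the whole sample")
  q <- quantileLinear(values, c(tails[1], 1 - tails[2]))
  c(low = q[1], high = q[2])
}

#' Outcome-group proportions across the lab-value axis
#'
#' Bins the kept range of a lab feature into `nBins` equal-width bins
#' (right-closed final bin; lowest edge included) and tallies, per bin,
#' the counts and relative proportions of the five outcome groups — the
#' data behind stacked outcome-probability charts. Empty bins are
#' reported with zero counts and `NA` proportions so bin edges stay
#' stable across analytes.
#'
#' @param values per-stay worst values (NAs allowed and dropped).
#' @param groups outcome group per stay, aligned with `values`; factor
#'   with levels [outcomeLevels()] (or coercible).
#' @param nBins number of bins, at least 2 (default 20).
#' @param trimFraction total excluded extreme mass (see
#'   [trimExtremeSupport()]).
#' @param testId,direction labels carried into the result.
#' @return An [OutcomeProfile].
#' @export
outcomeProportions <- function(values, groups, nBins = 20,
                               trimFraction = 0.05, testId = "",
                               direction = "") {
  if (!isScalarNumber(nBins) || nBins < 2) stopf("nBins must be at least 2")
  nBins <- as.integer(nBins)
  if (length(values) != length(groups))
    stopf("values and groups must be aligned")
  groups <- factor(as.character(groups), levels = outcomeLevels())
  keep <- !is.na(values)
  if (any(is.na(groups[keep])))
    stopf("every stay with a value must have an outcome group")
  values <- values[keep]; groups <- groups[keep]
  if (!length(values)) stopf("no non-missing values to profile")
  kept <- trimExtremeSupport(values, trimFraction)
  if (kept[1] == kept[2]) {          # degenerate: all mass at one point
    pad <- max(abs(kept[1]), 1) * 1e-8
    kept <- c(kept[1] - pad, kept[2] + pad)
  }
  inRange <- values >= kept[1] & values <= kept[2]
  values <- values[inRange]; groups <- groups[inRange]
  edges <- seq(kept[1], kept[2], length.out = nBins + 1L)
  bin <- cut(values, breaks = edges, include.lowest = TRUE, right = TRUE)
  counts <- unclass(table(bin, groups))
  dimnames(counts) <- list(bin = levels(bin), group = outcomeLevels())
  storage.mode(counts) <- "integer"
  tot <- rowSums(counts)
  props <- counts / ifelse(tot > 0, tot, NA_real_)
  new("OutcomeProfile", testId = as.character(testId),
      direction = as.character(direction), binEdges = edges,
      counts = counts, proportions = props,
      keptRange = unname(c(kept[1], kept[2])))
}

#' Flatten an outcome profile to a long data frame
#'
#' @param profile an [OutcomeProfile].
#' @return `data.frame` with one row per (bin, group): bin edges, count
#'   and proportion.
#' @export
profileToDataFrame <- function(profile) {
  stopifnot(is(profile, "OutcomeProfile"))
  nb <- nrow(profile@counts)
  data.frame(
    test_id = profile@testId, direction = profile@direction,
    bin = rep(seq_len(nb), times = 5L),
    bin_lower = rep(profile@binEdges[-(nb + 1L)], times = 5L),
    bin_upper = rep(profile@binEdges[-1L], times = 5L),
    group = rep(outcomeLevels(), each = nb),
    count = as.vector(profile@counts),
    proportion = as.vector(profile@proportions),
    stringsAsFactors = FALSE)
}

#' Stacked outcome-proportion chart
#'
#' Base-graphics stacked bar rendering of an [OutcomeProfile]: within
#' each lab-value bin the bar is split by the relative proportion of the
#' five outcome groups, best (light) to worst (dark).
#'
#' @param x an [OutcomeProfile].
#' @param y ignored.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
setMethod("plot", signature("OutcomeProfile", "missing"), function(x, y, ...) {
  props <- t(x@proportions)
  props[is.na(props)] <- 0
  cols <- grDevices::gray(c(0.9, 0.75, 0.6, 0.4, 0.15))
  mids <- (x@binEdges[-1] + x@binEdges[-length(x@binEdges)]) / 2
  bp <- graphics::barplot(props, col = cols, border = NA, space = 0,
                          names.arg = sprintf("%.3g", mids), las = 2,
                          ylab = "proportion of outcome group",
                          xlab = sprintf("%s (%s)", x@testId, x@direction),
                          ...)
  graphics::legend("topright", rev(outcomeLevels()), fill = rev(cols),
                   bty = "n", cex = 0.8)
  invisible(bp)
})
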