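#' @include AllGenerics.R
NULL

#' Ordered outcome-group levels
#'
#' The five-level outcome stratification: ICU survivors split into
#' length-of-stay quartiles (`Q1_BEST` = shortest stay = best outcome,
#' through `Q4`) and ICU non-survivors (`DIED_WORST`).
#'
#' @return Character vector of the five level names, best to worst.
#' @export
outcomeLevels <- function() c("Q1_BEST", "Q2", "Q3", "Q4", "DIED_WORST")

# ---------------------------------------------------------------- DensityEstimate

#' Kernel density estimate on a fixed grid
#'
#' Container for a Gaussian-kernel density estimate evaluated on an evenly
#' spaced grid and renormalized to integrate to 1 (trapezoid rule). Created
#' by [estimateDensity()]; consumed by [overlapCoefficient()].
#'
#' @slot grid strictly increasing numeric vector of evaluation points
#'   (test units).
#' @slot density non-negative numeric vector, same length as `grid`.
#' @slot bw the bandwidth used (test units).
#' @slot n the sample size behind the estimate.
#' @aliases densityGrid densityValues bandwidth
#' @export
setClass("DensityEstimate",
  representation(grid = "numeric", density = "numeric",
                 bw = "numeric", n = "integer"))

setValidity("DensityEstimate", function(object) {
  msg <- character()
  if (length(object@grid) != length(object@density))
    msg <- c(msg, "grid and density lengths differ")
  if (length(object@grid) >= 2L && any(diff(object@grid) <= 0))
    msg <- c(msg, "grid must be strictly increasing")
  if (any(object@density < 0))
    msg <- c(msg, "density must be non-negative")
  if (length(object@bw) != 1L || !is.finite(object@bw) || object@bw <= 0)
    msg <- c(msg, "bw must be a single positive number")
  if (length(object@grid) >= 2L) {
    area <- trapezoid(object@grid, object@density)
    if (area < 0.999 || area > 1.001)
      msg <- c(msg, sprintf("density integrates to %.6f, not 1", area))
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("densityGrid", "DensityEstimate", function(x) x@grid)
#' @export
setMethod("densityValues", "DensityEstimate", function(x) x@density)
#' @export
setMethod("bandwidth", "DensityEstimate", function(x) x@bw)

setMethod("show", "DensityEstimate", function(object) {
  cat(sprintf(
    "DensityEstimate: %d grid points on [%.4g, %.4g], bw = %.4g, n = %d\n",
    length(object@grid), min(object@grid), max(object@grid),
    object@bw, object@n))
})

# ----------------------------------------------------------- ReferenceDistribution

#' Parametric instantiation of a hospital reference interval
#'
#' A hospital reference interval is, by convention, the central 95% of a
#' healthy reference population. To compare ICU value distributions against
#' it with density-based statistics, the interval is instantiated as a
#' parametric distribution whose central 95% reproduces the interval bounds
#' exactly: by default a normal with `mean = (lower+upper)/2` and
#' `sd = (upper-lower)/(2 * qnorm(0.975))`. A log-normal family is available
#' for strictly positive analytes (the same mapping applied to
#' `log(lower), log(upper)`).
#'
#' For normal-family analytes whose instantiation would put visible mass
#' below zero (`lower - 3*sd < 0`), the evaluated density is truncated at
#' zero and renormalized; the reported mean and quantiles remain those of
#' the untruncated normal (the truncated mass is negligible whenever the
#' flag triggers on a real reference interval).
#'
#' @slot family `"normal"` or `"lognormal"`.
#' @slot location,scale parameters on the family's latent scale
#'   (`meanlog`/`sdlog` for log-normal).
#' @slot lower,upper the reference interval bounds (test units).
#' @slot zCoverage the standard-normal quantile used by the mapping
#'   (`qnorm(0.975)`, approx. 1.959964).
#' @slot truncateAtZero whether density evaluation truncates at zero.
#' @aliases referenceMean referenceSd referenceQuantile
#' @seealso [intervalToDistribution()], [sampleReference()]
#' @export
setClass("ReferenceDistribution",
  representation(family = "character", location = "numeric",
                 scale = "numeric", lower = "numeric", upper = "numeric",
                 zCoverage = "numeric", truncateAtZero = "logical"))

setValidity("ReferenceDistribution", function(object) {
  msg <- character()
  if (!object@family %in% c("normal", "lognormal"))
    msg <- c(msg, "family must be 'normal' or 'lognormal'")
  if (!is.finite(object@scale) || object@scale <= 0)
    msg <- c(msg, "scale must be positive")
  if (!is.finite(object@lower) || !is.finite(object@upper) ||
      object@lower >= object@upper)
    msg <- c(msg, "lower must be < upper")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("referenceMean", "ReferenceDistribution", function(dist) {
  if (dist@family == "normal") dist@location else exp(dist@location)
})

#' @export
setMethod("referenceSd", "ReferenceDistribution", function(dist) {
  if (dist@family == "normal") dist@scale
  else sqrt((exp(dist@scale^2) - 1)) * exp(dist@location + dist@scale^2 / 2)
})

#' @export
setMethod("referenceQuantile", "ReferenceDistribution", function(dist, p) {
  if (dist@family == "normal") qnorm(p, dist@location, dist@scale)
  else exp(qnorm(p, dist@location, dist@scale))
})

setMethod("show", "ReferenceDistribution", function(object) {
  cat(sprintf(
    "ReferenceDistribution (%s): interval [%.4g, %.4g] -> location %.6g, scale %.6g%s\n",
    object@family, object@lower, object@upper, object@location, object@scale,
    if (object@truncateAtZero) " (density truncated at 0)" else ""))
})

# --------------------------------------------------------------------- IcuCohort

#' Cohort of first ICU stays with worst first-day lab values
#'
#' An `IcuCohort` extends [SummarizedExperiment::SummarizedExperiment]:
#' rows are lab features — one per (test, direction) pair, e.g.
#' `albumin_min` — and columns are included first ICU stays. The `"worst"`
#' assay holds the worst first-day value for each feature and stay (`NA`
#' when the test was never measured in the window). `colData` carries the
#' stay-level covariates and the five-level `outcome` factor; `rowData`
#' carries test id, direction, units and the hospital reference interval.
#'
#' Created by [buildCohort()]; consumed by [divergenceTable()],
#' [summarizeBestWorst()] and [outcomeProportions()].
#'
#' @aliases outcomeGroups worstValues
#' @export
setClass("IcuCohort", contains = "SummarizedExperiment")

setValidity("IcuCohort", function(object) {
  msg <- character()
  if (!"worst" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'worst' is required")
  cd <- SummarizedExperiment::colData(object)
  for (col in c("outcome", "los_days", "icu_death"))
    if (!col %in% colnames(cd)) msg <- c(msg, sprintf("colData lacks '%s'", col))
  if ("outcome" %in% colnames(cd) &&
      !identical(levels(cd$outcome), outcomeLevels()))
    msg <- c(msg, "outcome levels must equal outcomeLevels()")
  rd <- SummarizedExperiment::rowData(object)
  for (col in c("test_id", "direction"))
    if (!col %in% colnames(rd)) msg <- c(msg, sprintf("rowData lacks '%s'", col))
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("outcomeGroups", "IcuCohort", function(x)
  setNames(SummarizedExperiment::colData(x)$outcome, colnames(x)))

#' @export
setMethod("worstValues", "IcuCohort", function(x)
  SummarizedExperiment::assay(x, "worst"))

setMethod("show", "IcuCohort", function(object) {
  methods::callNextMethod()
  tab <- table(SummarizedExperiment::colData(object)$outcome)
  cat("outcome groups:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

# ----------------------------------------------------------------- OutcomeProfile

#' Outcome-group proportion profile across a lab-value axis
#'
#' The stacked-chart summary: the kept (central) range of a lab feature is
#' cut into equal-width bins and, within each bin, the relative proportions
#' of the five outcome groups are tallied. Bins with zero count are kept
#' (stable edges across analytes) with zero counts and `NA` proportions.
#'
#' @slot testId,direction which lab feature the profile describes.
#' @slot binEdges strictly increasing numeric vector, length bins + 1.
#' @slot counts integer matrix, bins x 5 outcome groups.
#' @slot proportions numeric matrix, rows summing to 1 (or `NA` for empty
#'   bins).
#' @slot keptRange the (low, high) value range kept after extreme-value
#'   exclusion.
#' @aliases binEdges binCounts binProportions keptRange
#' @seealso [outcomeProportions()], [trimExtremeSupport()]
#' @export
setClass("OutcomeProfile",
  representation(testId = "character", direction = "character",
                 binEdges = "numeric", counts = "matrix",
                 proportions = "matrix", keptRange = "numeric"))

setValidity("OutcomeProfile", function(object) {
  msg <- character()
  nb <- length(object@binEdges) - 1L
  if (nb < 1L || any(diff(object@binEdges) <= 0))
    msg <- c(msg, "binEdges must be strictly increasing with >= 2 entries")
  if (nrow(object@counts) != nb || ncol(object@counts) != 5L)
    msg <- c(msg, "counts must be bins x 5")
  if (!identical(dim(object@counts), dim(object@proportions)))
    msg <- c(msg, "counts and proportions dimensions differ")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  tot <- rowSums(object@counts)
  ps <- rowSums(object@proportions)
  bad <- tot > 0 & (is.na(ps) | abs(ps - 1) > 1e-9)
  if (any(bad)) msg <- c(msg, "non-empty bin proportions must sum to 1")
  if (length(object@keptRange) != 2L || object@keptRange[1] > object@keptRange[2])
    msg <- c(msg, "keptRange must be an ordered pair")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("binEdges", "OutcomeProfile", function(x) x@binEdges)
#' @export
setMethod("binCounts", "OutcomeProfile", function(x) x@counts)
#' @export
setMethod("binProportions", "OutcomeProfile", function(x) x@proportions)
#' @export
setMethod("keptRange", "OutcomeProfile", function(x) x@keptRange)

setMethod("show", "OutcomeProfile", function(object) {
  cat(sprintf(
    "OutcomeProfile %s (%s): %d bins on [%.4g, %.4g], %d stays\n",
    object@testId, object@direction, nrow(object@counts),
    object@keptRange[1], object@keptRange[2], sum(object@counts)))
})
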