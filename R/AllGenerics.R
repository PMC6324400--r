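#' @include utils.R
NULL

#' Overlapping coefficient between two distributions
#'
#' The overlapping coefficient (OVL) is the integral of the pointwise minimum
#' of two probability densities: 0 means the distributions share no mass,
#' 1 means they are identical. Methods are provided for every pairing of a
#' kernel density estimate ([DensityEstimate]) and an analytic
#' [ReferenceDistribution]; mixed pairings evaluate the analytic density
#' exactly on the union grid so no Monte-Carlo noise enters from the
#' reference side.
#'
#' @param d1,d2 `DensityEstimate` or `ReferenceDistribution` objects.
#' @return A single number in `[0, 1]`.
#' @seealso [estimateDensity()], [analyticNormalOvl()]
#' @examples
#' x <- estimateDensity(rnorm(2000))
#' overlapCoefficient(x, x)  # 1 up to integration tolerance
#' @export
setGeneric("overlapCoefficient", function(d1, d2)
  standardGeneric("overlapCoefficient"))

#' @rdname DensityEstimate-class
#' @param x a `DensityEstimate`.
#' @export
setGeneric("densityGrid", function(x) standardGeneric("densityGrid"))

#' @rdname DensityEstimate-class
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))

#' @rdname DensityEstimate-class
#' @export
setGeneric("bandwidth", function(x) standardGeneric("bandwidth"))

#' @rdname ReferenceDistribution-class
#' @param dist a `ReferenceDistribution`.
#' @export
setGeneric("referenceMean", function(dist) standardGeneric("referenceMean"))

#' @rdname ReferenceDistribution-class
#' @export
setGeneric("referenceSd", function(dist) standardGeneric("referenceSd"))

#' @rdname ReferenceDistribution-class
#' @param p probabilities.
#' @export
setGeneric("referenceQuantile", function(dist, p)
  standardGeneric("referenceQuantile"))

#' @rdname IcuCohort-class
#' @param x an `IcuCohort`.
#' @export
setGeneric("outcomeGroups", function(x) standardGeneric("outcomeGroups"))

#' @rdname IcuCohort-class
#' @export
setGeneric("worstValues", function(x) standardGeneric("worstValues"))

#' @rdname OutcomeProfile-class
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname OutcomeProfile-class
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @rdname OutcomeProfile-class
#' @export
setGeneric("binProportions", function(x) standardGeneric("binProportions"))

#' @rdname OutcomeProfile-class
#' @export
setGeneric("keptRange", function(x) standardGeneric("keptRange"))
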