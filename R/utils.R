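#' @importFrom stats quantile dnorm pnorm qnorm rnorm rlnorm rbinom rpois runif
#'   median wilcox.test kruskal.test chisq.test sd setNames density
#' @importFrom methods new validObject is slot
#' @importFrom utils write.csv read.csv head
NULL

# Linear-interpolation quantile at position 1 + p*(n-1) over the order
# statistics; identical to stats::quantile type 7, kept as a named wrapper so
# the convention is explicit at every call site.
quantileLinear <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}

# Trapezoidal integral of y over (sorted, strictly increasing) x.
trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Deterministic 31-bit polynomial string hash (no digest package available;
# only used to derive RNG substreams and the run-manifest config hash).
# Arithmetic in doubles stays exact: intermediate values < 2^53.
stringHash31 <- function(s) {
  h <- 17
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Substream seed derived from (seed, id): adding an analyte never perturbs
# the draws of another.
deriveSeed <- function(seed, id) {
  stringHash31(paste(seed, id, sep = "\r"))
}

# Evaluate with a temporary RNG state; restores .Random.seed afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assertFraction <- function(x, what) {
  if (!isScalarNumber(x) || x < 0 || x > 1)
    stopf("%s must be a single number in [0, 1], got %s", what,
          paste(format(x), collapse = ", "))
  invisible(x)
}
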