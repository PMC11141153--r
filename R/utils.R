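#' Derive a stage-specific random seed from a global seed
#'
#' Stage seeds are obtained by mixing the global seed with a stable integer
#' hash of the stage name, so a stage re-run in isolation reproduces the
#' full-pipeline run exactly. The result always lies in \code{[0, 2^31 - 1)}.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return A single integer seed.
#' @examples
#' deriveSeed(1, "simulate")
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(stage) == 1L)
  h <- 0
  for (k in utf8ToInt(as.character(stage)))
    h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

# Intercept a of plogis(a - z) such that mean missing probability over the
# observed log2 intensities z equals the requested rate.
.calibrateLogisticIntercept <- function(z, rate) {
  f <- function(a) mean(stats::plogis(a - z)) - rate
  lo <- min(z) - 50; hi <- max(z) + 50
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

.checkProportion <- function(x, name, allowOne = TRUE) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1 ||
      (!allowOne && x == 1))
    stop(sprintf("%s must be a proportion in [0, 1%s", name,
                 if (allowOne) "]" else ")"))
  invisible(x)
}
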