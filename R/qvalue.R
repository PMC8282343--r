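#' Storey q-values
#'
#' False-discovery-rate adjusted significance with an estimate of the
#' null proportion pi0. pi0 is estimated on the lambda grid as
#' \code{mean(p > lambda) / (1 - lambda)}, smoothed with a cubic
#' smoothing spline and read off at the largest lambda, then clipped to
#' (0, 1]. With \code{pi0 = 1} the q-values reduce exactly to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param p p-values in [0, 1].
#' @param lambdaGrid grid for pi0 estimation.
#' @param pi0 optional fixed null proportion; \code{NULL} estimates it.
#' @return q-values, with the estimate attached as \code{attr(, "pi0")}.
#' @examples
#' p <- c(0.001, 0.01, 0.5, 0.8)
#' storeyQvalue(p, pi0 = 1)          # equals p.adjust(p, "BH")
#' @export
storeyQvalue <- function(p, lambdaGrid = seq(0.05, 0.95, by = 0.05),
                         pi0 = NULL) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- tryCatch({
      pi0l <- vapply(lambdaGrid, function(l) mean(p > l) / (1 - l),
                     numeric(1))
      fit <- smooth.spline(lambdaGrid, pi0l, df = 3)
      predict(fit, x = max(lambdaGrid))$y
    }, error = function(e) 1)
    if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1
    pi0 <- min(pi0, 1)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o]))[ro]
  attr(q, "pi0") <- pi0
  q
}
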