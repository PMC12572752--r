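#' Six-moment summary of a numeric series
#'
#' Computes the six per-series statistics used throughout the feature set:
#' mean, standard deviation, skewness, kurtosis, minimum and maximum.
#' Skewness is the adjusted Fisher-Pearson sample form
#' \eqn{G_1 = g_1 \sqrt{n(n-1)}/(n-2)} and kurtosis the adjusted sample
#' excess kurtosis \eqn{G_2}; both are defined as 0 when the series has zero
#' variance or too few observations for the adjustment (n < 3 for skewness,
#' n < 4 for kurtosis).
#'
#' @param x numeric vector with at least one finite value.
#' @return named numeric vector with elements `mean`, `sd`, `skewness`,
#'   `kurtosis`, `min`, `max`.
#' @examples
#' summary_stats(c(2, 2, 2))   # sd 0, skewness and kurtosis 0 by policy
#' @export
summary_stats <- function(x) {
  stopifnot(is.numeric(x))
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) {
    return(c(mean = NA_real_, sd = NA_real_, skewness = NA_real_,
             kurtosis = NA_real_, min = NA_real_, max = NA_real_))
  }
  m <- mean(x)
  s <- if (n >= 2L) stats::sd(x) else 0
  if (!is.finite(s)) s <- 0
  skew <- 0
  kurt <- 0
  if (s > 0) {
    m2 <- mean((x - m)^2)
    m3 <- mean((x - m)^3)
    m4 <- mean((x - m)^4)
    g1 <- m3 / m2^1.5
    g2 <- m4 / m2^2 - 3
    if (n >= 3L) skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
    if (n >= 4L) kurt <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  }
  c(mean = m, sd = s, skewness = skew, kurtosis = kurt,
    min = min(x), max = max(x))
}
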