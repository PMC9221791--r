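intensity_feature_names <- c(
  "hist_mean", "hist_std", "hist_min", "hist_max", "hist_skewness",
  "hist_kurtosis", "hist_entropy",
  "hist_p05", "hist_p25", "hist_p50", "hist_p75", "hist_p95"
)

#' First-order intensity features of a gray-level region
#'
#' Seven histogram statistics (mean, SD, min, max, skewness, kurtosis,
#' Shannon entropy of the 256-bin gray histogram in bits) and five
#' percentiles (5/25/50/75/95, linear interpolation). Moments are
#' population moments; skewness and kurtosis of a constant region are 0 by
#' convention; kurtosis is the plain fourth standardized moment (not
#' excess).
#'
#' @param gray_values numeric vector of gray levels in \[0, 255\] from one
#'   region.
#' @return named numeric vector of length 12.
#' @export
intensity_features <- function(gray_values) {
  if (length(gray_values) == 0) {
    out <- rep(NA_real_, 12L)
    names(out) <- intensity_feature_names
    attr(out, "missing") <- TRUE
    return(out)
  }
  g <- as.numeric(gray_values)
  n <- length(g)
  m <- mean(g)
  s2 <- mean((g - m)^2)
  s <- sqrt(s2)
  skew <- if (s > 0) mean((g - m)^3) / s^3 else 0
  kurt <- if (s > 0) mean((g - m)^4) / s2^2 else 0
  h <- tabulate(floor(g) + 1L, nbins = 256L) / n
  h <- h[h > 0]
  ent <- -sum(h * log2(h))
  q <- stats::quantile(g, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE,
                       type = 7)
  out <- c(m, s, min(g), max(g), skew, kurt, ent, q)
  names(out) <- intensity_feature_names
  attr(out, "missing") <- FALSE
  out
}
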