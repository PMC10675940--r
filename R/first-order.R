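# First-order (histogram) intensity statistics: the standard 18-feature set.

#' First-order intensity features (18)
#'
#' Computed from the raw in-mask intensities; entropy and uniformity use the
#' discretized gray-level histogram. Percentile-based features use linear
#' quantile interpolation. Skewness and kurtosis are the population moment
#' ratios (kurtosis is non-excess: a normal sample gives ~3); both are 0 for
#' a constant ROI.
#'
#' @param droi A [discretize()]d ROI.
#' @return Named numeric vector of 18 features.
#' @export
first_order <- function(droi) {
  x <- droi$intensities
  n <- length(x)
  vox_vol <- prod(droi$spacing)
  p <- tabulate(droi$levels[droi$mask], nbins = droi$ng) / n
  pnz <- p[p > 0]
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  robust <- x[x >= q[1] & x <= q[5]]
  c(energy = sum(x^2),
    total_energy = vox_vol * sum(x^2),
    entropy = -sum(pnz * log2(pnz)),
    minimum = min(x),
    p10 = q[1],
    p90 = q[5],
    maximum = max(x),
    mean = mu,
    median = q[3],
    iqr = q[4] - q[2],
    range = max(x) - min(x),
    mad = mean(abs(x - mu)),
    rmad = if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    rms = sqrt(mean(x^2)),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    variance = m2,
    uniformity = sum(p^2))
}
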