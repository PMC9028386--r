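#' First-order (intensity histogram) features
#'
#' Statistics of the raw in-mask intensity distribution plus
#' discretised-histogram descriptors. Moments are population moments
#' (divide by N); skewness and kurtosis (excess) are undefined on a
#' zero-variance ROI and reported as missing rather than NaN. Percentiles
#' use the type-7 quantile definition. `stat.dp90` is the 90th percentile
#' of the discretised grey levels; entropy (log2) and uniformity are
#' computed on the discretised histogram.
#'
#' @param volume an [image_volume()].
#' @param mask an aligned non-empty [lesion_mask()].
#' @param discretized a [discretize_roi()] result for the same pair;
#'   computed on the fly if omitted.
#' @return Named numeric vector with keys prefixed `stat.`.
#' @export
first_order_features <- function(volume, mask, discretized = NULL) {
  check_aligned(volume, mask)
  if (is.null(discretized)) discretized <- discretize_roi(volume, mask)
  x <- volume$values[mask$values == 1L]
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2)                  # population variance
  qs <- quantile(x, c(.1, .25, .5, .75, .9), names = FALSE, type = 7)
  if (v > 0) {
    skew <- mean((x - mu)^3) / v^1.5
    kurt <- mean((x - mu)^4) / v^2 - 3
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  lev <- discretized$levels[mask$values == 1L]
  p <- tabulate(lev, nbins = discretized$n_bins) / n
  pp <- p[p > 0]
  c(stat.mean = mu,
    stat.variance = v,
    stat.skewness = skew,
    stat.kurtosis = kurt,
    stat.median = qs[3],
    stat.min = min(x),
    stat.max = max(x),
    stat.range = max(x) - min(x),
    stat.p10 = qs[1], stat.p25 = qs[2], stat.p75 = qs[4], stat.p90 = qs[5],
    stat.iqr = qs[4] - qs[2],
    stat.energy = sum(x^2),
    stat.rms = sqrt(mean(x^2)),
    stat.mad = mean(abs(x - mu)),
    stat.cov = if (abs(mu) > 0) sqrt(v) / mu else NA_real_,
    stat.entropy = -sum(pp * log2(pp)),
    stat.uniformity = sum(p^2),
    stat.dp90 = quantile(as.numeric(lev), 0.9, names = FALSE, type = 7))
}

#' Intensity-volume histogram features
#'
#' `ivh.v10` / `ivh.v90` are the fractions of ROI volume with intensity
#' at or above 10% / 90% of the ROI maximum (the dose-volume-histogram
#' style convention); `ivh.i10` / `ivh.i90` are the intensities of the
#' hottest 10% / 90% of the volume (descending-rank quantile). The two
#' differences `v10 - v90` and `i10 - i90` summarise histogram spread.
#' A constant ROI gives all volume fractions 1 and zero differences.
#'
#' @inheritParams first_order_features
#' @return Named numeric vector with keys prefixed `ivh.`.
#' @export
ivh_features <- function(volume, mask) {
  check_aligned(volume, mask)
  x <- volume$values[mask$values == 1L]
  n <- length(x)
  xmax <- max(x)
  vfrac <- function(f) mean(x >= f * xmax)
  # intensity reached by the top `f` fraction of voxels
  ifrac <- function(f) sort(x, decreasing = TRUE)[max(1L, ceiling(f * n))]
  v10 <- vfrac(0.10); v90 <- vfrac(0.90)
  i10 <- ifrac(0.10); i90 <- ifrac(0.90)
  c(ivh.v10 = v10, ivh.v90 = v90, ivh.v10_minus_v90 = v10 - v90,
    ivh.i10 = i10, ivh.i90 = i90, ivh.i10_minus_i90 = i10 - i90)
}
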