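#' The documented feature battery
#'
#' Fixed, ordered registry of every feature the extractor emits, by
#' family. [extract_all()] always returns exactly these keys in this
#' order; degenerate features are `NA` (explicit missing marker), never
#' silently dropped.
#'
#' @return Data frame with columns `feature` (namespaced key) and
#'   `family`.
#' @export
feature_registry <- function() {
  fams <- list(
    stat = c("mean", "variance", "skewness", "kurtosis", "median", "min",
             "max", "range", "p10", "p25", "p75", "p90", "iqr", "energy",
             "rms", "mad", "cov", "entropy", "uniformity", "dp90"),
    ivh = c("v10", "v90", "v10_minus_v90", "i10", "i90", "i10_minus_i90"),
    morph = c("volume", "surface_area", "sphericity", "compactness1",
              "compactness2", "elongation", "flatness",
              "inverse_elongation", "area_density_aabb",
              "volume_density_aabb"),
    glcm = c("joint_maximum", "joint_average", "joint_variance",
             "joint_entropy", "contrast", "dissimilarity",
             "inverse_difference", "inverse_difference_norm",
             "inverse_difference_moment", "inverse_variance",
             "correlation", "autocorrelation", "energy", "info_corr1",
             "info_corr2"),
    glrlm = c("sre", "lre", "glnu", "rlnu", "run_pct", "lglre", "hglre",
              "srlge", "lrhge"),
    glszm = c("sze", "lze", "glnu", "zsnu", "zone_pct", "lglze", "hglze",
              "lzlge", "szhge"),
    gldzm = c("sde", "lde", "zdnu", "zdnu_norm", "lgze", "hgze"))
  data.frame(
    feature = unlist(lapply(names(fams),
                            function(f) paste0(f, ".", fams[[f]])),
                     use.names = FALSE),
    family = rep(names(fams), lengths(fams)))
}

#' Extract the full feature battery from one volume/mask pair
#'
#' Runs all feature families (first-order, intensity-volume histogram,
#' morphology, GLCM, GLRLM, GLSZM, GLDZM) on a lesion. The result always
#' has the exact key set of [feature_registry()], in registry order;
#' any family-level failure or degenerate definition yields `NA` for the
#' affected keys rather than an error.
#'
#' @param volume an [image_volume()] on the analysis grid.
#' @param mask an aligned non-empty [lesion_mask()].
#' @param n_bins grey levels for discretisation (default 32).
#' @return Named numeric vector, one element per registry feature.
#' @export
extract_all <- function(volume, mask, n_bins = 32) {
  check_aligned(volume, mask)
  reg <- feature_registry()
  out <- setNames(rep(NA_real_, nrow(reg)), reg$feature)
  if (mask$degenerate) return(out)
  disc <- discretize_roi(volume, mask, n_bins)
  parts <- list(
    function() first_order_features(volume, mask, disc),
    function() ivh_features(volume, mask),
    function() morphology_features(mask),
    function() glcm_features(disc),
    function() glrlm_features(disc),
    function() glszm_features(disc),
    function() gldzm_features(disc))
  for (f in parts) {
    v <- tryCatch(f(), error = function(e) NULL)
    if (!is.null(v)) {
      keep <- intersect(names(v), reg$feature)
      out[keep] <- v[keep]
    }
  }
  out
}
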