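#' Grey-level quantisation of a region of interest
#'
#' Fixed-bin-number discretisation between the minimum and maximum
#' intensity inside the ROI:
#' `level = min(floor(n_bins * (x - min) / (max - min)) + 1, n_bins)`,
#' so levels run 1..n_bins, the ROI maximum falls in the top bin, and a
#' constant ROI maps entirely to level 1. Out-of-mask voxels carry the
#' sentinel 0.
#'
#' @param volume an [image_volume()].
#' @param mask an aligned non-empty [lesion_mask()].
#' @param n_bins number of grey levels (default 32).
#' @return An object of class `discretized_roi`: integer array `levels`
#'   (0 outside the mask), plus `n_bins`, `roi_min`, `roi_max`.
#' @export
discretize_roi <- function(volume, mask, n_bins = 32) {
  check_aligned(volume, mask)
  if (mask$degenerate) stop("cannot discretize a degenerate (empty) mask")
  stopifnot(n_bins >= 1)
  inm <- mask$values == 1L
  x <- volume$values[inm]
  rmin <- min(x); rmax <- max(x)
  lev <- array(0L, dim(volume$values))
  if (rmax > rmin) {
    lev[inm] <- pmin(as.integer(floor(n_bins * (x - rmin) /
                                        (rmax - rmin))) + 1L,
                     as.integer(n_bins))
  } else {
    lev[inm] <- 1L
  }
  structure(list(levels = lev, n_bins = as.integer(n_bins),
                 roi_min = rmin, roi_max = rmax),
            class = "discretized_roi")
}

check_aligned <- function(volume, mask) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "lesion_mask"))
  if (!all(dim(volume$values) == dim(mask$values))) {
    stop("volume and mask grids differ: ",
         paste(dim(volume$values), collapse = "x"), " vs ",
         paste(dim(mask$values), collapse = "x"))
  }
  if (max(abs(volume$spacing - mask$spacing)) > 1e-9) {
    stop("volume and mask spacing differ")
  }
  invisible(TRUE)
}
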