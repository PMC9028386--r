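#' Isotropic contour perturbation of a lesion mask
#'
#' Expansion by `d` mm includes every voxel whose centre lies within
#' Euclidean distance `d` of some voxel centre of the original mask;
#' contraction by `d` keeps the voxels whose centre is at distance
#' greater than `d` from every background voxel centre (signed-distance
#' thresholding). On the grid this is exactly morphological
#' dilation/erosion with the discrete Euclidean ball of radius `d`,
#' which is how it is implemented; non-integer radii are supported.
#'
#' A contraction that removes every voxel returns a mask flagged
#' `degenerate`; downstream stages drop such variants rather than fail,
#' mirroring the exclusion of over-aggressive contractions on small
#' lesions.
#'
#' @param mask a non-empty [lesion_mask()].
#' @param delta_mm signed perturbation in mm: positive expands, negative
#'   contracts, 0 returns the mask with only the variant tag changed.
#' @param variant variant tag for the result; defaults to a tag derived
#'   from `delta_mm` (`"minus1"`, `"plus1"`, ...).
#' @return A [lesion_mask()] tagged with the variant.
#' @export
perturb_mask <- function(mask, delta_mm, variant = NULL) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (mask$degenerate) stop("cannot perturb a degenerate (empty) mask")
  if (is.null(variant)) {
    variant <- if (delta_mm == 0) "orig" else
      paste0(if (delta_mm > 0) "plus" else "minus",
             sub("\\.", "p", format(abs(delta_mm))))
  }
  if (delta_mm == 0) {
    out <- mask
    out$variant <- variant
    return(out)
  }
  vals <- ball_morph(mask$values, mask$spacing, abs(delta_mm),
                     dilate = delta_mm > 0)
  lesion_mask(vals, mask$spacing, mask$origin, mask$patient_id,
              mask$lesion_id, mask$modality, variant, allow_empty = TRUE)
}

# Integer offsets whose physical displacement is within radius_mm.
ball_offsets <- function(spacing, radius_mm) {
  r <- floor(radius_mm / spacing)
  g <- expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3])
  d2 <- (g$i * spacing[1])^2 + (g$j * spacing[2])^2 + (g$k * spacing[3])^2
  as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

# Dilation / erosion with a Euclidean-ball structuring element, computed
# on the padded bounding box only. Outside the grid counts as background,
# so erosion eats inward from the image border too.
ball_morph <- function(values, spacing, radius_mm, dilate) {
  off <- ball_offsets(spacing, radius_mm)
  m <- max(abs(off))
  d <- dim(values)
  idx <- which(values != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(array(0L, d))
  lo <- pmax(apply(idx, 2, min) - m, 1L)
  hi <- pmin(apply(idx, 2, max) + m, d)
  sub <- values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ds <- dim(sub)
  pad <- array(0L, ds + 2L * m)
  pad[m + 1:ds[1], m + 1:ds[2], m + 1:ds[3]] <- sub
  acc <- if (dilate) array(0L, ds) else array(1L, ds)
  for (r in seq_len(nrow(off))) {
    o <- off[r, ]
    shp <- pad[m + o[1] + 1:ds[1], m + o[2] + 1:ds[2], m + o[3] + 1:ds[3],
               drop = FALSE]
    acc <- if (dilate) pmax(acc, shp) else pmin(acc, shp)
  }
  out <- array(0L, d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- acc
  # dilation may not overflow the padded bounding box by construction,
  # but it can hit the image border: clip is implicit since we never
  # index outside `out`.
  out
}

#' Contour-variant family of a lesion mask
#'
#' Produces the four stability-analysis variants: contraction by 1 mm,
#' the original contour, and expansions by 1 and 2 mm. A 2 mm
#' contraction is deliberately not offered: on small lesions it
#' routinely empties the mask and would fail feature extraction.
#'
#' @param mask a non-empty [lesion_mask()] (1 mm grid expected).
#' @return Named list `minus1`, `orig`, `plus1`, `plus2` of
#'   [lesion_mask()] objects; `minus1` may be flagged `degenerate`.
#' @export
variant_family <- function(mask) {
  list(minus1 = perturb_mask(mask, -1, "minus1"),
       orig   = perturb_mask(mask,  0, "orig"),
       plus1  = perturb_mask(mask, +1, "plus1"),
       plus2  = perturb_mask(mask, +2, "plus2"))
}
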