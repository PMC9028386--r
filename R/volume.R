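#' Image volume container
#'
#' A 3D scalar image with voxel spacing and modality metadata. The value
#' grid is stored as a plain numeric array; `spacing` gives the physical
#' voxel size in mm along each axis and `origin` the physical coordinate
#' (mm) of the lower corner of the grid. Voxel centres sit at
#' `origin + (index - 0.5) * spacing` (1-based indices), so all geometry
#' is done in continuous mm space.
#'
#' @param values numeric 3D array of voxel intensities.
#' @param spacing numeric length-3, voxel size in mm; strictly positive.
#' @param origin numeric length-3, physical position of the grid corner (mm).
#' @param modality `"PET_SUV"` (units g/mL) or `"MRI_ADC"`
#'   (units 1e-6 mm^2/s).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0),
                         modality = c("PET_SUV", "MRI_ADC")) {
  modality <- match.arg(modality)
  values <- check_grid(values)
  storage.mode(values) <- "double"
  spacing <- check_spacing(spacing)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("image volume contains ", sum(!is.finite(values)),
         " non-finite voxel(s)")
  }
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin),
         modality = modality,
         units = if (modality == "PET_SUV") "g/mL" else "1e-6 mm^2/s"),
    class = "image_volume")
}

#' Lesion mask container
#'
#' A binary 3D mask aligned to an [image_volume()]: same grid shape,
#' spacing and origin. Carries lesion identity and a contour-variant tag
#' used by the stability analysis.
#'
#' @param values 3D array coercible to 0/1.
#' @param spacing,origin as in [image_volume()].
#' @param patient_id,lesion_id identifiers.
#' @param modality `"PET_SUV"` or `"MRI_ADC"`.
#' @param variant contour variant: `"orig"`, `"minus1"`, `"plus1"`,
#'   `"plus2"`, or `"final"` (pairing-resolved mask).
#' @param allow_empty if `FALSE` (default), an all-zero mask is an error;
#'   degenerate masks must be created explicitly (see [perturb_mask()]).
#' @return An object of class `lesion_mask`. `degenerate` is `TRUE` when
#'   the mask is empty and `allow_empty` was set.
#' @export
lesion_mask <- function(values, spacing, origin = c(0, 0, 0),
                        patient_id = NA_character_, lesion_id = NA_character_,
                        modality = c("PET_SUV", "MRI_ADC"),
                        variant = "orig", allow_empty = FALSE) {
  modality <- match.arg(modality)
  values <- check_grid(values)
  if (!all(values %in% c(0, 1))) stop("mask values must be 0/1")
  storage.mode(values) <- "integer"
  n_in <- sum(values)
  if (n_in == 0L && !allow_empty) {
    stop("empty mask for lesion '", lesion_id, "' (flag allow_empty to keep)")
  }
  structure(
    list(values = values, spacing = check_spacing(spacing),
         origin = as.numeric(origin), patient_id = patient_id,
         lesion_id = lesion_id, modality = modality, variant = variant,
         degenerate = n_in == 0L),
    class = "lesion_mask")
}

check_grid <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("expected a 3D array, got ",
         if (is.array(values)) paste0(length(dim(values)), "D") else
           class(values)[1])
  }
  values
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three strictly positive numbers (mm)")
  }
  spacing
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  %s voxels @ %s mm  range [%.4g, %.4g] %s\n",
              x$modality, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "/"),
              min(x$values), max(x$values), x$units))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s/%s %s variant=%s  %d voxels%s\n",
              x$patient_id, x$lesion_id, x$modality, x$variant,
              sum(x$values), if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

nifti_affine <- function(spacing, origin) {
  aff <- diag(c(spacing, 1))
  # NIfTI positions are voxel centres; our origin is the grid corner
  aff[1:3, 4] <- origin + spacing / 2
  aff
}

write_nifti_grid <- function(values, spacing, origin, path, datatype) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- spacing
  RNifti::sform(img) <- structure(nifti_affine(spacing, origin), code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

read_nifti_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(img, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) {
    stop("expected a 3D NIfTI volume, got ", length(d), "D: ", path)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  aff <- RNifti::xform(img)
  origin <- aff[1:3, 4] - spacing / 2
  list(values = array(as.numeric(img), dim = d), spacing = spacing,
       origin = as.numeric(origin))
}

#' Read / write volumes and masks as NIfTI-1
#'
#' Volumes are written as 32-bit float, masks as unsigned 8-bit 0/1; the
#' header affine encodes spacing and origin. Reading validates that the
#' file is 3D, that spacing is recoverable and that all voxels are finite
#' (volumes) or binary (masks).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param modality modality tag to attach on read.
#' @return `read_volume()` an [image_volume()]; `read_mask()` a
#'   [lesion_mask()].
#' @export
read_volume <- function(path, modality = c("PET_SUV", "MRI_ADC")) {
  g <- read_nifti_grid(path)
  n_bad <- sum(!is.finite(g$values))
  if (n_bad > 0) {
    stop("volume ", basename(path), " contains ", n_bad,
         " non-finite voxel(s)")
  }
  image_volume(g$values, g$spacing, g$origin, match.arg(modality))
}

#' @rdname read_volume
#' @param volume an [image_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  write_nifti_grid(volume$values, volume$spacing, volume$origin, path,
                   datatype = "float")
}

#' @rdname read_volume
#' @param patient_id,lesion_id,variant identity metadata to attach on read.
#' @param allow_empty passed to [lesion_mask()].
#' @export
read_mask <- function(path, modality = c("PET_SUV", "MRI_ADC"),
                      patient_id = NA_character_, lesion_id = NA_character_,
                      variant = "orig", allow_empty = FALSE) {
  g <- read_nifti_grid(path)
  lesion_mask(g$values, g$spacing, g$origin, patient_id, lesion_id,
              match.arg(modality), variant, allow_empty = allow_empty)
}

#' @rdname read_volume
#' @param mask a [lesion_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  write_nifti_grid(mask$values, mask$spacing, mask$origin, path,
                   datatype = "uint8")
}

#' Resample a volume or mask to an isotropic grid
#'
#' Both modalities are analysed on a common 1 mm isotropic grid. The
#' output grid covers the same physical extent (rounded to the nearest
#' whole voxel); intensities are interpolated trilinearly, masks by
#' nearest neighbour so they stay strictly binary.
#'
#' @param x an [image_volume()] or [lesion_mask()].
#' @param target_spacing isotropic target voxel size in mm (default 1).
#' @return An object of the same class on the target grid.
#' @export
resample_isotropic <- function(x, target_spacing = 1) {
  UseMethod("resample_isotropic")
}

resample_grid_geometry <- function(dim_in, spacing, target) {
  if (length(target) == 1L) target <- rep(target, 3L)
  target <- check_spacing(target)
  extent <- dim_in * spacing
  dim_out <- pmax(1L, as.integer(round(extent / target)))
  list(dim_out = dim_out, target = target)
}

# Continuous (1-based, centre-of-voxel) source index of each target voxel
# centre along one axis.
source_index <- function(n_out, t_sp, s_sp) {
  x <- (seq_len(n_out) - 0.5) * t_sp   # physical mm from grid corner
  x / s_sp + 0.5
}

#' @export
resample_isotropic.image_volume <- function(x, target_spacing = 1) {
  g <- resample_grid_geometry(dim(x$values), x$spacing, target_spacing)
  if (isTRUE(all.equal(x$spacing, g$target)) &&
      all(dim(x$values) == g$dim_out)) {
    return(x)
  }
  out <- trilinear_resample(x$values, x$spacing, g$dim_out, g$target)
  image_volume(out, g$target, x$origin, x$modality)
}

#' @export
resample_isotropic.lesion_mask <- function(x, target_spacing = 1) {
  g <- resample_grid_geometry(dim(x$values), x$spacing, target_spacing)
  if (isTRUE(all.equal(x$spacing, g$target)) &&
      all(dim(x$values) == g$dim_out)) {
    return(x)
  }
  idx <- lapply(1:3, function(a) {
    i <- round(source_index(g$dim_out[a], g$target[a], x$spacing[a]))
    pmin(pmax(i, 1L), dim(x$values)[a])
  })
  out <- x$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  dim(out) <- g$dim_out
  lesion_mask(out, g$target, x$origin, x$patient_id, x$lesion_id,
              x$modality, x$variant, allow_empty = TRUE)
}

trilinear_resample <- function(values, spacing, dim_out, target) {
  dim_in <- dim(values)
  ax <- lapply(1:3, function(a) {
    ic <- source_index(dim_out[a], target[a], spacing[a])
    ic <- pmin(pmax(ic, 1), dim_in[a])       # clamp: edge replication
    lo <- pmin(floor(ic), dim_in[a] - 1L)
    lo <- pmax(lo, 1L)
    if (dim_in[a] == 1L) lo <- rep(1L, length(ic))
    w <- ic - lo
    if (dim_in[a] == 1L) w <- rep(0, length(ic))
    list(lo = as.integer(lo), w = w)
  })
  nx <- dim_out[1]; ny <- dim_out[2]; nz <- dim_out[3]
  out <- array(0, dim = dim_out)
  hi <- function(a) pmin(ax[[a]]$lo + 1L, dim_in[a])
  ii <- list(ax[[1]]$lo, hi(1)); jj <- list(ax[[2]]$lo, hi(2))
  kk <- list(ax[[3]]$lo, hi(3))
  wx <- ax[[1]]$w; wy <- ax[[2]]$w; wz <- ax[[3]]$w
  for (a in 1:2) for (b in 1:2) for (c in 1:2) {
    wa <- if (a == 1) 1 - wx else wx
    wb <- if (b == 1) 1 - wy else wy
    wc <- if (c == 1) 1 - wz else wz
    corner <- values[ii[[a]], jj[[b]], kk[[c]], drop = FALSE]
    dim(corner) <- dim_out
    w3 <- outer(outer(wa, wb), wc)
    dim(w3) <- dim_out
    out <- out + corner * w3
  }
  out
}
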