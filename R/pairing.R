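#' Overlap fraction of two masks
#'
#' Intersection volume divided by the volume of the smaller mask. With
#' this denominator, full containment of the smaller lesion is the
#' continuous limit (fraction 1) of partial overlap.
#'
#' @param mask_a,mask_b non-empty [lesion_mask()]s on the same grid.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(mask_a, mask_b) {
  if (mask_a$degenerate || mask_b$degenerate) {
    stop("overlap of an empty mask is undefined")
  }
  if (!all(dim(mask_a$values) == dim(mask_b$values))) {
    stop("masks are on different grids")
  }
  inter <- sum(mask_a$values == 1L & mask_b$values == 1L)
  inter / min(sum(mask_a$values), sum(mask_b$values))
}

#' Topographic pairing of PET and MRI lesion contours
#'
#' Applies the contour-resolution rules for lesions visible on both
#' modalities:
#' (a) if one contour is (up to a small discretisation tolerance)
#' contained in the other, the contained (inner) contour is used on
#' both modalities; (b) if the volumes partially overlap by more than
#' 80% (of the smaller volume), their voxel intersection is used;
#' (c) otherwise the lesions are not associated. Candidate pairs are
#' resolved one-to-one, greedily by descending overlap fraction, with
#' deterministic lexicographic tie-breaks on lesion ids.
#'
#' @param pet_masks,mri_masks lists of [lesion_mask()]s on a common 1 mm
#'   grid, all belonging to one patient.
#' @param overlap_threshold minimum overlap fraction for rule (b)
#'   (default 0.8, strict).
#' @param containment_tol fraction of the inner mask allowed to protrude
#'   while still counting as contained (default 0.05).
#' @return List of pairs; each has `patient_id`, `pet_lesion_id`,
#'   `mri_lesion_id`, `rule` (`"containment"` or `"intersection"`),
#'   `overlap_fraction`, and `final_pet` / `final_mri` masks (variant
#'   `"final"`).
#' @export
pair_lesions <- function(pet_masks, mri_masks, overlap_threshold = 0.8,
                         containment_tol = 0.05) {
  if (!length(pet_masks) || !length(mri_masks)) return(list())
  cand <- list()
  for (i in seq_along(pet_masks)) {
    for (j in seq_along(mri_masks)) {
      ov <- overlap_fraction(pet_masks[[i]], mri_masks[[j]])
      if (ov > 0) {
        cand[[length(cand) + 1L]] <- list(i = i, j = j, ov = ov)
      }
    }
  }
  if (!length(cand)) return(list())
  ovs <- vapply(cand, `[[`, numeric(1), "ov")
  pet_ids <- vapply(cand, function(cc) pet_masks[[cc$i]]$lesion_id,
                    character(1))
  mri_ids <- vapply(cand, function(cc) mri_masks[[cc$j]]$lesion_id,
                    character(1))
  cand <- cand[order(-ovs, pet_ids, mri_ids)]
  used_pet <- logical(length(pet_masks))
  used_mri <- logical(length(mri_masks))
  pairs <- list()
  for (cc in cand) {
    if (used_pet[cc$i] || used_mri[cc$j]) next
    pm <- pet_masks[[cc$i]]; mm <- mri_masks[[cc$j]]
    res <- resolve_pair(pm, mm, cc$ov, overlap_threshold, containment_tol)
    if (is.null(res)) next
    used_pet[cc$i] <- TRUE; used_mri[cc$j] <- TRUE
    pairs[[length(pairs) + 1L]] <- res
  }
  pairs
}

resolve_pair <- function(pm, mm, ov, overlap_threshold, containment_tol) {
  np <- sum(pm$values); nm <- sum(mm$values)
  inter <- pm$values & mm$values
  out_p <- 1 - sum(inter) / np      # fraction of PET outside MRI
  out_m <- 1 - sum(inter) / nm
  rule <- NULL; final <- NULL
  if (out_p <= containment_tol || out_m <= containment_tol) {
    rule <- "containment"
    final <- if (np <= nm) pm$values else mm$values   # inner contour
  } else if (ov > overlap_threshold) {
    rule <- "intersection"
    final <- array(as.integer(inter), dim(pm$values))
  } else {
    return(NULL)
  }
  mk <- function(proto) {
    lesion_mask(final, proto$spacing, proto$origin, proto$patient_id,
                proto$lesion_id, proto$modality, "final")
  }
  list(patient_id = pm$patient_id, pet_lesion_id = pm$lesion_id,
       mri_lesion_id = mm$lesion_id, rule = rule, overlap_fraction = ov,
       final_pet = mk(pm), final_mri = mk(mm))
}

#' Join histology labels onto a lesion table
#'
#' Lesions without a histology match (imaging false positives) are
#' discarded; the rest receive the binary endpoint label: 0 for ISUP
#' grade 1, 1 for grades 2 and above.
#'
#' @param lesions data frame with columns `patient_id`, `lesion_id`
#'   (one row per analysed lesion).
#' @param ground_truth data frame with `patient_id`, `lesion_id`,
#'   `isup_class`, `histology_match`.
#' @return `lesions` restricted to histology-matched rows, with columns
#'   `isup_class` and binary `label` appended.
#' @export
join_histology_labels <- function(lesions, ground_truth) {
  key <- function(df) paste(df$patient_id, df$lesion_id)
  idx <- match(key(lesions), key(ground_truth))
  if (anyNA(idx)) {
    miss <- key(lesions)[is.na(idx)]
    stop("lesion(s) absent from ground truth: ",
         paste(miss, collapse = ", "))
  }
  out <- lesions
  out$isup_class <- ground_truth$isup_class[idx]
  out$histology_match <- ground_truth$histology_match[idx]
  out <- out[out$histology_match, , drop = FALSE]
  out$label <- as.integer(out$isup_class >= 2)
  out$histology_match <- NULL
  rownames(out) <- NULL
  out
}
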