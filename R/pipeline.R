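#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> resample -> positivity/histology filtering
#' -> contour perturbation -> feature extraction -> ICC stability
#' screening -> PET/MRI pairing -> the five-model repeated-CV suite,
#' writing all tabular outputs, a markdown report and a hash manifest
#' to `out_dir`. The whole run is a pure function of
#' (configuration, seed): per-stage seeds are derived deterministically
#' from the master seed.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @param seed master seed; overrides `config$seed` when given.
#' @param n_repeats CV repetitions per model (default 30).
#' @param n_bins grey levels for discretisation (default 32).
#' @param icc_threshold stability threshold (default 0.6, strict).
#' @param write_images also write the resampled cohort images under
#'   `out_dir/cohort` (default `FALSE`; tables are always written).
#' @return Object of class `rad_run` with elements `cohort`,
#'   `stability` (per-modality tables), `pairs`, `suite`, `files`.
#' @export
run_all <- function(config = cohort_config(), out_dir = tempfile("radrun"),
                    seed = NULL, n_repeats = 30, n_bins = 32,
                    icc_threshold = 0.6, write_images = FALSE) {
  t0 <- Sys.time()
  if (!is.null(seed)) config$seed <- derive_seed(seed, "simulate")
  master <- seed %||% config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  message("[simulate] generating cohort (seed ", config$seed, ")")
  cohort <- generate_cohort(
    config, out_dir = if (write_images) file.path(out_dir, "cohort"))
  gt <- cohort$ground_truth

  message("[preprocess] resampling to 1 mm isotropic")
  vol1 <- lapply(cohort$volumes, function(v) {
    list(pet = resample_isotropic(v$pet), mri = resample_isotropic(v$mri))
  })
  masks1 <- lapply(cohort$masks, resample_isotropic)
  masks1 <- Filter(function(m) !m$degenerate, masks1)

  pet_masks <- Filter(function(m) m$modality == "PET_SUV", masks1)
  mri_masks <- Filter(function(m) m$modality == "MRI_ADC", masks1)
  pet_vols <- lapply(vol1, `[[`, "pet")
  mri_vols <- lapply(vol1, `[[`, "mri")

  message("[filter] PET positivity (SUVmax >= ", config$suv_threshold,
          ") and histology match")
  pet_masks <- pet_positivity_filter(pet_masks, pet_vols,
                                     config$suv_threshold)
  tp_key <- paste(gt$patient_id, gt$lesion_id)[gt$histology_match]
  is_tp <- function(m) paste(m$patient_id, m$lesion_id) %in% tp_key
  pet_masks <- Filter(is_tp, pet_masks)
  mri_masks <- Filter(is_tp, mri_masks)

  message("[perturb+extract] ", length(pet_masks), " PET / ",
          length(mri_masks), " MRI lesions x 4 contour variants")
  feat_pet <- extract_variant_features(pet_masks, pet_vols, n_bins)
  feat_mri <- extract_variant_features(mri_masks, mri_vols, n_bins)

  message("[stability] ICC > ", icc_threshold, " screening")
  stab_pet <- stability_filter(feat_pet, threshold = icc_threshold)
  stab_mri <- stability_filter(feat_mri, threshold = icc_threshold)
  message("  stable features: PET ", length(stab_pet$stable), ", MRI ",
          length(stab_mri$stable))

  message("[pair] topographic PET/MRI pairing")
  pairs <- list()
  for (pid in names(vol1)) {
    pp <- Filter(function(m) m$patient_id == pid, pet_masks)
    mm <- Filter(function(m) m$patient_id == pid, mri_masks)
    pairs <- c(pairs, pair_lesions(pp, mm))
  }
  pairs_tab <- pairs_table(pairs)

  message("[model] building the five-model suite (", length(pairs),
          " paired lesions)")
  label_of <- function(masks) {
    tab <- data.frame(
      patient_id = vapply(masks, `[[`, character(1), "patient_id"),
      lesion_id = vapply(masks, `[[`, character(1), "lesion_id"))
    join_histology_labels(tab, gt)$label
  }
  wide <- function(long, stable, masks) {
    keys <- vapply(masks, function(m) paste(m$patient_id, m$lesion_id),
                   character(1))
    long <- long[long$variant == "orig" & long$feature %in% stable, ]
    m <- matrix(NA_real_, length(keys), length(stable),
                dimnames = list(keys, stable))
    m[cbind(match(long$lesion, keys), match(long$feature, stable))] <-
      long$value
    m
  }
  pet_set <- list(x = wide(feat_pet, stab_pet$stable, pet_masks),
                  y = label_of(pet_masks))
  mri_set <- list(x = wide(feat_mri, stab_mri$stable, mri_masks),
                  y = label_of(mri_masks))
  paired_set <- paired_features(pairs, pet_vols, mri_vols,
                                stab_pet$stable, stab_mri$stable, gt,
                                n_bins)
  suite <- build_model_suite(pet_set, mri_set, paired_set,
                             n_repeats = n_repeats, seed = master)

  run <- structure(
    list(cohort = cohort,
         stability = list(pet = stab_pet, mri = stab_mri),
         pairs = pairs, pairs_table = pairs_tab, suite = suite,
         datasets = list(pet = pet_set, mri = mri_set,
                         paired = paired_set),
         out_dir = out_dir, seed = master,
         elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "rad_run")
  run$files <- write_run_outputs(run)
  run
}

# Feature extraction across the contour-variant family, long format.
extract_variant_features <- function(masks, volumes, n_bins) {
  if (!length(masks)) {
    return(data.frame(lesion = character(0), patient_id = character(0),
                      lesion_id = character(0), variant = character(0),
                      feature = character(0), value = numeric(0)))
  }
  rows <- lapply(masks, function(m) {
    vol <- volumes[[m$patient_id]]
    fam <- variant_family(m)
    per_var <- lapply(names(fam), function(vn) {
      vm <- fam[[vn]]
      if (vm$degenerate) return(NULL)
      fv <- extract_all(vol, vm, n_bins)
      data.frame(lesion = paste(m$patient_id, m$lesion_id),
                 patient_id = m$patient_id, lesion_id = m$lesion_id,
                 variant = vn, feature = names(fv), value = unname(fv))
    })
    do.call(rbind, per_var)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

paired_features <- function(pairs, pet_vols, mri_vols, stable_pet,
                            stable_mri, gt, n_bins) {
  if (!length(pairs)) {
    return(list(x_pet = NULL, x_mri = NULL, y = integer(0)))
  }
  xp <- matrix(NA_real_, length(pairs), length(stable_pet),
               dimnames = list(NULL, stable_pet))
  xm <- matrix(NA_real_, length(pairs), length(stable_mri),
               dimnames = list(NULL, stable_mri))
  tab <- data.frame(
    patient_id = vapply(pairs, `[[`, character(1), "patient_id"),
    lesion_id = vapply(pairs, `[[`, character(1), "pet_lesion_id"))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    fp <- extract_all(pet_vols[[pr$patient_id]], pr$final_pet, n_bins)
    fm <- extract_all(mri_vols[[pr$patient_id]], pr$final_mri, n_bins)
    xp[i, ] <- fp[stable_pet]
    xm[i, ] <- fm[stable_mri]
  }
  rownames(xp) <- rownames(xm) <- paste(tab$patient_id, tab$lesion_id)
  y <- join_histology_labels(tab, gt)$label
  list(x_pet = xp, x_mri = xm, y = y)
}

pairs_table <- function(pairs) {
  if (!length(pairs)) {
    return(data.frame(patient_id = character(0),
                      pet_lesion_id = character(0),
                      mri_lesion_id = character(0), rule = character(0),
                      overlap_fraction = numeric(0)))
  }
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(patient_id = p$patient_id,
               pet_lesion_id = p$pet_lesion_id,
               mri_lesion_id = p$mri_lesion_id, rule = p$rule,
               overlap_fraction = p$overlap_fraction)
  }))
}

write_run_outputs <- function(run) {
  d <- run$out_dir
  w <- function(df, name) {
    path <- file.path(d, name)
    write.csv(df, path, row.names = FALSE)
    path
  }
  files <- c(
    w(run$suite$summary, "model_summary.csv"),
    w(run$stability$pet$table, "stability_pet.csv"),
    w(run$stability$mri$table, "stability_mri.csv"),
    w(run$pairs_table, "pairs.csv"),
    w(run$cohort$ground_truth, "ground_truth.csv"))
  for (id in names(run$suite$models)) {
    m <- run$suite$models[[id]]
    if (is.null(m)) next
    files <- c(files,
               w(m$iterations, paste0("iterations_", id, ".csv")),
               w(data.frame(feature = names(m$selection_frequency),
                            frequency = as.numeric(m$selection_frequency)),
                 paste0("selection_frequency_", id, ".csv")),
               w(roc_points(m$best$scores, m$best$labels),
                 paste0("roc_best_test_", id, ".csv")))
  }
  rep_path <- file.path(d, "report.md")
  writeLines(render_report(run), rep_path)
  files <- c(files, rep_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         seed = run$seed)
  write.csv(manifest, file.path(d, "manifest.csv"), row.names = FALSE)
  c(files, file.path(d, "manifest.csv"))
}

#' Human-readable run report
#'
#' Renders (or re-renders, idempotently) the markdown report of a
#' completed pipeline run: the five-model summary table, the most
#' frequently selected features per model, ICC pass counts per modality
#' and the pairing breakdown.
#'
#' @param run a `rad_run` object from [run_all()].
#' @param path optional file to (re)write; when `NULL` the text is
#'   returned only.
#' @return Character vector of markdown lines, invisibly when `path` is
#'   given.
#' @export
report <- function(run, path = NULL) {
  stopifnot(inherits(run, "rad_run"))
  txt <- render_report(run)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

render_report <- function(run) {
  s <- run$suite$summary
  fmt <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", x))
  lines <- c(
    "# Radiomics pipeline run report",
    "",
    sprintf("Master seed: %s.", run$seed),
    "",
    "## Model performance",
    "",
    paste("| Model Type | Number of Lesions | Train Mean AUC |",
          "Test Mean AUC | Train Best AUC | Test Best AUC |"),
    "|---|---|---|---|---|---|",
    sprintf("| %s | %d | %s | %s | %s | %s |", s$model_type,
            s$n_lesions, fmt(s$train_mean_auc), fmt(s$test_mean_auc),
            fmt(s$train_best_auc), fmt(s$test_best_auc)))
  for (id in names(run$suite$skipped)) {
    lines <- c(lines, sprintf("- model (%s) skipped: %s", id,
                              run$suite$skipped[[id]]))
  }
  lines <- c(lines, "", "## Feature stability (ICC > 0.6)", "",
             sprintf("- PET: %d of %d features stable",
                     sum(run$stability$pet$table$pass),
                     nrow(run$stability$pet$table)),
             sprintf("- MRI-ADC: %d of %d features stable",
                     sum(run$stability$mri$table$pass),
                     nrow(run$stability$mri$table)),
             "", "## Lesion pairing", "",
             sprintf("- %d paired lesions (%d containment, %d intersection)",
                     nrow(run$pairs_table),
                     sum(run$pairs_table$rule == "containment"),
                     sum(run$pairs_table$rule == "intersection")))
  for (id in names(run$suite$models)) {
    m <- run$suite$models[[id]]
    if (is.null(m)) next
    sf <- head(m$selection_frequency, 10)
    sf <- sf[sf > 0]
    if (!length(sf)) next
    lines <- c(lines, "", sprintf("## Top features, model (%s) %s", id,
                                  m$model_id), "")
    lines <- c(lines, sprintf("- %s (%.0f%% of iterations)", names(sf),
                              100 * as.numeric(sf)))
  }
  lines
}

#' @export
print.rad_run <- function(x, ...) {
  cat("<rad_run> seed", x$seed, "-", x$out_dir, "\n")
  print(x$suite)
  invisible(x)
}
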