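#' The five-model evaluation suite
#'
#' Runs repeated cross-validation for the five model configurations:
#' (a) all PET-visible lesions, PET features; (b) all MRI-visible
#' lesions, MRI features; (c) paired lesions, PET features; (d) paired
#' lesions, MRI features; (e) paired lesions, both feature sets
#' concatenated with modality-prefixed names (`PET.`, `ADC.`).
#' A configuration whose lesion subset is empty or single-class is
#' skipped with a recorded reason rather than failing the suite.
#'
#' @param pet,mri lists `list(x = feature matrix, y = binary labels)`
#'   for the full per-modality lesion sets (stability-filtered
#'   features).
#' @param paired list `list(x_pet, x_mri, y)` for the topographically
#'   paired lesions (features from the pairing-resolved masks).
#' @param n_repeats,train_fraction,inner_folds passed to
#'   [run_repeated_cv()].
#' @param seed master seed; each configuration derives its own stream.
#' @return Object of class `rad_suite`: named list of `rad_cv` results
#'   (`NULL` where skipped), `skipped` reasons, and a `summary` data
#'   frame with one row per configuration (model type, number of
#'   lesions, train/test mean AUC, train/test best AUC).
#' @export
build_model_suite <- function(pet, mri, paired, n_repeats = 30,
                              train_fraction = 2 / 3, inner_folds = 3,
                              seed = 1L) {
  specs <- list(
    a = list(label = "PET", x = pet$x, y = pet$y),
    b = list(label = "MRI", x = mri$x, y = mri$y),
    c = list(label = "PET (MRI-visible)", x = paired$x_pet,
             y = paired$y),
    d = list(label = "MRI (PET-visible)", x = paired$x_mri,
             y = paired$y),
    e = list(label = "MRI+PET",
             x = if (!is.null(paired$x_pet) && !is.null(paired$x_mri)) {
               xp <- paired$x_pet; xm <- paired$x_mri
               colnames(xp) <- paste0("PET.", colnames(xp))
               colnames(xm) <- paste0("ADC.", colnames(xm))
               cbind(xp, xm)
             },
             y = paired$y))
  models <- list()
  skipped <- list()
  for (id in names(specs)) {
    s <- specs[[id]]
    reason <- NULL
    if (is.null(s$x) || is.null(s$y) || nrow(as.matrix(s$x)) == 0) {
      reason <- "empty lesion subset"
    } else if (length(unique(s$y)) < 2 || any(table(s$y) < 2)) {
      reason <- "fewer than 2 lesions in one class"
    } else if (ncol(as.matrix(s$x)) == 0) {
      reason <- "no stable features available"
    }
    if (is.null(reason)) {
      models[[id]] <- run_repeated_cv(
        s$x, s$y, n_repeats = n_repeats,
        train_fraction = train_fraction, inner_folds = inner_folds,
        seed = derive_seed(seed, "model") + 10000L * match(id, letters),
        model_id = s$label)
    } else {
      models[id] <- list(NULL)
      skipped[[id]] <- reason
      message("model (", id, ") '", s$label, "' skipped: ", reason)
    }
  }
  summ <- do.call(rbind, lapply(names(specs), function(id) {
    m <- models[[id]]
    data.frame(
      model = id, model_type = specs[[id]]$label,
      n_lesions = if (is.null(m)) 0L else m$n_lesions,
      n_features = if (is.null(m)) 0L else m$n_features,
      train_mean_auc = if (is.null(m)) NA_real_ else m$train_mean_auc,
      test_mean_auc = if (is.null(m)) NA_real_ else m$test_mean_auc,
      train_best_auc = if (is.null(m)) NA_real_ else m$train_best_auc,
      test_best_auc = if (is.null(m)) NA_real_ else m$test_best_auc)
  }))
  structure(list(models = models, skipped = skipped, summary = summ),
            class = "rad_suite")
}

#' @export
print.rad_suite <- function(x, ...) {
  cat("<rad_suite> five-model evaluation\n")
  print(x$summary, row.names = FALSE, digits = 3)
  for (id in names(x$skipped)) {
    cat("  (", id, ") skipped: ", x$skipped[[id]], "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.rad_suite <- function(object, n_top = 5, ...) {
  print(object)
  for (id in names(object$models)) {
    m <- object$models[[id]]
    if (is.null(m)) next
    sf <- head(m$selection_frequency, n_top)
    sf <- sf[sf > 0]
    if (!length(sf)) next
    cat(sprintf("  (%s) %s top features: %s\n", id, m$model_id,
                paste(sprintf("%s [%.0f%%]", names(sf), 100 * sf),
                      collapse = ", ")))
  }
  invisible(object)
}
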