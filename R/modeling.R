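#' Stratified train/test split
#'
#' Splits lesions into training and test sets, stratified by class so
#' both classes appear in both partitions. The training set has
#' `round(train_fraction * n)` lesions overall, allocated to classes by
#' largest remainder of `train_fraction * n_class` and clamped so
#' neither partition loses a class entirely (n = 31 at 2/3 gives
#' 21 train / 10 test).
#'
#' @param labels binary vector (0/1).
#' @param train_fraction fraction of lesions used for training
#'   (default 2/3).
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, train_fraction = 2 / 3, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("both classes must be present")
  if (any(table(labels) < 2L)) {
    stop("each class needs at least 2 lesions for a stratified split")
  }
  set.seed(seed)
  n_c <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  exact <- train_fraction * n_c
  n_tr <- floor(exact)
  extra <- round(train_fraction * length(labels)) - sum(n_tr)
  if (extra > 0) {
    ord <- order(exact - floor(exact), decreasing = TRUE)
    n_tr[ord[seq_len(extra)]] <- n_tr[ord[seq_len(extra)]] + 1L
  }
  n_tr <- pmin(pmax(n_tr, 1L), n_c - 1L)
  train <- integer(0)
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    train <- c(train, sample(idx, n_tr[ci]))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

# Stratified fold ids for the inner CV; guarantees both classes in every
# fold whenever each class has >= n_folds members (folds are reduced
# otherwise).
stratified_folds <- function(labels, n_folds) {
  n_folds <- max(2L, min(n_folds, min(table(labels))))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' LASSO-penalised logistic regression with internal cross-validation
#'
#' Standardises features on the training data (missing values imputed
#' with training medians, zero-variance columns kept at 0), then fits an
#' L1-penalised logistic model over a log-spaced penalty path and picks
#' the penalty minimising the inner stratified k-fold CV binomial
#' deviance. The intercept is never penalised. Selected features are the
#' nonzero coefficients at the chosen penalty; an intercept-only model
#' is a legitimate outcome.
#'
#' @param x numeric feature matrix (rows = lesions).
#' @param y binary labels (0/1).
#' @param inner_folds inner CV folds (default 3).
#' @param n_lambda,lambda_min_ratio penalty path: `n_lambda` log-spaced
#'   values from the smallest all-zero penalty down
#'   `lambda_min_ratio` times.
#' @param seed integer seed (fold assignment).
#' @return Object of class `rad_lasso`: coefficients on the original
#'   feature scale, selected feature names, chosen penalty, and the
#'   stored standardisation so [predict()] can score new lesions.
#' @export
fit_lasso_logistic <- function(x, y, inner_folds = 3, n_lambda = 100,
                               lambda_min_ratio = 1e-4, seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  set.seed(seed)
  med <- apply(x, 2, median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  model <- list(center = ctr, scale = scl, median = med,
                features = colnames(x), lambda = NA_real_,
                intercept = qlogis(max(min(mean(y), 1 - 1e-6), 1e-6)),
                beta = setNames(numeric(ncol(x)), colnames(x)),
                selected = character(0))
  fit <- tryCatch({
    lmax <- max(abs(crossprod(xs, y - mean(y))) / length(y), 1e-4)
    path <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = n_lambda))
    foldid <- stratified_folds(y, inner_folds)
    # small-cohort fits are the whole point here; glmnet's advisory
    # warning about class counts below 8 would fire on almost every
    # iteration, so it is muffled (and only it)
    withCallingHandlers(
      glmnet::cv.glmnet(xs, y, family = "binomial", lambda = path,
                        foldid = foldid, standardize = FALSE,
                        type.measure = "deviance",
                        grouped = length(y) >= 3 * max(foldid)),
      warning = function(w) {
        # two known advisories: tiny class counts (inherent to this
        # cohort scale) and non-convergence at the deepest end of the
        # penalty path (solutions for the relevant larger lambdas are
        # still returned)
        if (grepl("fewer than 8\\s+observations|Convergence for",
                  conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }, error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- as.numeric(coef(fit, s = "lambda.min"))
    model$lambda <- fit$lambda.min
    model$intercept <- cf[1]
    model$beta <- setNames(cf[-1], colnames(x))
    model$selected <- colnames(x)[cf[-1] != 0]
  }
  class(model) <- "rad_lasso"
  model
}

#' @export
predict.rad_lasso <- function(object, newdata, type = c("response",
                                                        "link"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)[, object$features, drop = FALSE]
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- object$median[j]
  }
  xs <- scale(x, center = object$center, scale = object$scale)
  eta <- drop(object$intercept + xs %*% object$beta)
  if (type == "response") plogis(eta) else eta
}

#' @export
print.rad_lasso <- function(x, ...) {
  cat(sprintf("<rad_lasso> lambda=%.4g, %d/%d features selected\n",
              x$lambda, length(x$selected), length(x$beta)))
  if (length(x$selected)) {
    cat(" ", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with ties counted one half, identical to the
#' trapezoidal area under the empirical ROC curve. Constant scores give
#' 0.5.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Repeated stochastic cross-validation of a LASSO-logistic model
#'
#' The core evaluation loop: the lesion set is split 2/3 train / 1/3
#' test (stratified), a LASSO-logistic model with internal 3-fold CV is
#' fitted on the training set, and train/test AUCs plus the selected
#' features are recorded; repeated `n_repeats` times with fresh splits.
#' The "best" iteration is the one with maximal test AUC (ties broken by
#' train AUC, then iteration index).
#'
#' @param x feature matrix or data frame (rows = lesions).
#' @param y binary labels (0/1).
#' @param n_repeats number of repetitions (default 30).
#' @param train_fraction,inner_folds see [split_train_test()] and
#'   [fit_lasso_logistic()].
#' @param seed master seed; iteration `i` uses `seed + i`.
#' @param model_id optional label carried into summaries.
#' @return Object of class `rad_cv`: per-iteration data frame
#'   (`iterations`), selection frequencies, aggregate AUCs, and the best
#'   iteration's test scores for ROC plotting.
#' @export
run_repeated_cv <- function(x, y, n_repeats = 30, train_fraction = 2 / 3,
                            inner_folds = 3, seed = 1L,
                            model_id = "model") {
  x <- as.matrix(x)
  iters <- vector("list", n_repeats)
  sel_list <- vector("list", n_repeats)
  best <- NULL
  for (i in seq_len(n_repeats)) {
    it_seed <- seed + i
    sp <- split_train_test(y, train_fraction, seed = it_seed)
    fit <- fit_lasso_logistic(x[sp$train, , drop = FALSE], y[sp$train],
                              inner_folds = inner_folds, seed = it_seed)
    tr_scores <- predict(fit, x[sp$train, , drop = FALSE])
    te_scores <- predict(fit, x[sp$test, , drop = FALSE])
    iters[[i]] <- data.frame(
      iteration = i,
      train_auc = roc_auc(tr_scores, y[sp$train]),
      test_auc = roc_auc(te_scores, y[sp$test]),
      n_selected = length(fit$selected),
      lambda = fit$lambda)
    sel_list[[i]] <- fit$selected
    rec <- list(iteration = i, scores = te_scores, labels = y[sp$test],
                train_scores = tr_scores, train_labels = y[sp$train],
                selected = fit$selected)
    if (is.null(best) ||
        iters[[i]]$test_auc > best$test_auc ||
        (iters[[i]]$test_auc == best$test_auc &&
           iters[[i]]$train_auc > best$train_auc)) {
      best <- c(rec, list(test_auc = iters[[i]]$test_auc,
                          train_auc = iters[[i]]$train_auc))
    }
  }
  iters <- do.call(rbind, iters)
  sel_freq <- sort(table(factor(unlist(sel_list),
                                levels = colnames(x))) / n_repeats,
                   decreasing = TRUE)
  structure(
    list(model_id = model_id, n_lesions = length(y),
         n_features = ncol(x), iterations = iters,
         selection_frequency = sel_freq,
         train_mean_auc = mean(iters$train_auc),
         test_mean_auc = mean(iters$test_auc),
         train_best_auc = best$train_auc,
         test_best_auc = best$test_auc,
         best = best),
    class = "rad_cv")
}

#' @export
print.rad_cv <- function(x, ...) {
  cat(sprintf(paste0("<rad_cv> %s: %d lesions, %d candidate features, ",
                     "%d repeats\n"),
              x$model_id, x$n_lesions, x$n_features,
              nrow(x$iterations)))
  cat(sprintf("  mean AUC  train %.3f / test %.3f\n",
              x$train_mean_auc, x$test_mean_auc))
  cat(sprintf("  best AUC  train %.3f / test %.3f (iteration %d)\n",
              x$train_best_auc, x$test_best_auc, x$best$iteration))
  invisible(x)
}

#' @export
summary.rad_cv <- function(object, n_top = 10, ...) {
  print(object)
  sf <- head(object$selection_frequency, n_top)
  sf <- sf[sf > 0]
  if (length(sf)) {
    cat("  most frequently selected features:\n")
    for (nm in names(sf)) {
      cat(sprintf("    %-35s %.0f%%\n", nm, 100 * sf[[nm]]))
    }
  }
  invisible(object)
}

#' ROC curve of the best iteration
#'
#' @param x a `rad_cv` object.
#' @param which `"test"` or `"train"` scores of the best iteration.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rad_cv <- function(x, which = c("test", "train"), ...) {
  which <- match.arg(which)
  sc <- if (which == "test") x$best$scores else x$best$train_scores
  lb <- if (which == "test") x$best$labels else x$best$train_labels
  ro <- roc_points(sc, lb)
  graphics::plot(ro$fpr, ro$tpr, type = "s", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "false positive rate",
                 ylab = "true positive rate",
                 main = sprintf("%s: best iteration %s ROC (AUC %.2f)",
                                x$model_id, which,
                                roc_auc(sc, lb)), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# Empirical ROC coordinates, thresholds descending.
roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o] == 1)
  fp <- cumsum(labels[o] == 0)
  # collapse tied thresholds
  last <- !duplicated(scores[o], fromLast = TRUE)
  data.frame(threshold = c(Inf, scores[o][last]),
             tpr = c(0, tp[last] / sum(labels == 1)),
             fpr = c(0, fp[last] / sum(labels == 0)))[
               , c("fpr", "tpr", "threshold")]
}
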