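test_that("stratified splits have the documented sizes and contracts", {
  y31 <- c(rep(0, 14), rep(1, 17))       # paired-cohort-sized problem
  sp <- split_train_test(y31, seed = 3)
  expect_identical(length(sp$train), 21L)   # round(2/3 * 14) + round(2/3 * 17)
  expect_identical(length(sp$test), 10L)
  expect_setequal(c(sp$train, sp$test), seq_along(y31))

  sp2 <- split_train_test(y31, seed = 3)
  expect_identical(sp, sp2)               # same seed, same split

  # stratification: both classes in both partitions across 100 draws
  y <- c(rep(0, 5), rep(1, 25))
  for (s in 1:100) {
    spl <- split_train_test(y, seed = s)
    expect_identical(sort(unique(y[spl$train])), c(0, 1))
    expect_identical(sort(unique(y[spl$test])), c(0, 1))
  }
  expect_error(split_train_test(c(0, 1, 1, 1)), "at least 2")
  expect_error(split_train_test(rep(1, 10)), "both classes")
})

test_that("the LASSO finds a separating feature among noise", {
  set.seed(11)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 21), n, 21,
              dimnames = list(NULL, c("signal", paste0("noise", 1:20))))
  x[, "signal"] <- y * 4 + rnorm(n, sd = 0.3)   # complete separation
  fit <- fit_lasso_logistic(x, y, seed = 5)
  expect_true("signal" %in% fit$selected)
  expect_gt(fit$beta["signal"], 0)

  # determinism given the seed, also with a duplicated informative column
  x2 <- cbind(x, signal_copy = x[, "signal"])
  fit2a <- fit_lasso_logistic(x2, y, seed = 5)
  fit2b <- fit_lasso_logistic(x2, y, seed = 5)
  expect_identical(fit2a$beta, fit2b$beta)
  expect_true(any(c("signal", "signal_copy") %in% fit2a$selected))
})

test_that("pure-noise features are mostly rejected by the LASSO", {
  # under minimum-deviance lambda selection the intercept-only model is
  # the modal outcome on pure noise, and the few escapes are small
  set.seed(23)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  n_sel <- integer(20)
  for (s in 1:20) {
    x <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, paste0("noise", 1:20)))
    fit <- fit_lasso_logistic(x, y, seed = 100 + s)
    n_sel[s] <- length(fit$selected)
  }
  expect_identical(as.integer(names(which.max(table(n_sel)))), 0L)
  expect_lt(mean(n_sel), 3)
})

test_that("missing values are imputed with training medians", {
  set.seed(4)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  x[1:5, 2] <- NA
  fit <- fit_lasso_logistic(x, y, seed = 1)
  expect_false(anyNA(predict(fit, x)))
  xnew <- x[1:3, ]; xnew[, 1] <- NA
  expect_false(anyNA(predict(fit, xnew)))
})

test_that("AUC handles the canonical cases", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 20, 30), rep(c(0, 1), each = 3)), 1)
  expect_equal(roc_auc(c(3, 2, 1), c(1, 0, 0)), 1)
  expect_equal(roc_auc(-c(1, 2, 3, 4), c(0, 0, 1, 1)), 0)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)  # all tied
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("repeated CV bookkeeping is complete and reproducible", {
  set.seed(2)
  n <- 36
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  x[, 1] <- x[, 1] + 2 * y
  cv1 <- run_repeated_cv(x, y, n_repeats = 10, seed = 9)
  cv2 <- run_repeated_cv(x, y, n_repeats = 10, seed = 9)
  expect_identical(cv1$iterations, cv2$iterations)
  expect_identical(cv1$selection_frequency, cv2$selection_frequency)
  expect_identical(nrow(cv1$iterations), 10L)
  expect_true(all(cv1$iterations$train_auc >= 0 &
                    cv1$iterations$train_auc <= 1))
  expect_equal(cv1$test_mean_auc, mean(cv1$iterations$test_auc))
  # best iteration is the max-test-AUC one
  expect_equal(cv1$test_best_auc, max(cv1$iterations$test_auc))
  expect_true(all(cv1$selection_frequency >= 0 &
                    cv1$selection_frequency <= 1))
  # print/summary/plot methods run
  expect_output(print(cv1), "mean AUC")
  expect_output(summary(cv1), "selected")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(cv1))
})

test_that("the model suite builds five configurations and skips sanely", {
  set.seed(6)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  xp <- matrix(rnorm(n * 6), n, 6,
               dimnames = list(NULL, paste0("glcm.f", 1:6)))
  xm <- matrix(rnorm(n * 4), n, 4,
               dimnames = list(NULL, paste0("stat.f", 1:4)))
  suite <- build_model_suite(list(x = xp, y = y), list(x = xm, y = y),
                             list(x_pet = xp, x_mri = xm, y = y),
                             n_repeats = 3, seed = 1)
  expect_identical(nrow(suite$summary), 5L)
  expect_identical(suite$summary$model, letters[1:5])
  expect_identical(suite$models$e$n_features, ncol(xp) + ncol(xm))
  expect_true(all(grepl("^(PET|ADC)\\.",
                        names(suite$models$e$selection_frequency))))
  expect_named(
    suite$summary,
    c("model", "model_type", "n_lesions", "n_features",
      "train_mean_auc", "test_mean_auc", "train_best_auc",
      "test_best_auc"))

  # empty paired subset: c, d, e skipped with reasons
  suppressMessages(
    suite2 <- build_model_suite(list(x = xp, y = y), list(x = xm, y = y),
                                list(x_pet = NULL, x_mri = NULL,
                                     y = integer(0)),
                                n_repeats = 2, seed = 1))
  expect_identical(sort(names(suite2$skipped)), c("c", "d", "e"))
  expect_true(all(is.na(suite2$summary$test_mean_auc[3:5])))
})
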