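#' Two-way absolute-agreement intraclass correlation, single measurement
#'
#' ICC(A,1) for a lesions-by-contour-variants table: contour variants
#' are a fixed, crossed factor, and absolute agreement (not mere
#' consistency) is required, so systematic offsets between variants
#' lower the coefficient. From the two-way ANOVA mean squares (rows =
#' lesions, columns = variants, `n` lesions, `k` variants):
#' `ICC = (MS_R - MS_E) / (MS_R + (k - 1) MS_E + (k / n)(MS_C - MS_E))`.
#'
#' Lesions with any missing variant are dropped listwise. A table with
#' zero total variance (all measurements identical) has ICC 1 by
#' definition; fewer than 3 usable lesions or fewer than 2 variants
#' gives `NA`.
#'
#' @param values numeric matrix, lesions in rows, contour variants in
#'   columns; `NA`s allowed (listwise deletion).
#' @return ICC value with attributes `n` (lesions used) and
#'   `k` (variants).
#' @export
icc <- function(values) {
  values <- as.matrix(values)
  keep <- stats::complete.cases(values)
  values <- values[keep, , drop = FALSE]
  n <- nrow(values); k <- ncol(values)
  out <- function(v) structure(v, n = n, k = k)
  if (n < 3L || k < 2L) return(out(NA_real_))
  grand <- mean(values)
  if (all(values == values[1])) return(out(1))
  row_m <- rowMeans(values); col_m <- colMeans(values)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_e <- ss_tot - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  if (denom == 0) return(out(1))   # no variance anywhere
  out((ms_r - ms_e) / denom)
}

#' Contour-stability screening of features
#'
#' Computes the ICC of every feature across the contour-variant family
#' and retains those strictly above the threshold. A feature is dropped
#' (ICC `NA`) when more than `max_missing_frac` of the lesions are lost
#' to listwise deletion (degenerate variants or undefined values), or
#' when fewer than 3 usable lesions remain.
#'
#' @param features long-format data frame with columns `lesion`
#'   (lesion key), `variant`, `feature`, `value`.
#' @param threshold retain features with ICC strictly greater than this
#'   (default 0.6).
#' @param max_missing_frac maximum tolerated fraction of lesions lost to
#'   missing values (default 0.2).
#' @return List with `stable` (character vector of retained feature
#'   names) and `table` (data frame: feature, icc, n_lesions,
#'   n_variants, pass).
#' @export
stability_filter <- function(features, threshold = 0.6,
                             max_missing_frac = 0.2) {
  stopifnot(all(c("lesion", "variant", "feature", "value") %in%
                  names(features)))
  if (!nrow(features)) {
    return(list(stable = character(0),
                table = data.frame(feature = character(0),
                                   icc = numeric(0),
                                   n_lesions = integer(0),
                                   n_variants = integer(0),
                                   pass = logical(0))))
  }
  lesions <- unique(features$lesion)
  variants <- unique(features$variant)
  rows <- lapply(split(features, features$feature), function(df) {
    m <- matrix(NA_real_, length(lesions), length(variants),
                dimnames = list(lesions, variants))
    m[cbind(match(df$lesion, lesions), match(df$variant, variants))] <-
      df$value
    usable <- sum(stats::complete.cases(m))
    v <- if (1 - usable / length(lesions) > max_missing_frac) {
      structure(NA_real_, n = usable, k = length(variants))
    } else {
      icc(m)
    }
    data.frame(feature = df$feature[1], icc = as.numeric(v),
               n_lesions = attr(v, "n"), n_variants = attr(v, "k"))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- tab[order(tab$feature), ]
  tab$pass <- !is.na(tab$icc) & tab$icc > threshold
  list(stable = tab$feature[tab$pass], table = tab)
}
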