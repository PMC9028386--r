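# Texture feature families. GLCM and GLRLM features are computed per
# direction over the 13 unique 3D offsets and averaged ("averaged"
# aggregation); directions that produce no pairs/runs are skipped, and a
# feature undefined in every direction is missing. GLSZM/GLDZM are
# direction-free. Features that require grey-level variance (GLCM
# correlation, information correlation) are missing on a single-level
# ROI rather than NaN.

glcm_features_one <- function(P, ng) {
  tot <- sum(P)
  if (tot == 0) return(NULL)
  p <- P / tot
  i <- row(p); j <- col(p)
  pi_ <- rowSums(p)
  mu <- sum(i * p)
  sg2 <- sum((i - mu)^2 * p)
  pp <- p[p > 0]
  hxy <- -sum(pp * log2(pp))
  px <- pi_[pi_ > 0]
  hx <- -sum(px * log2(px))
  pipj <- pi_[i] * pi_[j]
  dim(pipj) <- dim(p)
  ok <- p > 0 & pipj > 0
  hxy1 <- -sum(p[ok] * log2(pipj[ok]))
  ok2 <- pipj > 0
  hxy2 <- -sum(pipj[ok2] * log2(pipj[ok2]))
  corr <- if (sg2 > 0) (sum(i * j * p) - mu^2) / sg2 else NA_real_
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else NA_real_
  ic2v <- 1 - exp(-2 * log(2) * (hxy2 - hxy))
  c(joint_maximum = max(p),
    joint_average = mu,
    joint_variance = sg2,
    joint_entropy = hxy,
    contrast = sum((i - j)^2 * p),
    dissimilarity = sum(abs(i - j) * p),
    inverse_difference = sum(p / (1 + abs(i - j))),
    inverse_difference_norm = sum(p / (1 + abs(i - j) / ng)),
    inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    inverse_variance = sum(p[i != j] / (i - j)[i != j]^2),
    correlation = corr,
    autocorrelation = sum(i * j * p),
    energy = sum(p^2),
    info_corr1 = ic1,
    info_corr2 = if (ic2v >= 0) sqrt(ic2v) else NA_real_)
}

avg_over_directions <- function(per_dir) {
  per_dir <- per_dir[!vapply(per_dir, is.null, logical(1))]
  if (!length(per_dir)) return(NULL)
  m <- do.call(rbind, per_dir)
  out <- colMeans(m, na.rm = TRUE)
  all_na <- apply(m, 2, function(col) all(is.na(col)))
  out[all_na] <- NA_real_
  out
}

#' Grey-level co-occurrence features
#'
#' Symmetric GLCM at Chebyshev distance 1, features averaged over the 13
#' unique 3D directions.
#'
#' @param discretized a [discretize_roi()] result.
#' @return Named numeric vector with keys prefixed `glcm.`.
#' @export
glcm_features <- function(discretized) {
  ng <- discretized$n_bins
  offs <- direction_offsets_13()
  per_dir <- lapply(seq_len(nrow(offs)), function(r) {
    glcm_features_one(glcm_matrix(discretized, offs[r, ]), ng)
  })
  out <- avg_over_directions(per_dir)
  setNames(out, paste0("glcm.", names(out)))
}

glrlm_features_one <- function(R, n_vox) {
  nr <- sum(R)
  if (nr == 0) return(NULL)
  g <- row(R); l <- col(R)
  c(sre = sum(R / l^2) / nr,
    lre = sum(R * l^2) / nr,
    glnu = sum(rowSums(R)^2) / nr,
    rlnu = sum(colSums(R)^2) / nr,
    run_pct = nr / n_vox,
    lglre = sum(R / g^2) / nr,
    hglre = sum(R * g^2) / nr,
    srlge = sum(R / (g^2 * l^2)) / nr,
    lrhge = sum(R * g^2 * l^2) / nr)
}

#' Grey-level run-length features
#'
#' Runs at Chebyshev distance 1, features averaged over the 13 unique 3D
#' directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector with keys prefixed `glrlm.`.
#' @export
glrlm_features <- function(discretized) {
  n_vox <- sum(discretized$levels > 0L)
  offs <- direction_offsets_13()
  per_dir <- lapply(seq_len(nrow(offs)), function(r) {
    glrlm_features_one(glrlm_matrix(discretized, offs[r, ]), n_vox)
  })
  out <- avg_over_directions(per_dir)
  setNames(out, paste0("glrlm.", names(out)))
}

#' Grey-level size-zone features
#'
#' Zones are 26-connected equal-level components of the ROI.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector with keys prefixed `glszm.`.
#' @export
glszm_features <- function(discretized) {
  S <- glszm_matrix(discretized)
  ns <- sum(S)
  n_vox <- sum(discretized$levels > 0L)
  g <- row(S); z <- col(S)
  setNames(
    c(sum(S / z^2) / ns,
      sum(S * z^2) / ns,
      sum(rowSums(S)^2) / ns,
      sum(colSums(S)^2) / ns,
      ns / n_vox,
      sum(S / g^2) / ns,
      sum(S * g^2) / ns,
      sum(S * z^2 / g^2) / ns,
      sum(S * g^2 / z^2) / ns),
    paste0("glszm.", c("sze", "lze", "glnu", "zsnu", "zone_pct",
                       "lglze", "hglze", "lzlge", "szhge")))
}

#' Grey-level distance-zone features
#'
#' Zone distance is the minimum city-block distance of a zone to the ROI
#' border (border voxels at distance 1).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector with keys prefixed `gldzm.`.
#' @export
gldzm_features <- function(discretized) {
  M <- gldzm_matrix(discretized)
  nz <- sum(M)
  g <- row(M); d <- col(M)
  setNames(
    c(sum(M / d^2) / nz,
      sum(M * d^2) / nz,
      sum(colSums(M)^2) / nz,
      sum(colSums(M)^2) / nz^2,
      sum(M / g^2) / nz,
      sum(M * g^2) / nz),
    paste0("gldzm.", c("sde", "lde", "zdnu", "zdnu_norm",
                       "lgze", "hgze")))
}
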