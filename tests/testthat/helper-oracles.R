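# Independent brute-force oracles used to validate the fast
# implementations. These deliberately use naive enumeration (loops,
# recursion-free BFS) and share no code with the package internals.

# level array with 0 outside the mask, cropped like the package does not
# need to be: oracles work on the full grid.
oracle_levels <- function(volume, mask, n_bins = 32) {
  x <- volume$values[mask$values == 1L]
  lev <- array(0L, dim(volume$values))
  if (max(x) > min(x)) {
    lev[mask$values == 1L] <-
      pmin(floor(n_bins * (x - min(x)) / (max(x) - min(x))) + 1L, n_bins)
  } else {
    lev[mask$values == 1L] <- 1L
  }
  lev
}

# symmetric co-occurrence counts by direct pair enumeration
bf_glcm <- function(lev, off, ng) {
  d <- dim(lev)
  M <- matrix(0, ng, ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lev[i, j, k]
    if (a == 0) next
    ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
    if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
        kk < 1 || kk > d[3]) next
    b <- lev[ii, jj, kk]
    if (b == 0) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

# runs by walking each line from its start voxel
bf_runs <- function(lev, off) {
  d <- dim(lev)
  inb <- function(v) all(v >= 1 & v <= d)
  runs <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- c(i, j, k)
    g <- lev[i, j, k]
    if (g == 0) next
    prev <- v - off
    if (inb(prev) && lev[prev[1], prev[2], prev[3]] == g) next  # not a start
    len <- 1L
    nxt <- v + off
    while (inb(nxt) && lev[nxt[1], nxt[2], nxt[3]] == g) {
      len <- len + 1L
      nxt <- nxt + off
    }
    runs[[length(runs) + 1L]] <- c(g, len)
  }
  do.call(rbind, runs)
}

bf_runs_matrix <- function(lev, off, ng) {
  r <- bf_runs(lev, off)
  lmax <- max(r[, 2])
  M <- matrix(0, ng, lmax)
  for (q in seq_len(nrow(r))) M[r[q, 1], r[q, 2]] <- M[r[q, 1], r[q, 2]] + 1
  M
}

# 26-connected equal-level zones by queue flood fill
bf_zones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  zones <- list()
  for (s in which(lev > 0L)) {
    if (seen[s]) next
    g <- lev[s]
    queue <- s
    seen[s] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      members <- c(members, cur)
      ci <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        nb <- ci + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        nl <- nb[1] + d[1] * ((nb[2] - 1) + d[2] * (nb[3] - 1))
        if (!seen[nl] && lev[nl] == g) {
          seen[nl] <- TRUE
          queue <- c(queue, nl)
        }
      }
    }
    zones[[length(zones) + 1L]] <- list(level = g, size = length(members),
                                        voxels = members)
  }
  zones
}

bf_zone_matrix <- function(lev, ng) {
  z <- bf_zones(lev)
  smax <- max(vapply(z, `[[`, integer(1), "size"))
  M <- matrix(0, ng, smax)
  for (zz in z) M[zz$level, zz$size] <- M[zz$level, zz$size] + 1
  M
}

# per-voxel minimum city-block distance to any non-ROI voxel, where
# everything outside the grid is non-ROI; computed by direct
# minimisation over the (padded) complement
bf_border_distance <- function(lev) {
  d <- dim(lev)
  pd <- d + 2L
  pad <- array(0L, pd)
  pad[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- lev
  bg <- which(pad == 0L, arr.ind = TRUE)
  roi <- which(pad > 0L, arr.ind = TRUE)
  dist <- array(NA_integer_, d)
  for (q in seq_len(nrow(roi))) {
    v <- roi[q, ]
    dl <- min(abs(bg[, 1] - v[1]) + abs(bg[, 2] - v[2]) +
                abs(bg[, 3] - v[3]))
    dist[v[1] - 1L, v[2] - 1L, v[3] - 1L] <- dl
  }
  dist
}

bf_distance_matrix <- function(lev, ng) {
  z <- bf_zones(lev)
  dist <- bf_border_distance(lev)
  zd <- vapply(z, function(zz) min(dist[zz$voxels]), integer(1))
  dmax <- max(zd)
  M <- matrix(0, ng, dmax)
  for (q in seq_along(z)) {
    M[z[[q]]$level, zd[q]] <- M[z[[q]]$level, zd[q]] + 1
  }
  M
}

# trapezoidal area under the empirical ROC curve
trapezoid_auc <- function(scores, labels) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[labels == 0] >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# two-way ANOVA mean-squares ICC(A,1) via aov()
aov_icc <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  df <- data.frame(v = as.vector(tab),
                   lesion = factor(rep(seq_len(n), k)),
                   variant = factor(rep(seq_len(k), each = n)))
  ms <- anova(aov(v ~ lesion + variant, data = df))$`Mean Sq`
  (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + (k / n) * (ms[2] - ms[3]))
}

# random digital ellipsoid lesion on a 1 mm grid
random_lesion <- function(grid = c(26, 26, 26), rmin = 2.5, rmax = 6) {
  radii <- runif(3, rmin, rmax)
  center <- runif(3, max(radii) + 3, grid - max(radii) - 3)
  make_ellipsoid_mask(center, radii, grid, c(1, 1, 1),
                      lesion_id = "rnd")
}

all_fixtures <- c("constant_5", "checkerboard_4", "two_level_bar",
                  "stripes_5", "mixed_5")
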