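# Texture-matrix construction over a discretised ROI.
#
# All four matrix families work on the cropped level array (sentinel 0
# outside the mask) with a 1-voxel zero margin, so neighbourhood lookups
# never leave the array. Directions are the 13 unique 3D offsets at
# Chebyshev distance 1 (the other 13 are their negations and carry no
# extra information once matrices are symmetrised / runs are undirected).

direction_offsets_13 <- function() {
  g <- expand.grid(i = -1:1, j = -1:1, k = -1:1)
  g <- g[!(g$i == 0 & g$j == 0 & g$k == 0), ]
  keep <- g$k > 0 | (g$k == 0 & (g$j > 0 | (g$j == 0 & g$i > 0)))
  as.matrix(g[keep, , drop = FALSE])
}

cropped_levels <- function(discretized) {
  lev <- discretized$levels
  b <- bbox_of(lev)
  sub <- lev[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3],
             drop = FALSE]
  ds <- dim(sub) + 2L
  out <- array(0L, ds)
  out[1L + seq_len(dim(sub)[1]), 1L + seq_len(dim(sub)[2]),
      1L + seq_len(dim(sub)[3])] <- sub
  out
}

shift_pair <- function(lev, off) {
  d <- dim(lev)
  i <- max(1L, 1L - off[1]):min(d[1], d[1] - off[1])
  j <- max(1L, 1L - off[2]):min(d[2], d[2] - off[2])
  k <- max(1L, 1L - off[3]):min(d[3], d[3] - off[3])
  a <- lev[i, j, k]
  b <- lev[i + off[1], j + off[2], k + off[3]]
  ok <- a > 0L & b > 0L
  list(a = a[ok], b = b[ok])
}

#' Grey-level co-occurrence matrix for one direction
#'
#' Counts of grey-level pairs at the given voxel offset, symmetrised
#' (both scan directions), over in-mask voxel pairs only.
#'
#' @param discretized a [discretize_roi()] result.
#' @param offset integer length-3 voxel offset.
#' @return `n_bins x n_bins` symmetric count matrix.
#' @export
glcm_matrix <- function(discretized, offset) {
  ng <- discretized$n_bins
  lev <- cropped_levels(discretized)
  p <- shift_pair(lev, as.integer(offset))
  m <- matrix(0, ng, ng)
  if (length(p$a)) {
    tab <- tabulate(p$a + ng * (p$b - 1L), nbins = ng * ng)
    m <- matrix(as.numeric(tab), ng, ng)
  }
  m + t(m)
}

#' Grey-level run-length matrix for one direction
#'
#' A run is a maximal set of collinear, consecutive in-mask voxels with
#' equal grey level along the offset direction.
#'
#' @inheritParams glcm_matrix
#' @return `n_bins x max_run_length` count matrix (`r[g, l]` = number of
#'   runs of level `g` and length `l`).
#' @export
glrlm_matrix <- function(discretized, offset) {
  ng <- discretized$n_bins
  lev <- cropped_levels(discretized)
  off <- as.integer(offset)
  idx <- which(lev > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(0, ng, 1))
  s <- sum(off^2)
  t_ <- idx %*% off                      # strictly increasing along a line
  base <- idx * s - t_ %*% t(off)        # constant along a line
  B <- 4L * s * sum(dim(lev)) + 10L
  key <- (base[, 1] + B) + B * ((base[, 2] + B) + B * (base[, 3] + B))
  g <- lev[idx]
  o <- order(key, t_)
  key <- key[o]; tt <- t_[o]; g <- g[o]
  n <- length(g)
  brk <- c(TRUE, key[-1] != key[-n] | tt[-1] != tt[-n] + s |
             g[-1] != g[-n])
  run_id <- cumsum(brk)
  run_len <- tabulate(run_id)
  run_lev <- g[brk]
  lmax <- max(run_len)
  m <- matrix(0, ng, lmax)
  tab <- tabulate(run_lev + ng * (run_len - 1L), nbins = ng * lmax)
  matrix(as.numeric(tab), ng, lmax)
}

# 26-connected components of equal grey level (zones), via union-find.
# Returns per-zone grey level and size, plus a per-voxel zone id aligned
# with `which(lev > 0)` on the cropped grid.
roi_zones <- function(discretized) {
  lev <- cropped_levels(discretized)
  d <- dim(lev)
  vlin <- which(lev > 0L)
  n <- length(vlin)
  pos <- integer(prod(d)); pos[vlin] <- seq_len(n)
  g <- lev[vlin]
  offs <- direction_offsets_13()
  deltas <- offs[, 1] + d[1] * offs[, 2] + d[1] * d[2] * offs[, 3]
  ea <- integer(0); eb <- integer(0)
  for (r in seq_along(deltas)) {
    nb <- vlin + deltas[r]
    pb <- pos[nb]
    ok <- pb > 0L
    ok[ok] <- g[pos[vlin[ok]]] == g[pb[ok]]
    ea <- c(ea, pos[vlin[ok]]); eb <- c(eb, pb[ok])
  }
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(ea)) {
    ra <- find(ea[e]); rb <- find(eb[e])
    if (ra != rb) parent[min(ra, rb)] <- max(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  zid <- match(root, unique(root))
  list(zone_id = zid, voxel_lin = vlin, grid_dim = d,
       zone_level = g[!duplicated(zid)][order(unique(zid))],
       zone_size = tabulate(zid), grey = g)
}

#' Grey-level size-zone matrix
#'
#' Zones are 26-connected components of equal grey level within the ROI.
#'
#' @inheritParams glcm_matrix
#' @return `n_bins x max_zone_size` count matrix.
#' @export
glszm_matrix <- function(discretized) {
  z <- roi_zones(discretized)
  ng <- discretized$n_bins
  smax <- max(z$zone_size)
  tab <- tabulate(z$zone_level + ng * (z$zone_size - 1L), nbins = ng * smax)
  matrix(as.numeric(tab), ng, smax)
}

# City-block (6-connected) distance of every ROI voxel to the nearest
# non-ROI voxel, counting voxels just inside the border as distance 1.
# Outside the image grid counts as background. Multi-source layer
# peeling (equivalent to repeated 6-connected erosion).
roi_border_distance <- function(lev) {
  d <- dim(lev)
  inroi <- lev > 0L
  dist <- array(NA_integer_, d)
  remaining <- inroi
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    # voxels of `remaining` with a 6-neighbour outside `remaining`
    sh <- function(m, ax, by) {
      out <- array(FALSE, d)
      idx <- lapply(d, seq_len)
      src <- idx; src[[ax]] <- idx[[ax]] - by
      keep <- src[[ax]] >= 1L & src[[ax]] <= d[ax]
      tgt <- idx; tgt[[ax]] <- idx[[ax]][keep]
      src[[ax]] <- src[[ax]][keep]
      out[tgt[[1]], tgt[[2]], tgt[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
      out
    }
    core <- remaining
    for (ax in 1:3) for (by in c(-1L, 1L)) {
      core <- core & sh(remaining, ax, by)
    }
    border <- remaining & !core
    if (!any(border)) border <- remaining   # last interior shell
    dist[border] <- k
    remaining <- remaining & !border
  }
  dist
}

#' Grey-level distance-zone matrix
#'
#' Same zones as [glszm_matrix()]; each zone's distance is the minimum
#' city-block distance of its voxels to the ROI border (border voxels
#' have distance 1).
#'
#' @inheritParams glcm_matrix
#' @return `n_bins x max_distance` count matrix (`m[g, d]` = number of
#'   zones of level `g` at distance `d`).
#' @export
gldzm_matrix <- function(discretized) {
  z <- roi_zones(discretized)
  lev <- cropped_levels(discretized)
  dist <- roi_border_distance(lev)
  vd <- dist[z$voxel_lin]
  zone_dist <- vapply(split(vd, z$zone_id), min, integer(1))
  ng <- discretized$n_bins
  dmax <- max(zone_dist)
  tab <- tabulate(z$zone_level + ng * (zone_dist - 1L), nbins = ng * dmax)
  matrix(as.numeric(tab), ng, dmax)
}
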