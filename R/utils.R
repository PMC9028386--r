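`%||%` <- function(a, b) if (is.null(a)) b else a

# Periodic 3D Gaussian convolution via FFT. `sigma_vox` is per-axis in
# voxel units; zero sigma along an axis leaves that axis untouched.
gaussian_smooth_3d <- function(values, sigma_vox) {
  d <- dim(values)
  if (all(sigma_vox <= 0)) return(values)
  kern1 <- function(n, s) {
    if (s <= 0) return(c(1, rep(0, n - 1)))
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  K <- outer(outer(kern1(d[1], sigma_vox[1]), kern1(d[2], sigma_vox[2])),
             kern1(d[3], sigma_vox[3]))
  dim(K) <- d
  out <- Re(fft(fft(values) * fft(K), inverse = TRUE)) / prod(d)
  dim(out) <- d
  out
}

# Deterministic per-stage seed derivation from a master seed. Keeps the
# derived value inside 32-bit integer range.
derive_seed <- function(master, stage) {
  offs <- c(simulate = 101L, resample = 211L, perturb = 307L,
            extract = 401L, stability = 503L, pair = 601L, model = 701L)
  s <- offs[[stage]] %||% 997L
  as.integer((as.numeric(master) * 1009 + s) %% 2147483647)
}

linind <- function(i, j, k, d) i + d[1] * ((j - 1) + d[2] * (k - 1))

bbox_of <- function(values, margin = 0L) {
  idx <- which(values != 0L, arr.ind = TRUE)
  d <- dim(values)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  list(lo = lo, hi = hi)
}

crop_bbox <- function(values, margin = 0L) {
  b <- bbox_of(values, margin)
  values[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3], drop = FALSE]
}
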