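#' Deterministic micro-phantoms for texture oracle checks
#'
#' Tiny hard-coded volume/mask pairs (at most 6^3 voxels, 1 mm grid)
#' whose texture matrices can be enumerated by hand or brute force:
#'
#' * `constant_5` — 5^3 volume of a single value, full mask.
#' * `checkerboard_4` — 4^3 two-level parity checkerboard, full mask.
#' * `two_level_bar` — 1x1x4 bar of values 10,10,20,20 inside a 3x3x4
#'   grid, masked to the bar only.
#' * `stripes_5` — 5^3 volume whose value equals the first-axis index
#'   (planes of constant level), full mask.
#' * `mixed_5` — 5^3 deterministic pseudo-texture
#'   `((7i + 11j + 13k) mod 5) + 1`, full mask.
#'
#' @param name fixture name.
#' @return List with elements `volume` ([image_volume()]) and `mask`
#'   ([lesion_mask()]).
#' @export
fixture_phantom <- function(name) {
  registry <- c("constant_5", "checkerboard_4", "two_level_bar",
                "stripes_5", "mixed_5")
  if (!name %in% registry) {
    stop("unknown fixture '", name, "'; available: ",
         paste(registry, collapse = ", "))
  }
  full <- function(d) array(1L, d)
  vm <- switch(
    name,
    constant_5 = list(array(5, c(5, 5, 5)), full(c(5, 5, 5))),
    checkerboard_4 = {
      d <- c(4, 4, 4)
      idx <- which(array(TRUE, d), arr.ind = TRUE)
      v <- array(1 + (rowSums(idx) %% 2), d)
      list(v, full(d))
    },
    two_level_bar = {
      d <- c(3, 3, 4)
      v <- array(0, d)
      m <- array(0L, d)
      v[2, 2, ] <- c(10, 10, 20, 20)
      m[2, 2, ] <- 1L
      list(v, m)
    },
    stripes_5 = {
      d <- c(5, 5, 5)
      v <- array(rep(1:5, times = 25), d)
      list(v, full(d))
    },
    mixed_5 = {
      d <- c(5, 5, 5)
      idx <- which(array(TRUE, d), arr.ind = TRUE)
      v <- array(((7 * idx[, 1] + 11 * idx[, 2] + 13 * idx[, 3]) %% 5) + 1,
                 d)
      list(v, full(d))
    })
  list(volume = image_volume(vm[[1]], c(1, 1, 1), modality = "PET_SUV"),
       mask = lesion_mask(vm[[2]], c(1, 1, 1), patient_id = "fixture",
                          lesion_id = name, modality = "PET_SUV"))
}
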