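# Every texture matrix must equal independent brute-force enumeration
# (pair counting, run walking, flood-fill zones, border-distance
# minimisation) on all micro-fixtures, exactly.

test_that("GLCM matrices equal brute-force pair enumeration", {
  offs <- psmarad:::direction_offsets_13()
  for (nm in all_fixtures) {
    fx <- fixture_phantom(nm)
    d <- discretize_roi(fx$volume, fx$mask)
    lev <- oracle_levels(fx$volume, fx$mask)
    for (r in seq_len(nrow(offs))) {
      expect_identical(glcm_matrix(d, offs[r, ]),
                       bf_glcm(lev, offs[r, ], d$n_bins),
                       info = paste(nm, "dir", r))
    }
  }
})

test_that("GLRLM matrices equal brute-force run walking", {
  offs <- psmarad:::direction_offsets_13()
  for (nm in all_fixtures) {
    fx <- fixture_phantom(nm)
    d <- discretize_roi(fx$volume, fx$mask)
    lev <- oracle_levels(fx$volume, fx$mask)
    for (r in seq_len(nrow(offs))) {
      expect_identical(glrlm_matrix(d, offs[r, ]),
                       bf_runs_matrix(lev, offs[r, ], d$n_bins),
                       info = paste(nm, "dir", r))
    }
  }
})

test_that("GLSZM matrices equal flood-fill zone enumeration", {
  for (nm in all_fixtures) {
    fx <- fixture_phantom(nm)
    d <- discretize_roi(fx$volume, fx$mask)
    lev <- oracle_levels(fx$volume, fx$mask)
    expect_identical(glszm_matrix(d), bf_zone_matrix(lev, d$n_bins),
                     info = nm)
  }
  # two disjoint equal-level blobs are two zones
  v <- array(1, c(5, 5, 5))
  m <- array(0L, c(5, 5, 5))
  m[1:2, 1:2, 1] <- 1L
  m[4:5, 4:5, 5] <- 1L
  d <- discretize_roi(image_volume(v, c(1, 1, 1)),
                      lesion_mask(m, c(1, 1, 1), lesion_id = "blobs"))
  expect_identical(sum(glszm_matrix(d)), 2)
})

test_that("GLDZM matrices equal brute-force border distances", {
  for (nm in all_fixtures) {
    fx <- fixture_phantom(nm)
    d <- discretize_roi(fx$volume, fx$mask)
    lev <- oracle_levels(fx$volume, fx$mask)
    expect_identical(gldzm_matrix(d), bf_distance_matrix(lev, d$n_bins),
                     info = nm)
  }
  # single-voxel ROI: one zone at distance 1, ZDNU = 1
  v <- array(1, c(3, 3, 3))
  m <- array(0L, c(3, 3, 3)); m[2, 2, 2] <- 1L
  d1 <- discretize_roi(image_volume(v, c(1, 1, 1)),
                       lesion_mask(m, c(1, 1, 1), lesion_id = "s"))
  f1 <- gldzm_features(d1)
  expect_identical(dim(gldzm_matrix(d1)), c(32L, 1L))
  expect_equal(unname(f1["gldzm.zdnu"]), 1)
  # constant 3^3 ROI: one zone touching the border, distance 1
  m3 <- lesion_mask(array(1L, c(3, 3, 3)), c(1, 1, 1), lesion_id = "c3")
  d3 <- discretize_roi(image_volume(array(4, c(3, 3, 3)), c(1, 1, 1)), m3)
  M3 <- gldzm_matrix(d3)
  expect_identical(sum(M3), 1)
  expect_identical(which(M3 > 0, arr.ind = TRUE)[1, 2], c(col = 1L))
})

test_that("texture features derived from matrices match hand formulas", {
  # constant 1x1xN bar: one run of length N along the bar, run
  # percentage 1/N in that direction
  fx <- fixture_phantom("two_level_bar")
  d <- discretize_roi(fx$volume, fx$mask)
  R <- glrlm_matrix(d, c(0, 0, 1))
  expect_identical(sum(R), 2)          # two runs (one per level)
  expect_identical(R[1, 2], 1)         # level 1, length 2
  expect_identical(R[32, 2], 1)

  # joint maximum by direct pair count on the bar along z:
  # pairs (1,1), (1,32), (32,32) -> symmetrised counts 2,2,2, max 1/3
  G <- glcm_matrix(d, c(0, 0, 1))
  expect_identical(G[1, 1], 2)
  expect_identical(G[1, 32], 1)
  p <- G / sum(G)
  expect_equal(max(p), 1 / 3)

  # grey-level label permutation leaves joint entropy unchanged
  fmix <- fixture_phantom("mixed_5")
  dmix <- discretize_roi(fmix$volume, fmix$mask, n_bins = 5)
  vperm <- fmix$volume
  # map intensities 1..5 -> 5,3,1,2,4 (a permutation of the labels)
  vperm$values <- c(5, 3, 1, 2, 4)[fmix$volume$values]
  dim(vperm$values) <- dim(fmix$volume$values)
  dperm <- discretize_roi(vperm, fmix$mask, n_bins = 5)
  f1 <- glcm_features(dmix)
  f2 <- glcm_features(dperm)
  expect_equal(f1["glcm.joint_entropy"], f2["glcm.joint_entropy"],
               tolerance = 1e-12)

  # checkerboard: along axis directions every run has length 1
  cb <- fixture_phantom("checkerboard_4")
  dcb <- discretize_roi(cb$volume, cb$mask)
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    R <- glrlm_matrix(dcb, ax)
    expect_identical(ncol(R), 1L, info = paste(ax, collapse = ","))
  }

  # normalisation: probability-normalised matrices sum to 1
  for (nm in all_fixtures) {
    fx2 <- fixture_phantom(nm)
    d2 <- discretize_roi(fx2$volume, fx2$mask)
    G2 <- glcm_matrix(d2, c(1, 0, 0))
    if (sum(G2) > 0) expect_equal(sum(G2 / sum(G2)), 1, tolerance = 1e-12)
  }
})

test_that("zone counts survive random ROI shapes", {
  set.seed(99)
  for (rep in 1:5) {
    d <- c(5, 5, 5)
    vals <- array(sample(1:3, prod(d), replace = TRUE), d)
    mvals <- array(rbinom(prod(d), 1, 0.7), d)
    if (sum(mvals) < 2) next
    vol <- image_volume(vals + 0, c(1, 1, 1))
    msk <- lesion_mask(mvals, c(1, 1, 1), lesion_id = "r")
    disc <- discretize_roi(vol, msk, n_bins = 3)
    lev <- oracle_levels(vol, msk, n_bins = 3)
    expect_identical(glszm_matrix(disc), bf_zone_matrix(lev, 3))
    expect_identical(gldzm_matrix(disc), bf_distance_matrix(lev, 3))
    offs <- psmarad:::direction_offsets_13()
    for (r in c(1, 5, 9, 13)) {
      expect_identical(glcm_matrix(disc, offs[r, ]),
                       bf_glcm(lev, offs[r, ], 3))
      expect_identical(glrlm_matrix(disc, offs[r, ]),
                       bf_runs_matrix(lev, offs[r, ], 3))
    }
  }
})
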