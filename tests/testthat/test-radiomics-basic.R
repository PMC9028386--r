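test_that("grey-level discretisation follows the 32-bin min-max rule", {
  vals <- array(seq(0, 320, length.out = 5^3), c(5, 5, 5))
  vol <- image_volume(vals, c(1, 1, 1))
  msk <- lesion_mask(array(1L, c(5, 5, 5)), c(1, 1, 1), lesion_id = "m")
  d <- discretize_roi(vol, msk)
  # x = 160 on [0, 320]: floor(32 * 160/320) + 1 = 17
  i160 <- which.min(abs(vals - 160))
  expect_identical(d$levels[i160], 17L)
  expect_identical(d$levels[which.max(vals)], 32L)   # max clamps to top
  expect_identical(min(d$levels[msk$values == 1L]), 1L)

  cst <- fixture_phantom("constant_5")
  dc <- discretize_roi(cst$volume, cst$mask)
  expect_true(all(dc$levels[cst$mask$values == 1L] == 1L))
  expect_true(all(dc$levels[cst$mask$values == 0L] == 0L))
})

test_that("first-order features match hand computation", {
  vol <- image_volume(array(c(1, 2, 3, 4, 0, 0, 0, 0), c(2, 2, 2)),
                      c(1, 1, 1))
  msk <- lesion_mask(array(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
                           c(2, 2, 2)), c(1, 1, 1), lesion_id = "m")
  f <- first_order_features(vol, msk)
  expect_equal(unname(f["stat.mean"]), 2.5)
  expect_equal(unname(f["stat.variance"]), 1.25)   # population variance
  expect_equal(unname(f["stat.energy"]), 1 + 4 + 9 + 16)
  expect_equal(unname(f["stat.range"]), 3)
  # symmetric values: zero skewness
  expect_lt(abs(f["stat.skewness"]), 1e-12)

  cst <- fixture_phantom("constant_5")
  fc <- first_order_features(cst$volume, cst$mask)
  expect_equal(unname(fc["stat.variance"]), 0)
  expect_equal(unname(fc["stat.entropy"]), 0)
  expect_true(is.na(fc["stat.skewness"]))
  expect_true(is.na(fc["stat.kurtosis"]))
})

test_that("intensity-volume histogram follows the %-of-max convention", {
  # half the voxels low, half high
  vol <- image_volume(array(rep(c(1, 2), each = 32), c(4, 4, 4)),
                      c(1, 1, 1))
  msk <- lesion_mask(array(1L, c(4, 4, 4)), c(1, 1, 1), lesion_id = "m")
  f <- ivh_features(vol, msk)
  expect_equal(unname(f["ivh.v10_minus_v90"]), 0.5)
  expect_equal(unname(f["ivh.i10"]), 2)

  cst <- fixture_phantom("constant_5")
  fc <- ivh_features(cst$volume, cst$mask)
  expect_equal(unname(fc["ivh.v10_minus_v90"]), 0)

  # positive rescaling preserves intensity fractions, so V10/V90 are
  # unchanged
  vol2 <- vol
  vol2$values <- vol$values * 7
  f2 <- ivh_features(vol2, msk)
  expect_equal(unname(f2["ivh.v10"]), unname(f["ivh.v10"]))
  expect_equal(unname(f2["ivh.v90"]), unname(f["ivh.v90"]))
})

test_that("morphology features hit analytic limits", {
  cu <- lesion_mask(array(1L, c(10, 10, 10)), c(1, 1, 1),
                    lesion_id = "cube")
  mc <- morphology_features(cu)
  expect_equal(unname(mc["morph.volume"]), 1000)
  expect_equal(unname(mc["morph.volume_density_aabb"]), 1)

  e <- make_ellipsoid_mask(c(12, 12, 12), c(8, 4, 4), c(24, 24, 24),
                           c(1, 1, 1), lesion_id = "e")
  me <- morphology_features(e)
  expect_lt(abs(me["morph.elongation"] - 0.5) / 0.5, 0.1)
  expect_lt(abs(me["morph.flatness"] - 0.5) / 0.5, 0.1)
  expect_lt(abs(me["morph.inverse_elongation"] - 2) / 2, 0.1)

  # translation invariance
  e2 <- make_ellipsoid_mask(c(10, 13, 11), c(8, 4, 4), c(24, 24, 24),
                            c(1, 1, 1), lesion_id = "e2")
  me2 <- morphology_features(e2)
  expect_equal(unname(me2["morph.volume"]), unname(me["morph.volume"]))
  expect_equal(unname(me2["morph.elongation"]),
               unname(me["morph.elongation"]), tolerance = 1e-6)

  # tiny masks: PCA features flagged missing
  tri <- lesion_mask(array(c(1L, 1L, 1L, rep(0L, 24)), c(3, 3, 3)),
                     c(1, 1, 1), lesion_id = "t")
  mt <- morphology_features(tri)
  expect_true(is.na(mt["morph.elongation"]))
  expect_false(is.na(mt["morph.volume"]))
})

test_that("extract_all is complete, deterministic and degeneracy-safe", {
  reg <- feature_registry()
  fx <- fixture_phantom("mixed_5")
  f1 <- extract_all(fx$volume, fx$mask)
  f2 <- extract_all(fx$volume, fx$mask)
  expect_identical(names(f1), reg$feature)
  expect_identical(f1, f2)
  expect_false(anyNA(f1))

  cst <- fixture_phantom("constant_5")
  fc <- extract_all(cst$volume, cst$mask)
  expect_identical(names(fc), reg$feature)
  # documented degenerate values on a constant ROI
  expect_true(is.na(fc["stat.skewness"]))
  expect_true(is.na(fc["glcm.correlation"]))
  expect_true(is.na(fc["glcm.info_corr1"]))
  expect_equal(unname(fc["glcm.joint_maximum"]), 1)
  expect_equal(unname(fc["glszm.zone_pct"]), 1 / 125)
})

test_that("discretised features are intensity-shift invariant", {
  fx <- fixture_phantom("mixed_5")
  v2 <- fx$volume
  v2$values <- 3 * v2$values + 17       # order-preserving affine map
  f1 <- extract_all(fx$volume, fx$mask)
  f2 <- extract_all(v2, fx$mask)
  disc_keys <- grep("^(glcm|glrlm|glszm|gldzm)\\.|^stat\\.(entropy|uniformity|dp90)",
                    names(f1), value = TRUE)
  expect_equal(f1[disc_keys], f2[disc_keys], tolerance = 1e-12)
})

test_that("averaged GLCM/GLRLM features are 90-degree rotation invariant", {
  fx <- fixture_phantom("mixed_5")
  rot <- function(a) aperm(a[, dim(a)[2]:1, ], c(2, 1, 3))  # 90 deg in xy
  vr <- image_volume(rot(fx$volume$values), c(1, 1, 1))
  mr <- lesion_mask(rot(fx$mask$values), c(1, 1, 1), lesion_id = "r")
  f1 <- extract_all(fx$volume, fx$mask)
  f2 <- extract_all(vr, mr)
  keys <- grep("^(glcm|glrlm)\\.", names(f1), value = TRUE)
  expect_equal(f1[keys], f2[keys], tolerance = 1e-12)
})
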