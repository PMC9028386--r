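test_that("ellipsoid masks match analytic volume and symmetries", {
  b <- make_ellipsoid_mask(c(15, 15, 15), c(5, 5, 5), c(30, 30, 30),
                           c(1, 1, 1), lesion_id = "b")
  expect_lt(abs(sum(b$values) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125),
            0.1)
  # sphere invariant under radius axis permutation
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    b2 <- make_ellipsoid_mask(c(15, 15, 15), c(5, 5, 5)[perm],
                              c(30, 30, 30), c(1, 1, 1), lesion_id = "b")
    expect_identical(b2$values, b$values)
  }
  # sub-voxel radii: degenerate flag, not silence
  tiny <- make_ellipsoid_mask(c(15.01, 15.01, 15.01), c(.3, .3, .3),
                              c(30, 30, 30), c(1, 1, 1), lesion_id = "t")
  expect_true(tiny$degenerate)
  expect_error(make_ellipsoid_mask(c(1, 1, 1), c(-1, 2, 2), c(9, 9, 9),
                                   c(1, 1, 1)))
})

test_that("textured fields hit their requested moments and seeds", {
  v0 <- textured_volume(c(20, 20, 20), c(1, 1, 1), mean = 5,
                        amplitude = 0, correlation_length_mm = 3,
                        seed = 1)
  expect_true(all(v0$values == 5))

  v <- textured_volume(c(50, 50, 50), c(1, 1, 1), mean = 10,
                       amplitude = 2, correlation_length_mm = 2,
                       seed = 42)
  expect_lt(abs(mean(v$values) - 10), 3 * 2 / sqrt(length(v$values)))
  expect_equal(sd(as.numeric(v$values)), 2, tolerance = 1e-9)

  v2 <- textured_volume(c(50, 50, 50), c(1, 1, 1), mean = 10,
                        amplitude = 2, correlation_length_mm = 2,
                        seed = 43)
  expect_true(any(v2$values != v$values))
  v3 <- textured_volume(c(50, 50, 50), c(1, 1, 1), mean = 10,
                        amplitude = 2, correlation_length_mm = 2,
                        seed = 42)
  expect_identical(v3$values, v$values)
})

test_that("PET positivity threshold is inclusive at 3 g/mL", {
  vol <- image_volume(array(2.9, c(8, 8, 8)), c(1, 1, 1))
  m <- lesion_mask(array(1L, c(8, 8, 8)), c(1, 1, 1),
                   patient_id = "P", lesion_id = "L1")
  vols <- list(P = vol)
  expect_length(pet_positivity_filter(list(m), vols), 0)

  vol$values[4, 4, 4] <- 3.0
  vols <- list(P = vol)
  expect_length(pet_positivity_filter(list(m), vols), 1)
  expect_length(pet_positivity_filter(list(m), vols, threshold_suv = 0),
                1)

  empty <- lesion_mask(array(0L, c(8, 8, 8)), c(1, 1, 1),
                       patient_id = "P", lesion_id = "L2",
                       allow_empty = TRUE)
  expect_error(pet_positivity_filter(list(empty), vols), "empty mask")
})

test_that("cohort generation is deterministic and bookkept", {
  cfg <- cohort_config(n_patients = 4, seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  co1 <- generate_cohort(cfg, out_dir = d1)
  co2 <- generate_cohort(cfg, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))

  # one ground-truth row per lesion; mask files match visibility flags
  gt <- co1$ground_truth
  expect_identical(nrow(gt),
                   length(unique(paste(gt$patient_id, gt$lesion_id))))
  n_pet_masks <- sum(vapply(co1$masks, function(m)
    m$modality == "PET_SUV", logical(1)))
  n_mri_masks <- sum(vapply(co1$masks, function(m)
    m$modality == "MRI_ADC", logical(1)))
  expect_identical(n_pet_masks, sum(gt$pet_visible))
  expect_identical(n_mri_masks, sum(gt$mri_visible))
  expect_identical(length(list.files(file.path(d1, "masks"))),
                   n_pet_masks + n_mri_masks)

  # a cohort reloaded from disk matches the in-memory one
  lo <- load_cohort(d1)
  expect_equal(lo$ground_truth$isup_class, gt$isup_class)
  expect_identical(lo$volumes$P01$pet$spacing, co1$volumes$P01$pet$spacing)
})

test_that("configured effect size is realised empirically", {
  mean_lesion_adc <- function(cfg) {
    co <- generate_cohort(cfg)
    gt <- co$ground_truth
    tp <- gt[gt$histology_match & gt$mri_visible, ]
    vals <- vapply(seq_len(nrow(tp)), function(i) {
      r <- tp[i, ]
      v <- co$volumes[[r$patient_id]]$mri
      mk <- make_ellipsoid_mask(c(r$cx, r$cy, r$cz), c(r$rx, r$ry, r$rz),
                                dim(v$values), v$spacing,
                                lesion_id = "gt")
      mean(v$values[mk$values == 1L])
    }, numeric(1))
    list(vals = vals, hi = tp$isup_class >= 2)
  }
  cohen_d <- function(x) {
    a <- x$vals[x$hi]; b <- x$vals[!x$hi]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / sp
  }
  x2 <- mean_lesion_adc(cohort_config(n_patients = 50, lesions_min = 2,
                                      lesions_max = 4, effect_size = 2,
                                      mri_visibility_rate = 1, seed = 5))
  expect_gte(length(x2$vals), 100)
  expect_lt(abs(abs(cohen_d(x2)) - 2), 0.4)   # ADC effect is negative

  x0 <- mean_lesion_adc(cohort_config(n_patients = 40, lesions_min = 2,
                                      lesions_max = 4, effect_size = 0,
                                      mri_visibility_rate = 1, seed = 6))
  expect_lt(abs(cohen_d(x0)), 0.5)            # null case ~ 0
})

test_that("fixtures are registered and NIfTI-stable", {
  expect_error(fixture_phantom("nope"), "constant_5")
  for (nm in all_fixtures) {
    fx <- fixture_phantom(nm)
    f <- withr::local_tempfile(fileext = ".nii.gz")
    write_volume(fx$volume, f)
    expect_identical(read_volume(f)$values, fx$volume$values, info = nm)
  }
  cst <- fixture_phantom("constant_5")
  expect_true(all(cst$volume$values == 5))
  expect_identical(sum(cst$mask$values), 125L)
  cb <- fixture_phantom("checkerboard_4")
  expect_identical(sort(unique(as.numeric(cb$volume$values))), c(1, 2))
})
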