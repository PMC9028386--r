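#' Configuration of a synthetic dual-modality phantom cohort
#'
#' Describes the simulated study: patients with one or more ellipsoidal
#' prostate lesions on textured backgrounds, imaged as a PET SUVbw map
#' and an MRI-ADC map on their native (anisotropic) grids. Grade-group
#' structure follows the intended analysis endpoint (ISUP 1 vs 2+):
#' ISUP 2+ lesions have higher uptake, lower ADC, and rougher texture
#' (shorter correlation length). The configured `effect_size` is the
#' standardised mean difference (Cohen's d) between the two classes'
#' lesion mean intensities, realised by shifting the class means by
#' `effect_size * lesion_sd / 2` about the grand mean (up for SUV, down
#' for ADC).
#'
#' PET and MRI contours of the same lesion are jittered independently in
#' centre and radii so that the pairing rules (containment, >80%
#' partial overlap, no overlap) all occur; some lesions are invisible on
#' one modality, and a configurable fraction of contoured lesions has no
#' histology match (false positives, discarded at the label join).
#'
#' @param n_patients number of patients.
#' @param lesions_min,lesions_max per-patient lesion count range.
#' @param fov_mm cubic field of view per patient, mm.
#' @param spacing_pet,spacing_mri native voxel spacing per modality, mm.
#' @param p_isup1 probability a true lesion is ISUP grade 1.
#' @param radius_range_mm lesion base-radius range, mm.
#' @param radius_aniso relative per-axis radius anisotropy.
#' @param pet_lesion_suv,pet_lesion_sd grand mean / between-lesion SD of
#'   lesion mean SUVbw (g/mL).
#' @param adc_lesion,adc_lesion_sd same for ADC (1e-6 mm^2/s).
#' @param effect_size standardised mean class difference (>= 0).
#' @param texture_corr_isup1_mm,texture_corr_isup2_mm in-lesion texture
#'   correlation length per class, mm.
#' @param pet_texture_amp,adc_texture_amp in-lesion texture SD.
#' @param pet_bg_mean,pet_bg_amp,adc_bg_mean,adc_bg_amp,bg_corr_mm
#'   background field parameters.
#' @param pet_visibility_rate,mri_visibility_rate probability a true
#'   lesion is contoured on each modality.
#' @param false_positive_rate probability a contoured lesion has no
#'   histology match.
#' @param contour_jitter_mm SD of the PET-vs-MRI contour centre
#'   displacement.
#' @param radius_jitter_mm SD of per-modality contour radius error.
#' @param mri_contour_bias_mm systematic enlargement of MRI contours
#'   relative to the true lesion (ADC contours tend to run larger),
#'   which makes full PET-in-MRI containment a realisable pairing
#'   regime.
#' @param pet_invisible_suv mean SUV of lesions not visible on PET
#'   (below the positivity threshold).
#' @param suv_threshold PET positivity threshold on SUVmax (g/mL).
#' @param seed integer master seed.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 28,
                          lesions_min = 1, lesions_max = 4,
                          fov_mm = 60,
                          spacing_pet = c(2.5, 2.5, 4),
                          spacing_mri = c(2.5, 2.5, 3),
                          p_isup1 = 0.4,
                          radius_range_mm = c(3.5, 7),
                          radius_aniso = 0.3,
                          pet_lesion_suv = 6.5, pet_lesion_sd = 1.2,
                          adc_lesion = 800, adc_lesion_sd = 140,
                          effect_size = 1.5,
                          texture_corr_isup1_mm = 3,
                          texture_corr_isup2_mm = 1.5,
                          pet_texture_amp = 1.0, adc_texture_amp = 100,
                          pet_bg_mean = 1.5, pet_bg_amp = 0.4,
                          adc_bg_mean = 1400, adc_bg_amp = 150,
                          bg_corr_mm = 4,
                          pet_visibility_rate = 0.9,
                          mri_visibility_rate = 0.75,
                          false_positive_rate = 0.18,
                          contour_jitter_mm = 1.0,
                          radius_jitter_mm = 0.6,
                          mri_contour_bias_mm = 0.8,
                          pet_invisible_suv = 2.0,
                          suv_threshold = 3,
                          seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(p_isup1, pet_visibility_rate, mri_visibility_rate,
             false_positive_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  check_spacing(spacing_pet); check_spacing(spacing_mri)
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (lesions_min < 1 || lesions_max < lesions_min) {
    stop("invalid lesions_min/lesions_max")
  }
  structure(cfg, class = "cohort_config")
}

#' Stationary textured random field
#'
#' Gaussian random field built by smoothing white noise with a Gaussian
#' kernel of the requested correlation length, then affinely rescaled to
#' the requested mean and marginal SD (`amplitude`). `amplitude = 0`
#' yields a constant volume. Uses the current RNG stream unless `seed`
#' is given.
#'
#' @param dim integer length-3 grid shape.
#' @param spacing voxel spacing, mm.
#' @param mean,amplitude target mean and SD of the field.
#' @param correlation_length_mm texture scale (Gaussian kernel sigma).
#' @param seed optional integer seed.
#' @param modality modality tag of the returned [image_volume()].
#' @return An [image_volume()].
#' @export
textured_volume <- function(dim, spacing, mean, amplitude,
                            correlation_length_mm, seed = NULL,
                            modality = "PET_SUV") {
  stopifnot(amplitude >= 0)
  if (!is.null(seed)) set.seed(seed)
  dim <- as.integer(dim)
  if (amplitude == 0) {
    return(image_volume(array(mean, dim), spacing, modality = modality))
  }
  f <- array(rnorm(prod(dim)), dim)
  f <- gaussian_smooth_3d(f, correlation_length_mm / spacing)
  s <- sd(as.numeric(f))
  f <- if (s > 0) (f - base::mean(f)) / s * amplitude + mean
       else array(mean, dim)
  image_volume(f, spacing, modality = modality)
}

#' Ellipsoidal binary mask
#'
#' A voxel belongs to the mask iff its centre `x` satisfies
#' `sum(((x - center) / radii)^2) <= 1`. Voxel centres sit at
#' `(index - 0.5) * spacing` mm. An empty result (radii below the voxel
#' size) is returned flagged `degenerate`, never silently.
#'
#' @param center_mm,radii_mm ellipsoid centre and semi-axes, mm.
#' @param dim integer grid shape.
#' @param spacing voxel spacing, mm.
#' @param ... metadata passed to [lesion_mask()].
#' @return A [lesion_mask()] (possibly flagged `degenerate`).
#' @export
make_ellipsoid_mask <- function(center_mm, radii_mm, dim, spacing, ...) {
  stopifnot(all(radii_mm > 0))
  dim <- as.integer(dim)
  ax <- lapply(1:3, function(a) {
    ((seq_len(dim[a]) - 0.5) * spacing[a] - center_mm[a]) / radii_mm[a]
  })
  q <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  lesion_mask(array(as.integer(q <= 1), dim), spacing, ...,
              allow_empty = TRUE)
}

#' PET positivity filter
#'
#' A lesion is PET-positive iff the maximum SUVbw inside its contour
#' reaches the threshold (inclusive: a "minimum positivity threshold" is
#' attained at the boundary).
#'
#' @param masks list of PET [lesion_mask()]s.
#' @param volumes named list of PET [image_volume()]s, keyed by
#'   patient id.
#' @param threshold_suv SUVmax threshold in g/mL (default 3).
#' @return The retained subset of `masks`.
#' @export
pet_positivity_filter <- function(masks, volumes, threshold_suv = 3) {
  keep <- vapply(masks, function(m) {
    if (m$degenerate) stop("empty mask for lesion '", m$lesion_id, "'")
    vol <- volumes[[m$patient_id]]
    if (is.null(vol)) stop("no PET volume for patient ", m$patient_id)
    check_aligned(vol, m)
    max(vol$values[m$values == 1L]) >= threshold_suv
  }, logical(1))
  masks[keep]
}

# Draw an ISUP grade group: 1 with probability p1, otherwise 2-5 with
# weights mirroring a high-risk surgical cohort.
draw_isup <- function(p1) {
  if (runif(1) < p1) return(1L)
  sample(2:5, 1, prob = c(8, 3, 5, 1))
}

#' Generate a synthetic dual-modality phantom cohort
#'
#' Realises a [cohort_config()]: per patient one PET-like SUVbw volume
#' and one ADC-like volume on their native grids, per-lesion contour
#' masks per modality where the lesion is visible, and a ground-truth
#' table. Lesion interiors are textured fields whose mean intensity
#' carries the configured class effect; ADC values are clipped at 0.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory; when given, volumes and masks are
#'   written as NIfTI (`volumes/`, `masks/`) along with
#'   `ground_truth.csv` and a YAML snapshot of the configuration.
#' @return An object of class `synthetic_cohort`: list with `volumes`
#'   (per patient, `$pet` and `$mri`), `masks` (list of [lesion_mask()],
#'   native grids), `ground_truth` (data frame), `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)
  dim_pet <- as.integer(round(cfg$fov_mm / cfg$spacing_pet))
  dim_mri <- as.integer(round(cfg$fov_mm / cfg$spacing_mri))
  max_r <- max(cfg$radius_range_mm) * (1 + cfg$radius_aniso)
  margin <- max_r + cfg$radius_jitter_mm + cfg$contour_jitter_mm + 2
  if (2 * margin >= cfg$fov_mm) {
    stop("lesion radius ", max_r, " mm too large for a ", cfg$fov_mm,
         " mm field of view")
  }
  volumes <- list()
  masks <- list()
  gt <- list()
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", p)
    pet <- textured_volume(dim_pet, cfg$spacing_pet, cfg$pet_bg_mean,
                           cfg$pet_bg_amp, cfg$bg_corr_mm,
                           modality = "PET_SUV")
    mri <- textured_volume(dim_mri, cfg$spacing_mri, cfg$adc_bg_mean,
                           cfg$adc_bg_amp, cfg$bg_corr_mm,
                           modality = "MRI_ADC")
    n_les <- if (cfg$lesions_min == cfg$lesions_max) cfg$lesions_min
      else sample(cfg$lesions_min:cfg$lesions_max, 1)
    centers <- matrix(NA_real_, 0, 3)
    for (l in seq_len(n_les)) {
      lid <- sprintf("L%02d", l)
      r_base <- runif(1, cfg$radius_range_mm[1], cfg$radius_range_mm[2])
      radii <- r_base * (1 + runif(3, -cfg$radius_aniso, cfg$radius_aniso))
      center <- NULL
      for (try in 1:100) {
        cand <- runif(3, margin, cfg$fov_mm - margin)
        if (nrow(centers) == 0 ||
            min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >
              2 * max_r + 2) {
          center <- cand; break
        }
      }
      if (is.null(center)) center <- runif(3, margin, cfg$fov_mm - margin)
      centers <- rbind(centers, center)

      histology <- runif(1) >= cfg$false_positive_rate
      isup <- if (histology) draw_isup(cfg$p_isup1) else NA_integer_
      pet_vis <- runif(1) < cfg$pet_visibility_rate
      mri_vis <- runif(1) < cfg$mri_visibility_rate
      is2plus <- isTRUE(isup >= 2)

      # lesion mean intensity: class shift about the grand mean plus a
      # between-lesion random offset
      suv_mu <- if (!histology) rnorm(1, 4.5, 0.8)
        else if (!pet_vis) rnorm(1, cfg$pet_invisible_suv, 0.3)
        else cfg$pet_lesion_suv +
          (if (is2plus) 0.5 else -0.5) * cfg$effect_size *
            cfg$pet_lesion_sd + rnorm(1, 0, cfg$pet_lesion_sd)
      adc_mu <- if (!histology) rnorm(1, 1000, 100)
        else if (!mri_vis) cfg$adc_bg_mean - 100 + rnorm(1, 0, 30)
        else cfg$adc_lesion -
          (if (is2plus) 0.5 else -0.5) * cfg$effect_size *
            cfg$adc_lesion_sd + rnorm(1, 0, cfg$adc_lesion_sd)
      corr_mm <- if (is2plus) cfg$texture_corr_isup2_mm
        else cfg$texture_corr_isup1_mm

      # paint the lesion into both native volumes over its true support
      pet$values <- paint_lesion(pet$values, cfg$spacing_pet, center,
                                 radii, suv_mu, cfg$pet_texture_amp,
                                 corr_mm)
      mri$values <- paint_lesion(mri$values, cfg$spacing_mri, center,
                                 radii, adc_mu, cfg$adc_texture_amp,
                                 corr_mm)

      # per-modality contours: independently jittered centre and radii
      if (pet_vis) {
        masks[[length(masks) + 1L]] <- contour_mask(
          center, radii, cfg, dim_pet, cfg$spacing_pet, pid, lid,
          "PET_SUV", bias = 0)
      }
      if (mri_vis) {
        masks[[length(masks) + 1L]] <- contour_mask(
          center, radii, cfg, dim_mri, cfg$spacing_mri, pid, lid,
          "MRI_ADC", bias = cfg$mri_contour_bias_mm)
      }
      gt[[length(gt) + 1L]] <- data.frame(
        patient_id = pid, lesion_id = lid, isup_class = isup,
        histology_match = histology, pet_visible = pet_vis,
        mri_visible = mri_vis,
        cx = center[1], cy = center[2], cz = center[3],
        rx = radii[1], ry = radii[2], rz = radii[3])
    }
    pet$values[pet$values < 0] <- 0
    mri$values[mri$values < 0] <- 0
    volumes[[pid]] <- list(pet = pet, mri = mri)
  }
  cohort <- structure(
    list(volumes = volumes, masks = masks,
         ground_truth = do.call(rbind, gt), config = cfg),
    class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

paint_lesion <- function(values, spacing, center, radii, mu, amp,
                         corr_mm) {
  d <- dim(values)
  lo <- pmax(floor((center - radii) / spacing), 1)
  hi <- pmin(ceiling((center + radii) / spacing) + 1, d)
  if (any(hi - lo < 0)) {
    stop("lesion at ", paste(round(center), collapse = ","),
         " mm falls outside the image grid")
  }
  sub_dim <- hi - lo + 1
  field <- textured_volume(sub_dim, spacing, mu, amp, corr_mm)$values
  ax <- lapply(1:3, function(a) {
    ((lo[a]:hi[a] - 0.5) * spacing[a] - center[a]) / radii[a]
  })
  q <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  sub <- values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub[q <= 1] <- field[q <= 1]
  values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  values
}

contour_mask <- function(center, radii, cfg, dim, spacing, pid, lid,
                         modality, bias = 0) {
  c_j <- center + rnorm(3, 0, cfg$contour_jitter_mm / sqrt(3))
  r_j <- pmax(radii + bias + rnorm(3, 0, cfg$radius_jitter_mm / 2), 1)
  make_ellipsoid_mask(c_j, r_j, dim, spacing, patient_id = pid,
                      lesion_id = lid, modality = modality,
                      variant = "orig")
}

#' Write / read a synthetic cohort on disk
#'
#' Volumes go to `volumes/<patient>_<PET|ADC>.nii.gz` (32-bit float),
#' masks to `masks/<patient>_<lesion>_<PET|ADC>.nii.gz` (uint8), the
#' ground truth to `ground_truth.csv`, and the configuration snapshot to
#' `config.yaml`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir target directory (created if needed).
#' @return `write_cohort()` the directory, invisibly; `load_cohort()` a
#'   `synthetic_cohort` rebuilt from disk (without the config class).
#' @export
write_cohort <- function(cohort, dir) {
  vdir <- file.path(dir, "volumes"); mdir <- file.path(dir, "masks")
  dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(cohort$volumes)) {
    write_volume(cohort$volumes[[pid]]$pet,
                 file.path(vdir, paste0(pid, "_PET.nii.gz")))
    write_volume(cohort$volumes[[pid]]$mri,
                 file.path(vdir, paste0(pid, "_ADC.nii.gz")))
  }
  for (m in cohort$masks) {
    tag <- if (m$modality == "PET_SUV") "PET" else "ADC"
    write_mask(m, file.path(mdir, paste0(m$patient_id, "_", m$lesion_id,
                                         "_", tag, ".nii.gz")))
  }
  write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
load_cohort <- function(dir) {
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  vfiles <- list.files(file.path(dir, "volumes"), full.names = TRUE)
  pids <- unique(sub("_(PET|ADC)\\.nii\\.gz$", "", basename(vfiles)))
  volumes <- lapply(setNames(pids, pids), function(pid) {
    list(pet = read_volume(file.path(dir, "volumes",
                                     paste0(pid, "_PET.nii.gz")),
                           "PET_SUV"),
         mri = read_volume(file.path(dir, "volumes",
                                     paste0(pid, "_ADC.nii.gz")),
                           "MRI_ADC"))
  })
  mfiles <- list.files(file.path(dir, "masks"), full.names = TRUE)
  masks <- lapply(mfiles, function(f) {
    parts <- strsplit(sub("\\.nii\\.gz$", "", basename(f)), "_")[[1]]
    read_mask(f, if (parts[3] == "PET") "PET_SUV" else "MRI_ADC",
              patient_id = parts[1], lesion_id = parts[2])
  })
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) {
    structure(yaml::read_yaml(cfg_path), class = "cohort_config")
  } else NULL
  structure(list(volumes = volumes, masks = masks, ground_truth = gt,
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf(paste0("<synthetic_cohort> %d patients, %d lesions ",
                     "(%d PET-visible, %d MRI-visible, %d histology-",
                     "matched)\n"),
              length(x$volumes), nrow(gt), sum(gt$pet_visible),
              sum(gt$mri_visible), sum(gt$histology_match)))
  invisible(x)
}
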