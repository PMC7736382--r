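# Synthetic PET/CT phantoms: an elliptical soft-tissue body in air
# containing uniform-uptake ellipsoidal lesions on a low background,
# benign hot structures (salivary-gland / tonsil / ureter analogues),
# and bone, with Gaussian PSF blur and additive Gaussian noise on PET.

#' Phantom generator configuration
#'
#' Ranges are sampled uniformly per phantom/structure. Defaults emulate
#' FDG-avid nodal lymphoma on a 2 mm isotropic grid: lesions at SUV 3-15
#' on a background of SUV 0.5-1.5, small benign hot structures at SUV
#' 2.5-8, bone at 400 HU inside a 40 HU soft-tissue body, a 6 mm FWHM
#' isotropic Gaussian point-spread function and SUV-space Gaussian noise
#' of sigma 0.2.
#'
#' @param grid_size voxels per axis (cubic grid).
#' @param spacing isotropic voxel size, mm.
#' @param n_lesions integer range (min, max).
#' @param lesion_radius per-axis semi-axis range, mm.
#' @param lesion_suv lesion uptake range (SUV).
#' @param background_suv body-background uptake range (one constant per
#'   phantom).
#' @param n_benign_hot integer range of benign hot structures.
#' @param benign_radius,benign_suv geometry/uptake ranges of benign
#'   structures.
#' @param bone_structures number of bone ellipsoids.
#' @param bone_radius bone semi-axis range, mm.
#' @param bone_hu,soft_tissue_hu,air_hu CT values.
#' @param psf_fwhm isotropic PSF full width at half maximum, mm (0
#'   disables blur).
#' @param noise_sigma additive Gaussian PET noise, SUV (0 disables).
#' @param ct_noise_sigma additive CT noise, HU.
#' @param roi_margin template-ROI dilation around each lesion's bounding
#'   box, voxels.
#' @param irregular_lesions when `TRUE`, each lesion is the union of its
#'   base ellipsoid with one or two overlapping sub-ellipsoids (lobulated
#'   shapes); the default keeps single ellipsoids, whose volumes have
#'   simple analytic oracles.
#' @param seed RNG seed; phantoms are bit-identical given the seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_size = 64, spacing = 2,
                           n_lesions = c(2, 5), lesion_radius = c(5, 15),
                           lesion_suv = c(3, 15), background_suv = c(0.5, 1.5),
                           n_benign_hot = c(1, 3), benign_radius = c(3, 6),
                           benign_suv = c(2.5, 8),
                           bone_structures = 2, bone_radius = c(4, 10),
                           bone_hu = 400, soft_tissue_hu = 40, air_hu = -1000,
                           psf_fwhm = 6, noise_sigma = 0.2,
                           ct_noise_sigma = 10, roi_margin = 3,
                           irregular_lesions = FALSE, seed = 1L) {
  rng2 <- function(x) if (length(x) == 1) c(x, x) else x
  cfg <- list(grid_size = as.integer(grid_size), spacing = spacing,
              n_lesions = rng2(n_lesions), lesion_radius = rng2(lesion_radius),
              lesion_suv = rng2(lesion_suv),
              background_suv = rng2(background_suv),
              n_benign_hot = rng2(n_benign_hot),
              benign_radius = rng2(benign_radius),
              benign_suv = rng2(benign_suv),
              bone_structures = as.integer(bone_structures),
              bone_radius = rng2(bone_radius), bone_hu = bone_hu,
              soft_tissue_hu = soft_tissue_hu, air_hu = air_hu,
              psf_fwhm = psf_fwhm, noise_sigma = noise_sigma,
              ct_noise_sigma = ct_noise_sigma,
              roi_margin = as.integer(roi_margin),
              irregular_lesions = isTRUE(irregular_lesions),
              seed = as.integer(seed))
  if (cfg$lesion_suv[1] <= cfg$background_suv[2])
    stop("lesion SUV range must lie above the background SUV range")
  if (cfg$psf_fwhm < 0 || cfg$noise_sigma < 0)
    stop("psf_fwhm and noise_sigma must be >= 0")
  structure(cfg, class = "phantom_config")
}

ellipsoid_mask <- function(d, spacing, center_mm, semi_mm) {
  q <- lapply(1:3, function(a) (((seq_len(d[a]) - 1) * spacing[a] -
                                   center_mm[a]) / semi_mm[a])^2)
  m <- outer(outer(q[[1]], q[[2]], `+`), q[[3]], `+`) <= 1
  array(m, d)
}

dilate_box1 <- function(m) {
  # 3x3x3 box dilation via sequential 1-voxel dilation per axis
  for (ax in 1:3)
    m <- m | shift_pad_false(m, ax, +1) | shift_pad_false(m, ax, -1)
  m
}

gaussian_blur <- function(arr, spacing, fwhm) {
  if (fwhm <= 0) return(arr)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    n <- dim(arr)[ax]
    s <- sigma_mm / spacing[ax]
    pos <- seq_len(n)
    k <- outer(pos, pos, function(i, j) exp(-((i - j)^2) / (2 * s^2)))
    k[abs(outer(pos, pos, `-`)) > ceiling(4 * s)] <- 0
    k <- k / rowSums(k)  # row renormalisation = edge-replicating behaviour
    arr <- apply_axis(arr, k, ax)
  }
  arr
}

place_ellipsoids <- function(n, radius_range, d, spacing, allowed, avoid,
                             max_tries = 1000, irregular = FALSE) {
  # draws n non-overlapping (unions of) ellipsoids fully inside
  # `allowed`, 26-disconnected from `avoid` (and from each other)
  masks <- vector("list", n)
  occ <- avoid
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      semi <- runif(3, radius_range[1], radius_range[2])
      ctr <- runif(3, 0, (d - 1) * spacing)
      m <- ellipsoid_mask(d, spacing, ctr, semi)
      if (!any(m)) next
      if (irregular) {
        vox <- which(m, arr.ind = TRUE)
        for (j in seq_len(sample(1:2, 1))) {
          sub_ctr <- (vox[sample.int(nrow(vox), 1), ] - 1) * spacing
          m <- m | ellipsoid_mask(d, spacing, sub_ctr,
                                  semi * runif(3, 0.4, 0.7))
        }
      }
      if (any(m & !allowed)) next
      if (any(dilate_box1(m) & occ)) next
      masks[[i]] <- list(mask = m, center_mm = ctr, semi_mm = semi)
      occ <- occ | m
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place structure ", i, " of ", n, " after ", max_tries,
           " attempts; reduce counts or radii")
  }
  masks
}

rint <- function(rg) if (rg[1] == rg[2]) rg[1] else sample(rg[1]:rg[2], 1)

#' Generate one synthetic PET/CT phantom
#'
#' Builds the body, bone, lesions, benign hot structures and template
#' ROIs, then applies PSF blur and noise to the PET. The returned truth
#' records planted geometry and the ground-truth feature set computed
#' from the merged lesion mask on the pre-blur PET (so planted MTV equals
#' [extract_features()] MTV on the truth mask exactly).
#'
#' @param config a [phantom_config()].
#' @return A list (one case) with `case_id`, `pet`, `ct`, `rois`
#'   (template-ROI `LABEL` volume) and `truth` (lesion/benign/bone masks,
#'   per-lesion bookkeeping, pre-blur PET and the truth `feature_set`).
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  d <- rep(config$grid_size, 3L)
  sp <- rep(config$spacing, 3L)
  extent <- d * sp

  body <- ellipsoid_mask(d, sp, extent / 2, extent * 0.44)
  interior <- ellipsoid_mask(d, sp, extent / 2, extent * 0.36)

  ct <- array(config$air_hu, d)
  ct[body] <- config$soft_tissue_hu

  bones <- place_ellipsoids(config$bone_structures, config$bone_radius, d, sp,
                            allowed = interior, avoid = array(FALSE, d))
  bone_mask <- array(FALSE, d)
  for (b in bones) bone_mask <- bone_mask | b$mask
  ct[bone_mask] <- config$bone_hu

  n_les <- rint(config$n_lesions)
  lesions <- place_ellipsoids(n_les, config$lesion_radius, d, sp,
                              allowed = interior & !bone_mask,
                              avoid = bone_mask,
                              irregular = config$irregular_lesions)
  merged <- array(FALSE, d)
  for (l in lesions) merged <- merged | l$mask

  # template ROIs: dilated bounding boxes around each lesion, overlapping
  # boxes merged into one region id
  boxes <- lapply(lesions, function(l) {
    idx <- which(l$mask, arr.ind = TRUE)
    lo <- pmax(apply(idx, 2, min) - config$roi_margin, 1)
    hi <- pmin(apply(idx, 2, max) + config$roi_margin, d)
    rbind(lo, hi)
  })
  overlap <- function(a, b) all(a[1, ] <= b[2, ] & b[1, ] <= a[2, ])
  groups <- seq_along(boxes)
  repeat {
    changed <- FALSE
    for (i in seq_along(boxes)) for (j in seq_along(boxes)) {
      if (groups[i] != groups[j] && overlap(boxes[[i]], boxes[[j]])) {
        groups[groups == groups[j]] <- groups[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  rois <- array(0, d)
  for (gi in seq_along(unique(groups))) {
    g <- unique(groups)[gi]
    for (i in which(groups == g)) {
      b <- boxes[[i]]
      rois[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2], b[1, 3]:b[2, 3]] <- gi
    }
  }

  n_ben <- rint(config$n_benign_hot)
  benigns <- place_ellipsoids(n_ben, config$benign_radius, d, sp,
                              allowed = interior & !bone_mask & rois == 0,
                              avoid = merged | bone_mask | rois > 0)
  benign_mask <- array(FALSE, d)
  for (b in benigns) benign_mask <- benign_mask | b$mask

  bg <- runif(1, config$background_suv[1], config$background_suv[2])
  pet0 <- array(0, d)
  pet0[body] <- bg
  les_suv <- runif(n_les, config$lesion_suv[1], config$lesion_suv[2])
  for (i in seq_len(n_les)) pet0[lesions[[i]]$mask] <- les_suv[i]
  for (b in benigns) pet0[b$mask] <- runif(1, config$benign_suv[1],
                                           config$benign_suv[2])

  pet <- gaussian_blur(pet0, sp, config$psf_fwhm)
  if (config$noise_sigma > 0)
    pet <- pet + rnorm(length(pet), 0, config$noise_sigma)
  pet <- pmax(array(pet, d), 0)
  if (config$ct_noise_sigma > 0) {
    ct <- ct + rnorm(length(ct), 0, config$ct_noise_sigma)
    ct <- pmin(pmax(ct, -1024), 3000)
  }

  vox_cm3 <- voxel_volume_cm3(sp)
  pet0_vol <- volume(pet0, sp, c(0, 0, 0), "PET_SUV")
  truth_features <- extract_features(pet0_vol, merged)
  lesion_info <- lapply(seq_len(n_les), function(i) {
    idx <- which(lesions[[i]]$mask, arr.ind = TRUE) - 1L
    list(volume_cm3 = sum(lesions[[i]]$mask) * vox_cm3, suv = les_suv[i],
         centroid_mm = as.numeric(colMeans(idx) * sp))
  })

  list(case_id = sprintf("phantom_%06d", config$seed),
       pet = volume(pet, sp, c(0, 0, 0), "PET_SUV"),
       ct = volume(array(ct, d), sp, c(0, 0, 0), "CT_HU"),
       rois = volume(rois, sp, c(0, 0, 0), "LABEL"),
       truth = list(
         lesion_masks = lapply(lesions, `[[`, "mask"),
         merged_mask = merged,
         lesions = lesion_info,
         benign_mask = benign_mask,
         bone_mask = bone_mask,
         background_suv = bg,
         pet_noiseless = pet0_vol,
         features = truth_features,
         config = config))
}

#' Generate a phantom cohort
#'
#' Per-case seeds are derived deterministically from the master seed, so
#' a fixed master seed reproduces the identical cohort. When `dir` is
#' given, each case is written to `case_XXXX/` as `pet.nii.gz`,
#' `ct.nii.gz`, `reference.nii.gz` (built with [build_reference()]),
#' `rois.nii.gz` and `truth.json`.
#'
#' @param n number of phantoms (>= 1).
#' @param config a [phantom_config()] shared by all cases (its `seed` is
#'   ignored in favour of per-case derived seeds).
#' @param seed master seed.
#' @param dir optional output directory.
#' @return Invisibly, the list of cases (each as in [generate_phantom()]
#'   plus a `reference` volume).
#' @export
generate_cohort <- function(n, config = phantom_config(), seed = 1L,
                            dir = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- case_seeds[i]
    cs <- generate_phantom(cfg)
    cs$case_id <- sprintf("case_%04d", i)
    cs$reference <- build_reference(cs$pet, cs$rois)
    if (!is.null(dir)) {
      cdir <- file.path(dir, cs$case_id)
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      write_volume(cs$pet, file.path(cdir, "pet.nii.gz"))
      write_volume(cs$ct, file.path(cdir, "ct.nii.gz"))
      write_volume(cs$reference, file.path(cdir, "reference.nii.gz"))
      write_volume(cs$rois, file.path(cdir, "rois.nii.gz"))
      jsonlite::write_json(list(
        case_id = cs$case_id, seed = case_seeds[i],
        background_suv = cs$truth$background_suv,
        n_lesions = length(cs$truth$lesions),
        lesions = cs$truth$lesions,
        features = unclass(cs$truth$features)[c("suv_max", "mtv", "tlg",
                                                "surface_area", "sa_mtv",
                                                "dmax_patient", "n_lesions")]),
        file.path(cdir, "truth.json"), auto_unbox = TRUE, digits = NA)
    }
    cases[[i]] <- cs
  }
  invisible(cases)
}

#' Read a phantom cohort directory written by [generate_cohort()]
#'
#' @param dir cohort directory containing `case_XXXX/` subdirectories.
#' @return List of cases with `pet`, `ct`, `reference`, `rois` volumes.
#' @export
read_cohort <- function(dir) {
  cdirs <- sort(list.dirs(dir, recursive = FALSE))
  cdirs <- cdirs[grepl("case_", basename(cdirs))]
  if (!length(cdirs)) stop("no case_* directories found in ", dir)
  lapply(cdirs, function(cd) {
    list(case_id = basename(cd),
         pet = read_volume(file.path(cd, "pet.nii.gz"), "PET_SUV"),
         ct = read_volume(file.path(cd, "ct.nii.gz"), "CT_HU"),
         reference = read_volume(file.path(cd, "reference.nii.gz"), "LABEL"),
         rois = read_volume(file.path(cd, "rois.nii.gz"), "LABEL"))
  })
}
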