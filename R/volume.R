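#' @useDynLib lymphseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif median quantile cor wilcox.test sd
#' @importFrom utils write.csv head
NULL

VOLUME_MODALITIES <- c("PET_SUV", "CT_HU", "PROBABILITY", "LABEL")

#' Construct a 3D scalar volume
#'
#' A `volume` is the package's core container: a 3D numeric grid plus the
#' geometry needed to relate voxel indices to world coordinates. Voxel
#' indices are 0-based internally; the world position of voxel `(i, j, k)`
#' is `origin + c(i, j, k) * spacing` (axis-aligned grids only).
#'
#' @param data 3D numeric array (all values finite).
#' @param spacing numeric length-3, voxel size in mm per axis (positive).
#' @param origin numeric length-3, world position of voxel (0,0,0) in mm.
#' @param modality one of `"PET_SUV"`, `"CT_HU"`, `"PROBABILITY"`, `"LABEL"`.
#'   `LABEL` volumes must contain only non-negative integers; `PROBABILITY`
#'   volumes must lie in \[0, 1\].
#' @return An object of class `volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   modality = "PET_SUV") {
  modality <- match.arg(modality, VOLUME_MODALITIES)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3-dimensional array")
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values")
  if (any(!is.finite(data)))
    stop("volume data contains non-finite values")
  if (modality == "LABEL" && any(data < 0 | data != round(data)))
    stop("LABEL volumes must contain only non-negative integers")
  if (modality == "PROBABILITY" && (any(data < 0) || any(data > 1)))
    stop("PROBABILITY volumes must lie in [0, 1]")
  structure(list(data = data, spacing = spacing, origin = origin,
                 modality = modality),
            class = "volume")
}

is_volume <- function(x) inherits(x, "volume")

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s  %s voxels  spacing %s mm  origin (%s) mm\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              paste(format(x$origin, trim = TRUE), collapse = ", ")))
  rng <- range(x$data)
  cat(sprintf("  value range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-6 ||
      max(abs(a$origin - b$origin)) > 1e-6)
    stop(sprintf("%s do not share grid shape, spacing and origin", what))
  invisible(TRUE)
}

voxel_volume_cm3 <- function(spacing) prod(spacing) / 1000

#' Read a NIfTI-1 volume
#'
#' Reads a 3D NIfTI-1 image (`.nii` / `.nii.gz`). Spacing and origin are
#' taken from the image's xform affine; only axis-aligned affines with
#' positive scales are accepted — oblique orientations are rejected rather
#' than silently reoriented.
#'
#' @param path path to a NIfTI-1 file.
#' @param modality modality tag for the returned [volume()].
#' @return A [volume()].
#' @export
read_volume <- function(path, modality = "PET_SUV") {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("expected a 3-dimensional NIfTI image, got ", length(d), " dims")
  aff <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  if (is.null(aff)) {
    spacing <- rep(1, 3)
    origin <- rep(0, 3)
  } else {
    lin <- unclass(aff)[1:3, 1:3]
    if (max(abs(lin - diag(diag(lin)))) > 1e-4 * max(abs(diag(lin))))
      stop("oblique NIfTI affines are not supported; reorient the image first")
    spacing <- abs(diag(lin))
    if (any(diag(lin) <= 0))
      stop("NIfTI affine has non-positive axis scales; reorient the image first")
    origin <- unclass(aff)[1:3, 4]
  }
  volume(array(as.numeric(img), dim = d), spacing = spacing,
         origin = origin, modality = modality)
}

#' Write a volume as NIfTI-1
#'
#' The affine encodes spacing on the diagonal and origin in the translation
#' column. Label volumes are written losslessly.
#'
#' @param vol a [volume()].
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  dat <- vol$data
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(4)
  aff[1, 1] <- vol$spacing[1]
  aff[2, 2] <- vol$spacing[2]
  aff[3, 3] <- vol$spacing[3]
  aff[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  if (vol$modality == "LABEL")
    img <- RNifti::asNifti(img, datatype = "int32")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Scan metadata for SUV conversion
#'
#' @param injected_dose injected activity in Bq.
#' @param body_weight patient weight in kg.
#' @param injection_to_scan_time minutes between injection and scan.
#' @param half_life tracer half-life in minutes (default F-18: 109.77).
#' @return An object of class `scan_meta`.
#' @export
scan_meta <- function(injected_dose, body_weight, injection_to_scan_time = 0,
                      half_life = 109.77) {
  if (!is.finite(injected_dose) || injected_dose <= 0)
    stop("injected_dose must be > 0")
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be > 0")
  if (!is.finite(injection_to_scan_time) || injection_to_scan_time < 0)
    stop("injection_to_scan_time must be >= 0")
  if (!is.finite(half_life) || half_life <= 0)
    stop("half_life must be > 0")
  structure(list(injected_dose = injected_dose, body_weight = body_weight,
                 injection_to_scan_time = injection_to_scan_time,
                 half_life = half_life),
            class = "scan_meta")
}

#' Read scan metadata from a JSON sidecar
#'
#' Expects fields `dose_MBq`, `weight_kg`, `post_injection_min` (and
#' optionally `half_life_min`).
#'
#' @param path JSON file path.
#' @return A [scan_meta()].
#' @export
read_scan_meta <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  scan_meta(injected_dose = j$dose_MBq * 1e6,
            body_weight = j$weight_kg,
            injection_to_scan_time = j$post_injection_min,
            half_life = if (!is.null(j$half_life_min)) j$half_life_min else 109.77)
}

#' Convert an activity-concentration volume to body-weight SUV
#'
#' `SUV = C / (dose_decay_corrected / (1000 * weight))` where `C` is the
#' activity concentration in Bq/ml and the injected dose is decay-corrected
#' to scan time with the tracer half-life.
#'
#' @param activity a [volume()] of activity concentration in Bq/ml (>= 0).
#' @param meta a [scan_meta()].
#' @return A `PET_SUV` [volume()].
#' @export
compute_suv <- function(activity, meta) {
  stopifnot(is_volume(activity), inherits(meta, "scan_meta"))
  if (any(activity$data < 0)) stop("activity values must be >= 0")
  dose_at_scan <- meta$injected_dose *
    2^(-meta$injection_to_scan_time / meta$half_life)
  suv <- activity$data * (meta$body_weight * 1000) / dose_at_scan
  volume(suv, spacing = activity$spacing, origin = activity$origin,
         modality = "PET_SUV")
}

# 1D linear-interpolation matrix mapping an input axis (n_in samples at
# spacing s_in) onto output sample positions pos (in input-index units),
# clamped to the grid (edge-value extension).
interp_matrix <- function(n_in, pos, mode) {
  pos <- pmin(pmax(pos, 0), n_in - 1)
  m <- matrix(0, nrow = length(pos), ncol = n_in)
  if (mode == "nearest") {
    idx <- pmin(pmax(round(pos), 0), n_in - 1) + 1
    m[cbind(seq_along(pos), idx)] <- 1
  } else {
    lo <- pmin(floor(pos), n_in - 1)
    hi <- pmin(lo + 1, n_in - 1)
    w <- pos - lo
    m[cbind(seq_along(pos), lo + 1)] <- m[cbind(seq_along(pos), lo + 1)] + (1 - w)
    m[cbind(seq_along(pos), hi + 1)] <- m[cbind(seq_along(pos), hi + 1)] + w
  }
  m
}

apply_axis <- function(arr, m, axis) {
  # multiplies interpolation matrix m along the given axis of a 3D array
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- m %*% matrix(a, nrow = da[1])
  a <- array(a, c(nrow(m), da[2], da[3]))
  aperm(a, order(perm))
}

#' Resample a volume to an isotropic grid
#'
#' Output grid: same world origin, spacing `(t, t, t)`, and
#' `ceil(extent / t)` voxels per axis so the physical extent is preserved
#' to within one voxel. Interpolation is separable linear (with edge-value
#' extension) or nearest neighbour; `LABEL` volumes must use nearest and
#' remain integer-valued.
#'
#' @param vol a [volume()].
#' @param target_spacing target isotropic voxel size in mm (> 0).
#' @param mode `"linear"` or `"nearest"`.
#' @return The resampled [volume()].
#' @export
resample_isotropic <- function(vol, target_spacing = 2,
                               mode = c("linear", "nearest")) {
  stopifnot(is_volume(vol))
  mode <- match.arg(mode)
  if (!is.finite(target_spacing) || target_spacing <= 0)
    stop("target_spacing must be > 0")
  if (vol$modality == "LABEL" && mode == "linear")
    stop("LABEL volumes must be resampled with mode = \"nearest\"")
  d <- dim(vol$data)
  extent <- d * vol$spacing
  nd <- pmax(1L, as.integer(ceiling(extent / target_spacing - 1e-9)))
  out <- vol$data
  for (ax in 1:3) {
    pos <- (seq_len(nd[ax]) - 1) * target_spacing / vol$spacing[ax]
    m <- interp_matrix(d[ax], pos, mode)
    out <- apply_axis(out, m, ax)
  }
  if (vol$modality == "LABEL") out <- round(out)
  volume(out, spacing = rep(target_spacing, 3), origin = vol$origin,
         modality = vol$modality)
}

label_components <- function(mask, connectivity = 26) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  label_components_cpp(as.logical(mask != 0), as.integer(dim(mask)),
                       as.integer(connectivity))
}

fill_holes <- function(mask) {
  # background components (6-connected, complementary to 26-connected
  # foreground) not touching the border are holes
  bg <- label_components(!mask, connectivity = 6)
  d <- dim(mask)
  border <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ], bg[, , c(1, d[3])]))
  border <- border[border > 0]
  filled <- mask | !(bg %in% c(0L, border))
  array(filled, d)
}

#' Derive a binary body mask from CT
#'
#' Thresholds the CT at `hu_cut` (default -500 HU: excludes air, keeps
#' lung), keeps the largest 26-connected component and fills internal
#' holes (3D).
#'
#' @param ct a `CT_HU` [volume()].
#' @param hu_cut threshold in HU.
#' @return A binary `LABEL` [volume()] marking the patient's body.
#' @export
body_mask <- function(ct, hu_cut = -500) {
  stopifnot(is_volume(ct))
  fg <- ct$data > hu_cut
  if (!any(fg)) stop("no voxels above ", hu_cut, " HU; CT unusable")
  lab <- label_components(fg, connectivity = 26)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  m <- fill_holes(array(lab == keep, dim(ct$data)))
  volume(array(as.numeric(m), dim(ct$data)), spacing = ct$spacing,
         origin = ct$origin, modality = "LABEL")
}

#' Z-score a volume against a mask
#'
#' Standardises the whole grid using the mean and population variance of
#' the voxels inside the mask, so that after the transform the masked
#' voxels have mean 0 and variance 1.
#'
#' @param vol a [volume()].
#' @param mask a binary `LABEL` [volume()] on the same grid, non-empty.
#' @param clip optional length-2 range applied to the values before
#'   computing statistics and transforming (used to bound CT outliers).
#' @return A [volume()] with modality preserved for PET/CT inputs.
#' @export
normalize_volume <- function(vol, mask, clip = NULL) {
  stopifnot(is_volume(vol), is_volume(mask))
  stopifnot_same_grid(vol, mask, "volume and mask")
  m <- mask$data != 0
  if (!any(m)) stop("normalization mask is empty")
  x <- vol$data
  if (!is.null(clip)) x <- pmin(pmax(x, clip[1]), clip[2])
  mu <- mean(x[m])
  sig <- sqrt(mean((x[m] - mu)^2))
  if (sig == 0) stop("zero variance inside mask; cannot normalize")
  out <- (x - mu) / sig
  v <- vol
  v$data <- out
  v
}
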