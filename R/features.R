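# The five prognostic PET metrics: SUVmax, metabolic tumor volume (MTV),
# total lesion glycolysis (TLG), surface-area-to-volume ratio (SA/MTV)
# and lesion dissemination (Dmax). Patient-level, over all lesions.

#' Maximum SUV inside a mask
#' @param pet a `PET_SUV` [volume()].
#' @param mask logical/0-1 3D array on the PET grid.
#' @return Maximum SUV (g/ml), or `NA` for an empty mask.
#' @export
suv_max <- function(pet, mask) {
  stopifnot(is_volume(pet))
  m <- mask != 0
  if (!identical(dim(m), dim(pet$data)))
    stop("mask and PET do not share a grid")
  if (!any(m)) return(NA_real_)
  max(pet$data[m])
}

#' Metabolic tumor volume
#' @param mask logical/0-1 3D array.
#' @param spacing voxel size in mm (length 3 or scalar).
#' @return Volume in cm^3 (voxel count times voxel volume).
#' @export
mtv <- function(mask, spacing) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  sum(mask != 0) * voxel_volume_cm3(spacing)
}

#' Total lesion glycolysis
#'
#' `TLG = sum over mask of SUV * voxel volume`, identically equal to
#' `SUVmean * MTV`.
#' @inheritParams suv_max
#' @param spacing voxel size in mm.
#' @return TLG in g (SUV x cm^3); 0 for an empty mask.
#' @export
tlg <- function(pet, mask, spacing = pet$spacing) {
  stopifnot(is_volume(pet))
  m <- mask != 0
  if (!identical(dim(m), dim(pet$data)))
    stop("mask and PET do not share a grid")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  sum(pet$data[m]) * voxel_volume_cm3(spacing)
}

shift_pad_false <- function(m, ax, by) {
  # shifts a logical array by one voxel along axis ax, padding with FALSE
  d <- dim(m)
  out <- array(FALSE, d)
  if (d[ax] == 1L) return(out)  # shifting by one voxel empties the axis
  src <- lapply(d, seq_len)
  dst <- src
  if (by > 0) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
  else        { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Lesion surface area by exposed-face counting
#'
#' Counts voxel faces adjacent to background (6-neighbourhood, volume
#' borders count as background) over all components jointly and
#' multiplies by the face area. Exact and deterministic; overestimates
#' the area of a smooth surface by up to ~1.5x.
#'
#' @param mask logical/0-1 3D array.
#' @param spacing voxel size in mm.
#' @return Surface area in cm^2; 0 for an empty mask.
#' @export
surface_area <- function(mask, spacing) {
  m <- mask != 0
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (!any(m)) return(0)
  counts <- exposed_faces_by_axis(m)
  areas <- vapply(1:3, function(ax) prod(spacing[-ax]) / 100, numeric(1))
  sum(counts * areas)
}

# integer count of background-adjacent faces per axis (both directions)
exposed_faces_by_axis <- function(m) {
  vapply(1:3, function(ax)
    sum(m & !shift_pad_false(m, ax, +1)) +
      sum(m & !shift_pad_false(m, ax, -1)), integer(1))
}

#' Surface-area-to-volume ratio
#' @param mask logical/0-1 3D array.
#' @param spacing voxel size in mm.
#' @return SA/MTV in cm^-1, or `NA` when MTV is 0.
#' @export
sa_mtv <- function(mask, spacing) {
  v <- mtv(mask, spacing)
  if (v == 0) return(NA_real_)
  surface_area(mask, spacing) / v
}

#' Lesion dissemination: distance between the two farthest lesions
#'
#' Lesions are 26-connected components; the distance is the Euclidean
#' distance between lesion centroids in world coordinates (centroid =
#' mean of voxel centers). Returns 0 when fewer than two lesions exist.
#'
#' @param mask logical/0-1 3D array.
#' @param spacing voxel size in mm.
#' @param origin world position of voxel (0,0,0) (only shifts centroids;
#'   the distance is translation invariant).
#' @return Dmax in cm.
#' @export
dmax_patient <- function(mask, spacing, origin = c(0, 0, 0)) {
  m <- mask != 0
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (!any(m)) return(0)
  lab <- label_components(m, connectivity = 26)
  k <- max(lab)
  if (k < 2) return(0)
  cent <- t(vapply(seq_len(k), function(id) {
    idx <- which(lab == id, arr.ind = TRUE) - 1L
    origin + colMeans(idx) * spacing
  }, numeric(3)))
  max(stats::dist(cent)) / 10
}

#' Extract the five PET metrics from a segmentation
#'
#' @param pet a `PET_SUV` [volume()].
#' @param mask logical/0-1 3D array or binary `LABEL` [volume()] on the
#'   PET grid.
#' @return An object of class `feature_set`: `suv_max` (g/ml), `mtv`
#'   (cm^3), `tlg` (g), `surface_area` (cm^2), `sa_mtv` (cm^-1),
#'   `dmax_patient` (cm), `n_lesions`, and `flags` describing empty-mask
#'   degeneracies (`suv_max` and `sa_mtv` are `NA` when undefined;
#'   `dmax_patient` is 0 with fewer than two lesions).
#' @export
extract_features <- function(pet, mask) {
  stopifnot(is_volume(pet))
  if (is_volume(mask)) {
    stopifnot_same_grid(pet, mask, "PET and mask")
    mask <- mask$data
  }
  m <- mask != 0
  if (!identical(dim(m), dim(pet$data)))
    stop("mask and PET do not share a grid")
  sp <- pet$spacing
  lab <- label_components(m, connectivity = 26)
  n_les <- max(lab)
  fs <- list(
    suv_max = suv_max(pet, m),
    mtv = mtv(m, sp),
    tlg = tlg(pet, m, sp),
    surface_area = surface_area(m, sp),
    sa_mtv = sa_mtv(m, sp),
    dmax_patient = dmax_patient(m, sp, pet$origin),
    n_lesions = n_les,
    flags = character(0)
  )
  if (!any(m)) fs$flags <- c(fs$flags, "empty_mask")
  if (n_les < 2) fs$flags <- c(fs$flags, "dmax_undefined_set_to_zero")
  structure(fs, class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set>\n")
  cat(sprintf("  SUVmax  %8.3f g/ml\n", x$suv_max))
  cat(sprintf("  MTV     %8.3f cm^3\n", x$mtv))
  cat(sprintf("  TLG     %8.3f g\n", x$tlg))
  cat(sprintf("  SA      %8.3f cm^2\n", x$surface_area))
  cat(sprintf("  SA/MTV  %8.3f cm^-1\n", x$sa_mtv))
  cat(sprintf("  Dmax    %8.3f cm  (%d lesion%s)\n", x$dmax_patient,
              x$n_lesions, if (x$n_lesions == 1) "" else "s"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

feature_row <- function(case_id, fs, source) {
  data.frame(case_id = case_id, suv_max = fs$suv_max, mtv_cm3 = fs$mtv,
             tlg = fs$tlg, sa_cm2 = fs$surface_area, sa_mtv_cm1 = fs$sa_mtv,
             dmax_cm = fs$dmax_patient, n_lesions = fs$n_lesions,
             source = source, stringsAsFactors = FALSE)
}
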