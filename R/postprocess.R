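# Ensemble post-processing: per-contour SUV threshold refinement,
# voxelwise intersection of the three member masks, and exclusion of
# components dominated by bone on CT.

#' Refine a CNN mask with the reference thresholding scheme
#'
#' Within each 26-connected component of the mask, keeps voxels with
#' `SUV > 2.5` or `SUV >= 0.40 * component SUVmax` (the same union rule
#' used to build the reference segmentations, applied per contour).
#'
#' @param cnn_mask logical/0-1 3D array.
#' @param pet a `PET_SUV` [volume()] on the same grid.
#' @param suv_floor,rel_fraction threshold parameters (defaults 2.5, 0.40).
#' @return Logical 3D array.
#' @export
refine_with_thresholds <- function(cnn_mask, pet, suv_floor = 2.5,
                                   rel_fraction = 0.40) {
  stopifnot(is_volume(pet))
  m <- cnn_mask != 0
  if (!identical(dim(m), dim(pet$data)))
    stop("mask and PET do not share a grid")
  if (!any(m)) return(array(FALSE, dim(m)))
  lab <- label_components(m, connectivity = 26)
  ncomp <- max(lab)
  # per-component SUVmax, then the voxelwise union rule
  comp_max <- vapply(seq_len(ncomp), function(id) max(pet$data[lab == id]),
                     numeric(1))
  keep <- m & (pet$data > suv_floor |
                 (lab > 0 & pet$data >= rel_fraction * comp_max[pmax(lab, 1)]))
  array(keep, dim(m))
}

#' Voxelwise intersection of ensemble member masks
#'
#' @param masks list of logical/0-1 3D arrays on identical grids.
#' @return Logical 3D array (the voxelwise AND).
#' @export
intersect_ensemble <- function(masks) {
  stopifnot(length(masks) >= 1)
  d <- dim(masks[[1]])
  out <- masks[[1]] != 0
  for (m in masks[-1]) {
    if (!identical(dim(m), d)) stop("ensemble member grids do not match")
    out <- out & (m != 0)
  }
  array(out, d)
}

#' Exclude mask components dominated by bone
#'
#' Removes each 26-connected component whose fraction of voxels with
#' `HU > hu_cut` exceeds `bone_fraction`. The published rule excluded any
#' contour containing bone; the component-level fraction (default 0.5)
#' avoids deleting true lesions that merely abut a vertebra, and
#' `bone_fraction = 0` recovers the strict any-voxel reading.
#'
#' @param mask logical/0-1 3D array.
#' @param ct a `CT_HU` [volume()] on the same grid.
#' @param hu_cut Hounsfield threshold defining bone (default 150).
#' @param bone_fraction components with more than this fraction of bone
#'   voxels are removed.
#' @return List with `mask` (logical array) and `excluded` (data frame of
#'   removed component ids, sizes and bone fractions).
#' @export
exclude_bone <- function(mask, ct, hu_cut = 150, bone_fraction = 0.5) {
  stopifnot(is_volume(ct))
  m <- mask != 0
  if (!identical(dim(m), dim(ct$data)))
    stop("mask and CT do not share a grid")
  excluded <- data.frame(component = integer(), size = integer(),
                         bone_fraction = numeric())
  if (!any(m)) return(list(mask = array(FALSE, dim(m)), excluded = excluded))
  lab <- label_components(m, connectivity = 26)
  bone <- ct$data > hu_cut
  for (id in seq_len(max(lab))) {
    sel <- lab == id
    frac <- mean(bone[sel])
    if (frac > bone_fraction) {
      m[sel] <- FALSE
      excluded <- rbind(excluded,
                        data.frame(component = id, size = sum(sel),
                                   bone_fraction = frac))
    }
  }
  list(mask = array(m, dim(mask)), excluded = excluded)
}

#' Full ensemble post-processing
#'
#' Pipeline (order fixed): binarize each probability map at `cut_point`,
#' refine each member mask with the SUV threshold scheme, intersect the
#' members voxelwise, then drop bone-dominated components. The final mask
#' is therefore always a subset of every refined member mask.
#'
#' @param prob_maps list of `PROBABILITY` [volume()]s (typically 3).
#' @param pet a `PET_SUV` [volume()]; @param ct a `CT_HU` [volume()].
#' @param cut_point probability cut point (default 0.5).
#' @param hu_cut,bone_fraction see [exclude_bone()].
#' @return An object of class `ensemble_output`: `member_masks` (refined,
#'   one per member), `final_mask` (binary `LABEL` [volume()]) and
#'   `excluded_components`.
#' @export
postprocess_ensemble <- function(prob_maps, pet, ct, cut_point = 0.5,
                                 hu_cut = 150, bone_fraction = 0.5) {
  stopifnot(is_volume(pet), is_volume(ct))
  stopifnot_same_grid(pet, ct, "PET and CT")
  for (p in prob_maps) stopifnot_same_grid(p, pet, "probability map and PET")
  members <- lapply(prob_maps, function(p)
    refine_with_thresholds(binarize(p, cut_point), pet))
  inter <- intersect_ensemble(members)
  bx <- exclude_bone(inter, ct, hu_cut = hu_cut, bone_fraction = bone_fraction)
  structure(list(
    member_masks = members,
    final_mask = volume(array(as.numeric(bx$mask), dim(pet$data)),
                        spacing = pet$spacing, origin = pet$origin,
                        modality = "LABEL"),
    excluded_components = bx$excluded,
    cut_point = cut_point
  ), class = "ensemble_output")
}

#' @export
print.ensemble_output <- function(x, ...) {
  cat(sprintf("<ensemble_output> %d members, cut point %.2f\n",
              length(x$member_masks), x$cut_point))
  cat(sprintf("  final mask: %d voxels; %d component(s) excluded as bone\n",
              sum(x$final_mask$data), nrow(x$excluded_components)))
  invisible(x)
}
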