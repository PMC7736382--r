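# Reference (ground-truth) segmentation: physician-style threshold union
# inside loose template ROIs, then removal of 1-voxel islands.

#' Threshold union inside one region
#'
#' Within a region of interest, a voxel is selected when its SUV exceeds
#' the fixed floor (`SUV > 2.5`, strict) or reaches the relative cut
#' (`SUV >= 0.40 * max SUV in the region`, non-strict so the maximum voxel
#' is always kept). The union of the two rules captures small low-uptake
#' lesions sitting next to a high-uptake lesion that a pure percentage
#' threshold would miss.
#'
#' @param pet a `PET_SUV` [volume()].
#' @param roi_mask logical/0-1 3D array on the PET grid, non-empty.
#' @param suv_floor fixed SUV threshold (default 2.5).
#' @param rel_fraction relative threshold as a fraction of the region's
#'   maximum SUV (default 0.40).
#' @return Logical 3D array (the selected voxels).
#' @export
threshold_union <- function(pet, roi_mask, suv_floor = 2.5,
                            rel_fraction = 0.40) {
  stopifnot(is_volume(pet))
  roi <- roi_mask != 0
  if (!identical(dim(roi), dim(pet$data)))
    stop("ROI mask and PET do not share a grid")
  if (!any(roi)) stop("empty ROI")
  cut_rel <- rel_fraction * max(pet$data[roi])
  sel <- roi & (pet$data > suv_floor | pet$data >= cut_rel)
  array(sel, dim(pet$data))
}

#' Remove small islands from a binary mask
#'
#' Drops 26-connected components with fewer than `min_size` voxels. The
#' default removes exactly the 1-voxel islands that voxelwise thresholding
#' tends to produce.
#'
#' @param mask logical/0-1 3D array.
#' @param min_size minimum component size kept, in voxels.
#' @return Logical 3D array.
#' @export
remove_islands <- function(mask, min_size = 2) {
  m <- mask != 0
  if (!any(m)) return(array(FALSE, dim(mask)))
  lab <- label_components(m, connectivity = 26)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_size)
  if (length(small)) m[lab %in% small] <- FALSE
  array(m, dim(mask))
}

#' Build a reference segmentation from template ROIs
#'
#' Applies [threshold_union()] independently inside each template-ROI id
#' (the 40% rule uses the per-region SUV maximum), merges the results and
#' removes 1-voxel islands once on the merged mask.
#'
#' @param pet a `PET_SUV` [volume()].
#' @param rois an integer `LABEL` [volume()] with ids `1..K` marking
#'   physician-style disease regions (0 = background).
#' @param min_island_size passed to [remove_islands()].
#' @return A binary `LABEL` [volume()] on the PET grid.
#' @export
build_reference <- function(pet, rois, min_island_size = 2) {
  stopifnot(is_volume(pet), is_volume(rois))
  stopifnot_same_grid(pet, rois, "PET and template ROIs")
  ids <- sort(unique(as.vector(rois$data)))
  ids <- ids[ids > 0]
  if (!length(ids)) stop("template ROI volume contains no regions")
  acc <- array(FALSE, dim(pet$data))
  for (id in ids)
    acc <- acc | threshold_union(pet, rois$data == id)
  acc <- remove_islands(acc, min_size = min_island_size)
  volume(array(as.numeric(acc), dim(pet$data)), spacing = pet$spacing,
         origin = pet$origin, modality = "LABEL")
}
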