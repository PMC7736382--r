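test_that("threshold refinement applies the union rule per component", {
  d <- c(8, 8, 8)
  pet <- array(0, d)
  pet[1:3] <- c(1, 3, 10)
  mask <- array(FALSE, d); mask[1:3] <- TRUE
  out <- refine_with_thresholds(mask, vol3(pet))
  expect_equal(which(out), c(2L, 3L))   # {3, 10} survive

  # uniform SUV-1 component: 40% of its own max (0.4) keeps every voxel
  pet2 <- array(0, d); pet2[1:3] <- 1
  expect_equal(sum(refine_with_thresholds(mask, vol3(pet2))), 3)

  expect_equal(sum(refine_with_thresholds(array(FALSE, d), vol3(pet))), 0)

  # two components use their own maxima: the dim one is not judged by the
  # bright one's 40% cut
  pet3 <- array(0, d)
  m3 <- array(FALSE, d)
  pet3[1:2, 1, 1] <- 20
  pet3[6:7, 6, 6] <- c(1, 2)
  m3[1:2, 1, 1] <- TRUE
  m3[6:7, 6, 6] <- TRUE
  out3 <- refine_with_thresholds(m3, vol3(pet3))
  expect_true(all(out3[m3]))
})

test_that("ensemble intersection is a voxelwise AND", {
  d <- c(6, 6, 6)
  a <- rand_mask(d, 0.5); b <- rand_mask(d, 0.5); c3 <- rand_mask(d, 0.5)
  expect_equal(intersect_ensemble(list(a, a, a)), a)
  expect_equal(sum(intersect_ensemble(list(a, b, array(FALSE, d)))), 0)
  nested_c <- a & b & c3
  expect_equal(intersect_ensemble(list(a, a & b, nested_c)), nested_c)
  expect_error(intersect_ensemble(list(a, rand_mask(c(5, 5, 5)))), "match")
})

test_that("bone exclusion removes components by bone fraction", {
  d <- c(10, 10, 10)
  comp <- array(FALSE, d); comp[2:4, 2:4, 2:4] <- TRUE
  ct_bone <- vol3(array(300, d), modality = "CT_HU")
  ct_soft <- vol3(array(30, d), modality = "CT_HU")
  expect_equal(sum(exclude_bone(comp, ct_bone)$mask), 0)
  expect_equal(exclude_bone(comp, ct_soft)$mask, comp)

  # 60% bone voxels: removed at bone_fraction 0.5, kept at 0.7
  ctm <- array(30, d)
  idx <- which(comp)
  ctm[idx[1:ceiling(0.6 * length(idx))]] <- 300
  ctv <- vol3(ctm, modality = "CT_HU")
  expect_equal(sum(exclude_bone(comp, ctv, bone_fraction = 0.5)$mask), 0)
  expect_equal(exclude_bone(comp, ctv, bone_fraction = 0.7)$mask, comp)
  expect_equal(nrow(exclude_bone(comp, ctv, bone_fraction = 0.5)$excluded), 1)
})

test_that("ensemble post-processing composes the published pipeline", {
  d <- c(12, 12, 12)
  lesion <- array(FALSE, d); lesion[4:6, 4:6, 4:6] <- TRUE
  pet <- array(0.5, d); pet[lesion] <- 6
  ct <- array(40, d)
  pv <- function(m) vol3(array(as.numeric(m) * 0.9, d), modality = "PROBABILITY")

  # all members agree on the lesion -> final mask is the lesion
  out <- postprocess_ensemble(list(pv(lesion), pv(lesion), pv(lesion)),
                              vol3(pet), vol3(ct, modality = "CT_HU"))
  expect_equal(out$final_mask$data != 0, lesion)

  # a hot blob seen by one member only is vetoed by the intersection
  blob <- lesion; blob[9:10, 9:10, 9:10] <- TRUE
  pet2 <- pet; pet2[9:10, 9:10, 9:10] <- 8
  out2 <- postprocess_ensemble(list(pv(blob), pv(lesion), pv(lesion)),
                               vol3(pet2), vol3(ct, modality = "CT_HU"))
  expect_equal(out2$final_mask$data != 0, lesion)

  # a blob inside bone agreed by all members is removed by bone exclusion
  ct3 <- ct; ct3[9:10, 9:10, 9:10] <- 300
  out3 <- postprocess_ensemble(list(pv(blob), pv(blob), pv(blob)),
                               vol3(pet2), vol3(ct3, modality = "CT_HU"))
  expect_equal(out3$final_mask$data != 0, lesion)
  expect_equal(nrow(out3$excluded_components), 1)
})

test_that("final mask is always a subset of every refined member mask", {
  set.seed(17)
  d <- c(10, 10, 10)
  pet <- vol3(array(runif(prod(d), 0, 10), d))
  ct <- vol3(array(40 + rnorm(prod(d), 0, 200), d), modality = "CT_HU")
  for (rep in 1:5) {
    probs <- lapply(1:3, function(i)
      vol3(array(runif(prod(d)), d), modality = "PROBABILITY"))
    out <- postprocess_ensemble(probs, pet, ct)
    fin <- out$final_mask$data != 0
    for (m in out$member_masks) expect_true(all(m[fin]))
  }
})
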