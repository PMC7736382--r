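test_that("SUVmax, MTV and TLG follow their definitions", {
  d <- c(6, 6, 6)
  arr <- array(0, d)
  arr[1:3] <- c(2, 7.5, 3)
  pet <- vol3(arr)
  mask <- array(FALSE, d); mask[1:3] <- TRUE
  expect_equal(suv_max(pet, mask), 7.5)
  single <- array(FALSE, d); single[2] <- TRUE
  expect_equal(suv_max(pet, single), 7.5)
  expect_equal(suv_max(pet, array(TRUE, d)), max(arr))
  expect_true(is.na(suv_max(pet, array(FALSE, d))))

  # 125 voxels at 2 mm -> 1 cm^3; uniform SUV 5 over 1 cm^3 -> TLG 5
  m125 <- array(FALSE, c(10, 10, 10)); m125[1:5, 1:5, 1:5] <- TRUE
  expect_equal(mtv(m125, c(2, 2, 2)), 1.0)
  expect_equal(mtv(array(FALSE, d), c(2, 2, 2)), 0)
  u5 <- vol3(array(5, c(10, 10, 10)))
  expect_equal(tlg(u5, m125), 5.0)
  expect_equal(tlg(u5, array(FALSE, c(10, 10, 10))), 0)
})

test_that("surface area counts exposed voxel faces", {
  d <- c(8, 8, 8)
  one <- array(FALSE, d); one[4, 4, 4] <- TRUE
  expect_equal(surface_area(one, c(2, 2, 2)), 6 * 0.04)

  cube <- array(FALSE, d); cube[4:5, 4:5, 4:5] <- TRUE
  expect_equal(surface_area(cube, c(2, 2, 2)), 24 * 0.04)

  col2 <- array(FALSE, d); col2[4, 4, 4:5] <- TRUE
  expect_equal(surface_area(col2, c(2, 2, 2)), 10 * 0.04)

  # voxels on the volume border expose faces to the outside
  corner <- array(FALSE, d); corner[1, 1, 1] <- TRUE
  expect_equal(surface_area(corner, c(2, 2, 2)), 6 * 0.04)
})

test_that("SA/MTV decreases for growing cubes", {
  expect_equal(sa_mtv(array(TRUE, c(1, 1, 1)), 2), 30)
  d <- c(12, 12, 12)
  vals <- sapply(c(1, 2, 3, 4), function(L) {
    m <- array(FALSE, d); m[1:L, 1:L, 1:L] <- TRUE
    sa_mtv(m, c(2, 2, 2))
  })
  expect_equal(vals[1], 30)
  expect_equal(vals[2], 15)
  expect_true(all(diff(vals) < 0))
  expect_true(is.na(sa_mtv(array(FALSE, d), c(2, 2, 2))))
})

test_that("Dmax is the largest centroid distance between lesions", {
  d <- c(8, 8, 8)
  two <- array(FALSE, d)
  two[1, 1, 1] <- TRUE
  two[4, 5, 1] <- TRUE    # indices (0,0,0) and (3,4,0): 3-4-5 at 2 mm = 1 cm
  expect_equal(dmax_patient(two, c(2, 2, 2)), 1.0)

  one <- array(FALSE, d); one[3:4, 3, 3] <- TRUE
  expect_equal(dmax_patient(one, c(2, 2, 2)), 0)

  set.seed(5)
  for (rep in 1:5) {
    m <- rand_mask(c(10, 10, 10), 0.03)
    expect_equal(dmax_patient(m, c(2, 2, 2)), oracle_dmax(m, c(2, 2, 2)),
                 tolerance = 1e-12)
  }
})

test_that("extract_features is additive over disjoint lesions and handles empties", {
  d <- c(16, 16, 16)
  pet <- array(0.5, d)
  one <- array(FALSE, d); one[3:5, 3:5, 3:5] <- TRUE
  pet[one] <- 6
  two <- one; two[10:12, 10:12, 10:12] <- TRUE
  pet[two] <- 6
  v <- vol3(pet)
  f1 <- extract_features(v, one)
  f2 <- extract_features(v, two)
  expect_equal(f2$mtv, 2 * f1$mtv)
  expect_equal(f2$surface_area, 2 * f1$surface_area)
  expect_equal(f2$sa_mtv, f1$sa_mtv)
  expect_equal(f2$tlg, 2 * f1$tlg)
  expect_equal(f2$suv_max, f1$suv_max)
  expect_equal(f2$n_lesions, 2)
  expect_equal(f1$dmax_patient, 0)
  expect_true(f2$dmax_patient > 0)

  fe <- extract_features(v, array(FALSE, d))
  expect_equal(fe$mtv, 0)
  expect_equal(fe$tlg, 0)
  expect_true(is.na(fe$suv_max))
  expect_true(is.na(fe$sa_mtv))
  expect_equal(fe$dmax_patient, 0)
  expect_true("empty_mask" %in% fe$flags)

  expect_equal(fe$tlg, 0)
  expect_error(extract_features(v, array(FALSE, c(4, 4, 4))), "grid")
})

test_that("features are invariant to rigid translation of mask and image", {
  set.seed(9)
  d <- c(14, 14, 14)
  pet <- array(runif(prod(d), 0, 10), d)
  mask <- array(FALSE, d)
  mask[3:5, 3:6, 3:4] <- TRUE
  mask[9:10, 9:10, 9:11] <- TRUE
  sh <- function(a, by) {
    out <- array(if (is.logical(a)) FALSE else 0, d)
    out[(1 + by):d[1], (1 + by):d[2], (1 + by):d[3]] <-
      a[1:(d[1] - by), 1:(d[2] - by), 1:(d[3] - by)]
    out
  }
  f0 <- extract_features(vol3(pet), mask)
  f1 <- extract_features(vol3(sh(pet, 2)), sh(mask, 2))
  for (nm in c("suv_max", "mtv", "tlg", "surface_area", "sa_mtv",
               "dmax_patient", "n_lesions"))
    expect_equal(f1[[nm]], f0[[nm]], tolerance = 1e-12)
})
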