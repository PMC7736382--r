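test_that("NIfTI round trip preserves data, spacing and origin", {
  tmp <- withr::local_tempdir()
  arr <- array(1, c(10, 10, 10))
  v <- volume(arr, spacing = c(2, 2, 2), origin = c(5, -3, 12))
  p <- file.path(tmp, "v.nii.gz")
  write_volume(v, p)
  r <- read_volume(p, "PET_SUV")
  expect_equal(r$data, v$data)
  expect_equal(r$spacing, v$spacing)
  expect_equal(r$origin, v$origin)

  # label masks are lossless; float volumes agree to float32 precision
  lab <- volume(array(sample(0:3, 125, replace = TRUE), c(5, 5, 5)),
                spacing = c(2, 2, 2), modality = "LABEL")
  write_volume(lab, file.path(tmp, "lab.nii.gz"))
  expect_identical(read_volume(file.path(tmp, "lab.nii.gz"), "LABEL")$data,
                   lab$data)
  pet <- volume(array(rnorm(125)^2, c(5, 5, 5)), spacing = c(2, 2, 2))
  write_volume(pet, file.path(tmp, "pet.nii.gz"))
  back <- read_volume(file.path(tmp, "pet.nii.gz"))
  expect_lt(max(abs(back$data - pet$data)) / max(abs(pet$data)), 1e-6)
})

test_that("read_volume rejects 4-d images and invalid label content", {
  tmp <- withr::local_tempdir()
  p4 <- file.path(tmp, "v4.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), p4)
  expect_error(read_volume(p4), "3-dimensional")

  pf <- file.path(tmp, "half.nii.gz")
  write_volume(volume(array(0.5, c(4, 4, 4))), pf)
  expect_error(read_volume(pf, "LABEL"), "integer")
  expect_error(read_volume(file.path(tmp, "missing.nii")), "cannot read")
})

test_that("volume validation enforces the container invariants", {
  expect_error(volume(array(0, c(3, 3, 3)), spacing = c(0, 1, 1)), "positive")
  expect_error(volume(array(c(NA, rep(0, 26)), c(3, 3, 3))), "finite")
  expect_error(volume(array(-1, c(3, 3, 3)), modality = "LABEL"), "integer")
  expect_error(volume(array(1.5, c(3, 3, 3)), modality = "PROBABILITY"),
               "\\[0, 1\\]")
  expect_error(volume(matrix(0, 3, 3)), "3-dimensional")
})

test_that("SUV conversion follows the decay-corrected body-weight formula", {
  act <- volume(array(2000, c(4, 4, 4)))
  m0 <- scan_meta(injected_dose = 1e8, body_weight = 50,
                  injection_to_scan_time = 0)
  expect_equal(unique(as.vector(compute_suv(act, m0)$data)), 1.0)

  m1 <- scan_meta(1e8, 50, injection_to_scan_time = 109.77)
  expect_equal(unique(as.vector(compute_suv(act, m1)$data)), 2.0)

  zero <- volume(array(0, c(4, 4, 4)))
  expect_true(all(compute_suv(zero, m0)$data == 0))

  expect_error(scan_meta(-1, 50), "dose")
  expect_error(scan_meta(1e8, 0), "weight")
  expect_error(compute_suv(volume(array(1, c(3, 3, 3))) |>
                             (\(v) { v$data[1] <- -1; v })(), m0), ">= 0")
})

test_that("scan metadata reads from the JSON sidecar convention", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "meta.json")
  jsonlite::write_json(list(dose_MBq = 100, weight_kg = 50,
                            post_injection_min = 0),
                       p, auto_unbox = TRUE)
  meta <- read_scan_meta(p)
  expect_equal(meta$injected_dose, 1e8)
  expect_equal(meta$half_life, 109.77)
  act <- volume(array(2000, c(3, 3, 3)))
  expect_equal(unique(as.vector(compute_suv(act, meta)$data)), 1.0)
})

test_that("isotropic resampling preserves extent, origin and constants", {
  v <- volume(array(3, c(10, 10, 10)), spacing = c(4, 4, 4),
              origin = c(1, 2, 3))
  r <- resample_isotropic(v, 2, "linear")
  expect_equal(dim(r$data), c(20L, 20L, 20L))
  expect_equal(r$spacing, c(2, 2, 2))
  expect_equal(r$origin, v$origin)
  expect_true(all(abs(r$data - 3) < 1e-12))

  lab <- volume(array(as.numeric(rand_mask(c(8, 8, 8), 0.3)), c(8, 8, 8)),
                spacing = c(3, 3, 3), modality = "LABEL")
  rl <- resample_isotropic(lab, 2, "nearest")
  expect_true(all(rl$data %in% c(0, 1)))
  expect_error(resample_isotropic(lab, 2, "linear"), "nearest")

  # resampling at the native spacing is the identity
  w <- volume(array(rnorm(512), c(8, 8, 8)), spacing = c(2, 2, 2))
  expect_equal(resample_isotropic(w, 2, "linear")$data, w$data,
               tolerance = 1e-12)
})

test_that("body mask keeps the largest component and fills cavities", {
  d <- c(24, 24, 24)
  ell <- function(ctr, semi) {
    q <- lapply(1:3, function(a) ((seq_len(d[a]) - ctr[a]) / semi[a])^2
    )
    array(outer(outer(q[[1]], q[[2]], `+`), q[[3]], `+`) <= 1, d)
  }
  body <- ell(c(12, 12, 12), c(9, 9, 9))
  ct <- array(-1000, d)
  ct[body] <- 0
  bm <- body_mask(volume(ct, c(2, 2, 2), modality = "CT_HU"))
  expect_equal(bm$data != 0, body)

  cavity <- ell(c(12, 12, 12), c(3, 3, 3))
  ct2 <- ct
  ct2[cavity] <- -1000
  bm2 <- body_mask(volume(ct2, c(2, 2, 2), modality = "CT_HU"))
  expect_equal(bm2$data != 0, body)  # cavity filled

  small <- ell(c(4, 4, 4), c(2, 2, 2))
  ct3 <- ct
  ct3[small] <- 0
  bm3 <- body_mask(volume(ct3, c(2, 2, 2), modality = "CT_HU"))
  expect_equal(bm3$data != 0, body)  # smaller body dropped

  expect_error(body_mask(volume(array(-1000, d), modality = "CT_HU")),
               "unusable")
})

test_that("normalization gives mean 0 / population variance 1 inside the mask", {
  set.seed(3)
  v <- vol3(array(rnorm(27^3, 5, 2), c(27, 27, 27)))
  mask <- vol3(array(as.numeric(rand_mask(c(27, 27, 27), 0.4)), c(27, 27, 27)),
               modality = "LABEL")
  nv <- normalize_volume(v, mask)
  inside <- nv$data[mask$data != 0]
  expect_lt(abs(mean(inside)), 1e-6)
  expect_lt(abs(mean((inside - mean(inside))^2) - 1), 1e-6)

  # idempotence
  nv2 <- normalize_volume(nv, mask)
  expect_equal(nv2$data, nv$data, tolerance = 1e-8)

  # hand computation: {1,2,3} with population variance 2/3
  v3 <- vol3(array(c(1, 2, 3, rep(0, 24)), c(3, 3, 3)))
  m3 <- vol3(array(c(1, 1, 1, rep(0, 24)), c(3, 3, 3)), modality = "LABEL")
  n3 <- normalize_volume(v3, m3)
  s <- sqrt(2 / 3)
  expect_equal(n3$data[1:3], c(-1, 0, 1) / s, tolerance = 1e-12)

  flat <- vol3(array(7, c(3, 3, 3)))
  m <- vol3(array(1, c(3, 3, 3)), modality = "LABEL")
  expect_error(normalize_volume(flat, m), "variance")
})
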