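test_that("configuration invariants are enforced", {
  dflt <- deepmedic_config()
  expect_equal(dflt$conv_features, c(90, 90, 110, 110, 110, 110, 130, 130))
  expect_equal(dflt$fc_features, 250)
  expect_equal(dflt$downsample_factors, c(1, 3, 5))
  expect_equal(output_tile_size(dflt), 9)  # 25 - 8*2

  expect_error(deepmedic_config(patch_size = 16), "output tile")
  expect_error(deepmedic_config(downsample_factors = c(2, 3, 5)),
               "full resolution")
  expect_error(deepmedic_config(n_pathways = 2), "per pathway")
})

test_that("a tiny network runs forward to the right tile shape", {
  cfg <- small_net_config()
  set.seed(1)
  params <- lymphseg:::init_params(cfg)
  pet <- vol3(array(rnorm(20^3), c(20, 20, 20)))
  ct <- vol3(array(rnorm(20^3), c(20, 20, 20)), modality = "CT_HU")
  prep <- lymphseg:::prepare_network_inputs(pet, ct, cfg)
  tile <- lymphseg:::extract_tile_inputs(prep, c(2L, 2L, 2L), c(9L, 9L, 9L), cfg)
  # normal-pathway segment is 25^3 (9 + 2*8) and the output tile 9^3
  expect_equal(dim(tile$paths[[1]]), c(25, 25, 25, 2))
  fw <- lymphseg:::forward_tile(params, cfg, tile)
  expect_equal(dim(fw$prob), c(9^3, 2))
  expect_equal(rowSums(fw$prob), rep(1, 9^3), tolerance = 1e-12)

  # downsampled-pathway feature maps match the normal tile after upsampling
  expect_gte(prod(dim(tile$paths[[2]])[1:3] - 16) * 27, 9^3)
})

test_that("patch sampling balances classes deterministically", {
  cs <- small_phantom_cases(1, seed = 21, grid = 32)[[1]]
  cfg <- small_net_config()
  pats <- sample_patches(cs, n = 40, positive_fraction = 0.5, seed = 3,
                         config = cfg)
  expect_length(pats, 40)
  flags <- vapply(pats, `[[`, TRUE, "center_is_positive")
  expect_equal(sum(flags), 20)
  ref <- cs$reference$data != 0
  for (p in pats) {
    ctr <- p$center + 1L
    expect_equal(ref[ctr[1], ctr[2], ctr[3]], p$center_is_positive)
  }

  neg <- sample_patches(cs, n = 10, positive_fraction = 0, seed = 4,
                        config = cfg)
  expect_true(all(!vapply(neg, `[[`, TRUE, "center_is_positive")))

  again <- sample_patches(cs, n = 40, positive_fraction = 0.5, seed = 3,
                          config = cfg)
  expect_identical(lapply(pats, `[[`, "center"),
                   lapply(again, `[[`, "center"))

  empty <- cs
  empty$reference$data[] <- 0
  expect_error(sample_patches(empty, 10, 0.5, 1, cfg), "no positive")
})

test_that("training reduces the loss and is reproducible by seed", {
  cases <- small_phantom_cases(3, seed = 33, grid = 32)
  cfg <- small_net_config(epochs = 3, steps_per_epoch = 4, batch_size = 6)
  m <- deepmedic_fit(cases, cfg)
  expect_lt(m$history$loss[nrow(m$history)], m$history$loss[1])

  cfg2 <- small_net_config(epochs = 1, steps_per_epoch = 2, batch_size = 4)
  m1 <- deepmedic_fit(cases[1], cfg2)
  m2 <- deepmedic_fit(cases[1], cfg2)
  expect_identical(m1$params, m2$params)

  expect_error(deepmedic_fit(list(), cfg2), "empty training set")
})

test_that("dense inference matches grid, range and is tiling-invariant", {
  cs <- small_phantom_cases(1, seed = 44, grid = 24)[[1]]
  cfg <- small_net_config(epochs = 1, steps_per_epoch = 2, batch_size = 4)
  m <- deepmedic_fit(list(cs), cfg)
  p_one <- predict(m, cs$pet_in, cs$ct_in, tile = 24L)   # single pass
  p_tiled <- predict(m, cs$pet_in, cs$ct_in, tile = 7L)  # many tiles
  expect_equal(dim(p_one$data), dim(cs$pet$data))
  expect_true(all(p_one$data >= 0 & p_one$data <= 1))
  expect_equal(p_tiled$data, p_one$data, tolerance = 1e-5)

  # body masking zeroes outside probabilities
  pb <- predict(m, cs$pet_in, cs$ct_in, body = cs$body, tile = 24L)
  expect_true(all(pb$data[cs$body$data == 0] == 0))

  bad_ct <- vol3(array(0, c(10, 10, 10)), modality = "CT_HU")
  expect_error(predict(m, cs$pet_in, bad_ct), "grid")
})

test_that("checkpoints round-trip through the JSON + weights-blob format", {
  tmp <- withr::local_tempdir()
  cs <- small_phantom_cases(1, seed = 90, grid = 24)[[1]]
  cfg <- small_net_config(epochs = 1, steps_per_epoch = 2, batch_size = 4)
  m <- deepmedic_fit(list(cs), cfg)
  stem <- file.path(tmp, "ckpt")
  save_deepmedic(m, stem)
  expect_true(file.exists(paste0(stem, ".json")))
  expect_true(file.exists(paste0(stem, ".bin")))
  back <- load_deepmedic(stem)
  expect_equal(back$params, m$params, tolerance = 1e-15)
  expect_equal(back$config$conv_features, m$config$conv_features)
  # reloaded model predicts identically
  p1 <- predict(m, cs$pet_in, cs$ct_in, tile = 24L)
  p2 <- predict(back, cs$pet_in, cs$ct_in, tile = 24L)
  expect_identical(p1$data, p2$data)
})

test_that("binarize is monotone in the cut point", {
  set.seed(2)
  pr <- vol3(array(runif(6^3), c(6, 6, 6)), modality = "PROBABILITY")
  expect_equal(sum(binarize(pr, 0)), 6^3)
  expect_equal(sum(binarize(pr, 1)), sum(pr$data >= 1))
  prev <- binarize(pr, 0)
  for (cp in seq(0.1, 0.9, by = 0.2)) {
    cur <- binarize(pr, cp)
    expect_true(all(prev[cur]))
    prev <- cur
  }
  expect_error(binarize(pr, 1.5), "\\[0, 1\\]")
})
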