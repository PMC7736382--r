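test_that("segmentation scores satisfy their defining identities", {
  d <- c(8, 8, 8)
  m <- rand_mask(d, 0.3)
  s <- score_segmentation(m, m)
  expect_equal(c(s$dsc, s$sensitivity, s$ppv), c(1, 1, 1))

  a <- array(FALSE, d); a[1:5] <- TRUE
  b <- array(FALSE, d); b[6:10] <- TRUE
  s2 <- score_segmentation(a, b)
  expect_equal(c(s2$dsc, s2$sensitivity, s2$ppv), c(0, 0, 0))

  # |pred| = 100, |ref| = 80, tp = 60
  pred <- array(FALSE, d); pred[1:100] <- TRUE
  ref <- array(FALSE, d); ref[41:120] <- TRUE
  s3 <- score_segmentation(pred, ref)
  expect_equal(s3$sensitivity, 0.75)
  expect_equal(s3$ppv, 0.60)
  expect_equal(s3$dsc, 2 * 60 / 180, tolerance = 1e-12)

  s4 <- score_segmentation(array(FALSE, d), array(FALSE, d))
  expect_true(is.na(s4$dsc) && "both_masks_empty" %in% s4$flags)
})

test_that("Pearson correlation and RPD match their closed forms", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1.0)
  expect_equal(pearson_r(1:10, -(1:10)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(r0 <- pearson_r(rep(1, 5), 1:5), "variance")
  expect_true(is.na(r0))

  expect_equal(rpd(95.8, 100), -4.2)
  expect_equal(rpd(7, 7), 0)
  expect_equal(rpd(14, 7), 100)
  expect_warning(bad <- rpd(1, 0), "undefined")
  expect_true(is.na(bad))
})

test_that("agreement summaries count exact matches and summarize RPD", {
  set.seed(8)
  ref <- runif(20, 5, 20)
  same <- summarize_agreement(ref, ref, exact_match = TRUE)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$rpd_median, 0)
  expect_equal(same$n_exact_matches, 20)

  auto <- ref
  auto[7] <- auto[7] * 1.5
  one_off <- summarize_agreement(auto, ref, exact_match = TRUE)
  expect_equal(one_off$n_exact_matches, 19)

  # median/IQR of RPD agree with a sort-based quantile oracle
  auto2 <- ref * runif(20, 0.8, 1.2)
  agg <- summarize_agreement(auto2, ref)
  rp <- 100 * (auto2 - ref) / ref
  expect_equal(agg$rpd_median, unname(quantile(rp, 0.5, type = 7)))
  expect_equal(agg$rpd_iqr,
               unname(quantile(rp, c(0.25, 0.75), type = 7)))
  expect_equal(agg$pearson_r, oracle_pearson(auto2, ref), tolerance = 1e-12)

  expect_error(summarize_agreement(1:3, 1:4), "equal length")
})

test_that("subgroup analysis splits at the median with ties to low", {
  set.seed(12)
  n <- 9
  tab <- data.frame(mtv_ref = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                    dsc = runif(n, 0.5, 1),
                    mtv_rpd = rnorm(n, 0, 10))
  sg <- subgroup_analysis(tab, "mtv_ref")
  expect_equal(sg$cut_value, 5)
  expect_equal(sg$group_low$n, 5)   # odd cohort: median case goes low
  expect_equal(sg$group_high$n, 4)

  # completely separated DSC, 5 vs 5 -> exact two-sided p = 2/252
  tab2 <- data.frame(mtv_ref = 1:10,
                     dsc = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95),
                     mtv_rpd = c(rnorm(10, 0, 5)))
  sg2 <- subgroup_analysis(tab2, "mtv_ref")
  expect_equal(unname(sg2$wilcoxon_p["dsc"]), 2 / 252, tolerance = 1e-12)

  expect_error(subgroup_analysis(tab[1:3, ], "mtv_ref"), "degenerate")
  expect_error(subgroup_analysis(tab, "nope"), "not found")
})

test_that("the exact rank-sum p matches full enumeration for small groups", {
  set.seed(77)
  for (nx in c(3, 5, 8)) {
    for (rep in 1:3) {
      x <- rnorm(nx)
      y <- rnorm(nx) + rep - 2
      expect_equal(lymphseg:::wilcoxon_ranksum(x, y), oracle_wilcox_p(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("threshold sweep is monotone and summarizes cohort medians", {
  set.seed(19)
  d <- c(12, 12, 12)
  lesion <- array(FALSE, d); lesion[4:7, 4:7, 4:7] <- TRUE
  pet <- array(0.5, d); pet[lesion] <- 6
  ct <- vol3(array(40, d), modality = "CT_HU")
  mk_case <- function(s) {
    set.seed(s)
    probs <- lapply(1:3, function(i) {
      pr <- pmin(pmax(as.numeric(lesion) * 0.8 +
                        runif(prod(d), 0, 0.3), 0), 1)
      vol3(array(pr, d), modality = "PROBABILITY")
    })
    list(prob_maps = probs, pet = vol3(pet), ct = ct,
         reference = vol3(array(as.numeric(lesion), d), modality = "LABEL"))
  }
  cases <- lapply(1:3, mk_case)
  cuts <- seq(0.1, 0.9, by = 0.2)
  sw <- threshold_sweep(cases, cut_points = cuts)
  for (ci in 1:3) {
    sub <- sw$per_case[sw$per_case$case == ci, ]
    sub <- sub[order(sub$cut), ]
    expect_true(all(diff(sub$pred_voxels) <= 0))
    expect_true(all(diff(sub$sensitivity) <= 1e-12))
  }
  # cohort median equals the hand-computed median of per-case values
  for (cp in cuts) {
    vals <- sw$per_case$dsc[sw$per_case$cut == cp]
    expect_equal(sw$summary$dsc_median[sw$summary$cut == cp],
                 median(vals))
  }
  expect_error(threshold_sweep(cases, cut_points = c(-0.1, 0.5)), "\\[0, 1\\]")
})
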