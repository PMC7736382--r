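# Evaluation protocol: voxelwise segmentation scores, probability-cut
# sweeps, feature-agreement statistics and median-dichotomized subgroup
# comparisons.

#' Voxelwise segmentation score
#'
#' @param pred,ref logical/0-1 3D arrays (or binary `LABEL` [volume()]s)
#'   on the same grid.
#' @return An object of class `segmentation_score` with `tp`, `fp`, `fn`,
#'   `dsc = 2*tp / (2*tp + fp + fn)`, `sensitivity = tp / (tp + fn)` and
#'   `ppv = tp / (tp + fp)`. When both masks are empty the three scores
#'   are `NA` and flagged.
#' @export
score_segmentation <- function(pred, ref) {
  if (is_volume(pred)) pred <- pred$data
  if (is_volume(ref)) ref <- ref$data
  p <- pred != 0
  r <- ref != 0
  if (!identical(dim(p), dim(r))) stop("masks do not share a grid")
  tp <- sum(p & r)
  fp <- sum(p & !r)
  fn <- sum(!p & r)
  flags <- character(0)
  if (tp + fp + fn == 0) {
    dsc <- sens <- ppv <- NA_real_
    flags <- "both_masks_empty"
  } else {
    dsc <- 2 * tp / (2 * tp + fp + fn)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  }
  structure(list(dsc = dsc, sensitivity = sens, ppv = ppv,
                 tp = tp, fp = fp, fn = fn, flags = flags),
            class = "segmentation_score")
}

#' @export
print.segmentation_score <- function(x, ...) {
  cat(sprintf("DSC %.3f  sensitivity %.3f  PPV %.3f  (tp %d, fp %d, fn %d)\n",
              x$dsc, x$sensitivity, x$ppv, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Segmentation performance as a function of the probability cut point
#'
#' For each cut point, runs the full ensemble post-processing for every
#' case and scores the result against its reference, returning per-case
#' scores plus the cohort median and interquartile range (linear-
#' interpolation quantiles) per cut.
#'
#' @param cases list of lists, each with `prob_maps` (list of
#'   `PROBABILITY` volumes), `pet`, `ct` and `reference`.
#' @param cut_points numeric vector of cut points in \[0, 1\].
#' @param ... passed to [postprocess_ensemble()].
#' @return List with `per_case` (data frame: case, cut, dsc, sensitivity,
#'   ppv, pred_voxels) and `summary` (per-cut median and quartiles of
#'   each score).
#' @export
threshold_sweep <- function(cases, cut_points = seq(0.05, 0.95, by = 0.1),
                            ...) {
  if (any(cut_points < 0 | cut_points > 1))
    stop("cut points must lie in [0, 1]")
  rows <- list()
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    for (cp in cut_points) {
      ens <- postprocess_ensemble(cs$prob_maps, cs$pet, cs$ct,
                                  cut_point = cp, ...)
      sc <- score_segmentation(ens$final_mask, cs$reference)
      rows[[length(rows) + 1]] <-
        data.frame(case = ci, cut = cp, dsc = sc$dsc,
                   sensitivity = sc$sensitivity, ppv = sc$ppv,
                   pred_voxels = sum(ens$final_mask$data))
    }
  }
  per_case <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(sort(unique(per_case$cut)), function(cp) {
    sub <- per_case[per_case$cut == cp, ]
    qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE,
                                      names = FALSE, type = 7)
    d <- qs(sub$dsc); s <- qs(sub$sensitivity); p <- qs(sub$ppv)
    data.frame(cut = cp, dsc_median = d[2], dsc_q1 = d[1], dsc_q3 = d[3],
               sens_median = s[2], sens_q1 = s[1], sens_q3 = s[3],
               ppv_median = p[2], ppv_q1 = p[1], ppv_q3 = p[3])
  }))
  list(per_case = per_case, summary = summ)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (n >= 3), each with
#'   non-zero variance.
#' @return Sample Pearson correlation in \[-1, 1\]; `NA` (with a warning)
#'   when a vector has zero variance.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}

#' Relative percent difference
#'
#' `100 * (auto - ref) / ref`; `NA` (flagged via warning) when the
#' reference value is 0.
#' @param auto,ref numeric (vectorised).
#' @return Percent difference(s).
#' @export
rpd <- function(auto, ref) {
  out <- 100 * (auto - ref) / ref
  out[ref == 0] <- NA_real_
  if (any(ref == 0)) warning("reference value 0; RPD undefined for those pairs")
  out
}

#' Agreement between automated and reference feature columns
#'
#' @param auto,ref paired numeric vectors (automated and reference values
#'   of one metric across the cohort).
#' @param exact_match also count pairs equal within relative tolerance
#'   1e-6 (used for SUVmax, where agreement means the same voxel was
#'   selected).
#' @return An `agreement_summary`: `pearson_r`, `rpd_median`, `rpd_iqr`
#'   (linear-interpolation quartiles, %), `n`, and `n_exact_matches` when
#'   requested.
#' @export
summarize_agreement <- function(auto, ref, exact_match = FALSE) {
  if (length(auto) != length(ref)) stop("auto and ref must have equal length")
  r <- pearson_r(auto, ref)
  keep <- is.finite(auto) & is.finite(ref) & ref != 0
  rp <- 100 * (auto[keep] - ref[keep]) / ref[keep]
  qs <- stats::quantile(rp, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  out <- list(pearson_r = r, rpd_median = qs[2], rpd_iqr = c(qs[1], qs[3]),
              n = sum(keep))
  if (exact_match) {
    fin <- is.finite(auto) & is.finite(ref)
    tol <- 1e-6 * pmax(abs(auto[fin]), abs(ref[fin]), 1e-300)
    out$n_exact_matches <- sum(abs(auto[fin] - ref[fin]) <= tol)
  }
  structure(out, class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("r = %.3f; RPD median %.2f%% (IQR %.2f to %.2f%%), n = %d",
              x$pearson_r, x$rpd_median, x$rpd_iqr[1], x$rpd_iqr[2], x$n))
  if (!is.null(x$n_exact_matches))
    cat(sprintf("; exact matches %d/%d", x$n_exact_matches, x$n))
  cat("\n")
  invisible(x)
}

wilcoxon_ranksum <- function(x, y) {
  # exact distribution for small samples without ties, normal
  # approximation with continuity and tie correction otherwise
  use_exact <- length(x) <= 25 && length(y) <= 25 &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = TRUE)$p.value)
}

#' Median-dichotomized subgroup analysis
#'
#' Splits the cohort at the median of a disease characteristic (ties go
#' to the low group, so with an odd cohort the median case is in the low
#' group) and compares segmentation accuracy between subgroups with
#' two-sided Wilcoxon rank-sum tests on DSC and on |RPD of MTV|.
#'
#' @param table data frame with one row per case, containing the
#'   dichotomizing feature column plus `dsc` and `mtv_rpd`.
#' @param dichotomize_by name of the feature column (e.g. `"mtv_ref"`).
#' @return A `subgroup_result`: cut value, per-group summaries (n, median
#'   DSC, median |MTV RPD|) and Wilcoxon p-values for both outcomes.
#' @export
subgroup_analysis <- function(table, dichotomize_by) {
  if (!dichotomize_by %in% names(table))
    stop("column not found: ", dichotomize_by)
  x <- table[[dichotomize_by]]
  cut_value <- stats::median(x)
  low <- x <= cut_value
  if (sum(low) < 2 || sum(!low) < 2)
    stop("degenerate split: need at least 2 cases per subgroup")
  grp <- function(sel) list(
    n = sum(sel),
    dsc_median = stats::median(table$dsc[sel], na.rm = TRUE),
    abs_mtv_rpd_median = stats::median(abs(table$mtv_rpd[sel]), na.rm = TRUE))
  p_dsc <- wilcoxon_ranksum(table$dsc[low], table$dsc[!low])
  p_rpd <- wilcoxon_ranksum(abs(table$mtv_rpd[low]), abs(table$mtv_rpd[!low]))
  structure(list(dichotomizing_feature = dichotomize_by,
                 cut_value = cut_value,
                 group_low = grp(low), group_high = grp(!low),
                 wilcoxon_p = c(dsc = p_dsc, abs_mtv_rpd = p_rpd)),
            class = "subgroup_result")
}

#' @export
print.subgroup_result <- function(x, ...) {
  cat(sprintf("Subgroups by median %s (cut %.3g):\n",
              x$dichotomizing_feature, x$cut_value))
  cat(sprintf("  low  (n=%d): DSC median %.3f, |MTV RPD| median %.2f%%\n",
              x$group_low$n, x$group_low$dsc_median,
              x$group_low$abs_mtv_rpd_median))
  cat(sprintf("  high (n=%d): DSC median %.3f, |MTV RPD| median %.2f%%\n",
              x$group_high$n, x$group_high$dsc_median,
              x$group_high$abs_mtv_rpd_median))
  cat(sprintf("  Wilcoxon p: DSC %.4g, |MTV RPD| %.4g\n",
              x$wilcoxon_p["dsc"], x$wilcoxon_p["abs_mtv_rpd"]))
  invisible(x)
}
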