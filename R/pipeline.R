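# Workflow plumbing: case preprocessing, cross-validation splitting,
# ensemble training and the end-to-end pipeline producing an evaluation
# report.

#' Preprocess a PET/CT case
#'
#' Resamples PET (linear) and any label volumes (nearest) to an isotropic
#' grid, derives the body mask from CT, and builds the normalized network
#' inputs: PET and CT are z-scored independently against the body mask,
#' the CT copy being clipped to \[-1000, 1000\] HU first to bound the
#' influence of implants. The unclipped HU volume is kept for bone
#' exclusion and the SUV volume for thresholding and features. When
#' template ROIs are given and no reference mask is, the reference is
#' built with [build_reference()].
#'
#' @param pet `PET_SUV` [volume()]; @param ct `CT_HU` [volume()].
#' @param rois optional template-ROI `LABEL` [volume()].
#' @param reference optional reference `LABEL` [volume()].
#' @param case_id identifier string.
#' @param target_spacing isotropic grid spacing, mm (default 2).
#' @return A case list with `pet`, `ct`, `reference`, `rois`, `body`,
#'   `pet_in`, `ct_in` all on the common grid.
#' @export
preprocess_case <- function(pet, ct, rois = NULL, reference = NULL,
                            case_id = "case", target_spacing = 2) {
  pet <- resample_isotropic(pet, target_spacing, "linear")
  ct <- resample_isotropic(ct, target_spacing, "linear")
  stopifnot_same_grid(pet, ct, "resampled PET and CT")
  if (!is.null(rois)) rois <- resample_isotropic(rois, target_spacing, "nearest")
  if (!is.null(reference))
    reference <- resample_isotropic(reference, target_spacing, "nearest")
  body <- body_mask(ct)
  if (is.null(reference) && !is.null(rois))
    reference <- build_reference(pet, rois)
  list(case_id = case_id, pet = pet, ct = ct, reference = reference,
       rois = rois, body = body,
       pet_in = normalize_volume(pet, body),
       ct_in = normalize_volume(ct, body, clip = c(-1000, 1000)))
}

#' Random cross-validation fold assignment
#'
#' Partitions cases into folds of near-equal size (sizes differ by at
#' most one); deterministic given the seed.
#'
#' @param case_ids character or integer vector of case identifiers.
#' @param n_folds number of folds (`2 <= n_folds <= length(case_ids)`).
#' @param seed RNG seed.
#' @return Integer vector of fold assignments (1..n_folds), named by
#'   case id.
#' @export
split_folds <- function(case_ids, n_folds = 5, seed = 1L) {
  n <- length(case_ids)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n_folds > n) stop("more folds than cases")
  set.seed(seed)
  ord <- sample.int(n)
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(n_folds), n)
  names(fold) <- as.character(case_ids)
  fold
}

#' Train an ensemble of networks
#'
#' Trains `n_members` identically configured networks that differ only in
#' their random initialisation and patch sampling (distinct derived
#' seeds), the published route to false-positive suppression by
#' intersecting their outputs.
#'
#' @param cases training cases ([preprocess_case()]).
#' @param config a [deepmedic_config()]; member m uses seed
#'   `config$seed + 101 * (m - 1)`.
#' @param n_members ensemble size (default 3).
#' @param validation optional validation cases (best-epoch checkpointing).
#' @param verbose print training progress.
#' @return An object of class `deepmedic_ensemble` (list of `deepmedic`
#'   models).
#' @export
fit_ensemble <- function(cases, config = deepmedic_config(), n_members = 3,
                         validation = NULL, verbose = FALSE) {
  stopifnot(n_members >= 1)
  members <- lapply(seq_len(n_members), function(m) {
    cfg <- config
    cfg$seed <- config$seed + 101L * (m - 1L)
    deepmedic_fit(cases, cfg, validation = validation, verbose = verbose)
  })
  structure(list(members = members, config = config),
            class = "deepmedic_ensemble")
}

#' @export
print.deepmedic_ensemble <- function(x, ...) {
  cat(sprintf("<deepmedic_ensemble> %d member(s)\n", length(x$members)))
  print(x$config)
  invisible(x)
}

#' Per-member probability maps for one case
#'
#' @param object a `deepmedic_ensemble`.
#' @param case a preprocessed case (normalized inputs and body mask).
#' @param tile inference tile size.
#' @param ... unused.
#' @return List of `PROBABILITY` [volume()]s, one per member.
#' @export
predict.deepmedic_ensemble <- function(object, case, tile = 32L, ...) {
  lapply(object$members, function(m)
    predict(m, case$pet_in, case$ct_in, body = case$body, tile = tile))
}

#' Run the full automated segmentation pipeline
#'
#' Cross-validates the whole method on a cohort: per fold, trains an
#' ensemble on the training cases (with a nested train/validation split
#' of about 7:1 used for best-epoch checkpointing), predicts the held-out
#' cases, applies the ensemble post-processing, extracts features from
#' automated and reference masks and assembles the evaluation report.
#'
#' @param cases list of preprocessed cases with reference masks.
#' @param config a [deepmedic_config()].
#' @param n_folds folds (>= 2); every case is held out exactly once.
#' @param ensemble_size networks per ensemble (1 = single-CNN mode,
#'   flagged in the report).
#' @param cut_point probability cut point for binarization.
#' @param bone_fraction see [exclude_bone()].
#' @param seed seed controlling fold splitting and per-fold training
#'   seeds.
#' @param val_fraction fraction of each fold's training cases set aside
#'   for validation (default 1/8, i.e. 7:1 train:validation); 0 disables.
#' @param tile inference tile size.
#' @param keep_probability retain per-case member probability maps in the
#'   report (needed for [threshold_sweep()] afterwards).
#' @param out_dir optional directory: writes final/member masks (NIfTI),
#'   the feature table (CSV), per-case scores (CSV), the report (JSON)
#'   and a run log with all seeds and configuration.
#' @param verbose print progress.
#' @return An object of class `lymphseg_report`: `per_case` (scores and
#'   feature RPDs), `features` (long table, reference and automated
#'   rows), `agreement` (per-metric [summarize_agreement()]),
#'   `subgroups`, `member_fp_voxels`, `single_cnn_mode`, `folds`,
#'   and optionally `probability_maps`.
#' @export
run_pipeline <- function(cases, config = deepmedic_config(), n_folds = 5,
                         ensemble_size = 3, cut_point = 0.5,
                         bone_fraction = 0.5, seed = 1L, val_fraction = 1 / 8,
                         tile = 32L, keep_probability = FALSE, out_dir = NULL,
                         verbose = FALSE) {
  if (!length(cases)) stop("pipeline stage 'input': empty cohort")
  for (cs in cases)
    if (is.null(cs$reference))
      stop("pipeline stage 'input': case ", cs$case_id, " has no reference")
  ids <- vapply(cases, `[[`, "", "case_id")
  folds <- split_folds(ids, n_folds = n_folds, seed = seed)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  log_lines <- c(sprintf("lymphseg run, %s", format(Sys.time())),
                 sprintf("seed %d, folds %d, ensemble %d, cut %.2f",
                         seed, n_folds, ensemble_size, cut_point))

  per_case <- list()
  feat_rows <- list()
  fp_rows <- list()
  probs_kept <- list()
  for (f in sort(unique(folds))) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    n_val <- if (val_fraction > 0) floor(length(train_idx) * val_fraction)
             else 0L
    set.seed(seed + 31L * f)
    val_idx <- if (n_val >= 1) sample(train_idx, n_val) else integer(0)
    tr_idx <- setdiff(train_idx, val_idx)
    cfg <- config
    cfg$seed <- config$seed + 1009L * (f - 1L)
    if (verbose)
      message(sprintf("fold %d: %d train, %d val, %d test", f,
                      length(tr_idx), length(val_idx), length(test_idx)))
    ens <- fit_ensemble(cases[tr_idx], cfg, n_members = ensemble_size,
                        validation = if (length(val_idx)) cases[val_idx],
                        verbose = verbose)
    log_lines <- c(log_lines,
                   sprintf("fold %d: train=[%s] val=[%s] member seeds=[%s]",
                           f, paste(ids[tr_idx], collapse = ","),
                           paste(ids[val_idx], collapse = ","),
                           paste(cfg$seed + 101L * (seq_len(ensemble_size) - 1L),
                                 collapse = ",")))
    for (ti in test_idx) {
      cs <- cases[[ti]]
      probs <- predict(ens, cs, tile = tile)
      ens_out <- postprocess_ensemble(probs, cs$pet, cs$ct,
                                      cut_point = cut_point,
                                      bone_fraction = bone_fraction)
      sc <- score_segmentation(ens_out$final_mask, cs$reference)
      fa <- extract_features(cs$pet, ens_out$final_mask)
      fr <- extract_features(cs$pet, cs$reference)
      ref_voxels <- cs$reference$data != 0
      member_fp <- vapply(ens_out$member_masks,
                          function(m) sum(m & !ref_voxels), numeric(1))
      per_case[[length(per_case) + 1]] <- data.frame(
        case_id = cs$case_id, fold = f, dsc = sc$dsc,
        sensitivity = sc$sensitivity, ppv = sc$ppv,
        tp = sc$tp, fp = sc$fp, fn = sc$fn,
        mtv_ref = fr$mtv, mtv_auto = fa$mtv,
        mtv_rpd = if (fr$mtv > 0) 100 * (fa$mtv - fr$mtv) / fr$mtv else NA,
        sa_mtv_ref = fr$sa_mtv, dmax_ref = fr$dmax_patient,
        stringsAsFactors = FALSE)
      feat_rows[[length(feat_rows) + 1]] <- feature_row(cs$case_id, fr,
                                                        "reference")
      feat_rows[[length(feat_rows) + 1]] <- feature_row(cs$case_id, fa,
                                                        "automated")
      fp_rows[[length(fp_rows) + 1]] <- data.frame(
        case_id = cs$case_id, member = seq_along(member_fp),
        fp_voxels = member_fp, ensemble_fp_voxels = sc$fp)
      if (keep_probability)
        probs_kept[[cs$case_id]] <- list(prob_maps = probs, pet = cs$pet,
                                         ct = cs$ct,
                                         reference = cs$reference)
      if (!is.null(out_dir)) {
        cdir <- file.path(out_dir, cs$case_id)
        dir.create(cdir, showWarnings = FALSE)
        write_volume(ens_out$final_mask, file.path(cdir, "automated.nii.gz"))
        for (m in seq_along(ens_out$member_masks))
          write_volume(volume(array(as.numeric(ens_out$member_masks[[m]]),
                                    dim(cs$pet$data)),
                              cs$pet$spacing, cs$pet$origin, "LABEL"),
                       file.path(cdir, sprintf("member_%d.nii.gz", m)))
      }
    }
  }
  per_case <- do.call(rbind, per_case)
  features <- do.call(rbind, feat_rows)
  fp_table <- do.call(rbind, fp_rows)

  wide <- function(col) {
    a <- features[features$source == "automated", c("case_id", col)]
    r <- features[features$source == "reference", c("case_id", col)]
    m <- merge(r, a, by = "case_id", suffixes = c("_ref", "_auto"))
    m[match(unique(features$case_id), m$case_id), ]
  }
  agreement <- list()
  for (metric in c("suv_max", "mtv_cm3", "tlg", "sa_mtv_cm1", "dmax_cm")) {
    w <- wide(metric)
    agreement[[metric]] <- tryCatch(
      summarize_agreement(w[[paste0(metric, "_auto")]],
                          w[[paste0(metric, "_ref")]],
                          exact_match = metric == "suv_max"),
      error = function(e) NULL, warning = function(w) NULL)
  }
  subgroups <- list()
  for (by in c("mtv_ref", "sa_mtv_ref", "dmax_ref")) {
    subgroups[[by]] <- tryCatch(subgroup_analysis(per_case, by),
                                error = function(e) NULL)
  }

  report <- structure(list(
    per_case = per_case, features = features, agreement = agreement,
    subgroups = subgroups, member_fp_voxels = fp_table,
    single_cnn_mode = ensemble_size == 1, folds = folds,
    config = config, cut_point = cut_point, seed = seed,
    probability_maps = if (keep_probability) probs_kept
  ), class = "lymphseg_report")

  if (!is.null(out_dir)) {
    write.csv(per_case, file.path(out_dir, "per_case_scores.csv"),
              row.names = FALSE)
    write.csv(features, file.path(out_dir, "feature_table.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(
      per_case = per_case,
      agreement = lapply(agreement, unclass),
      subgroups = lapply(subgroups, unclass),
      single_cnn_mode = ensemble_size == 1),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    writeLines(c(log_lines,
                 paste0("config: ",
                        jsonlite::toJSON(unclass(config), auto_unbox = TRUE))),
               file.path(out_dir, "run_log.txt"))
  }
  report
}

#' @export
print.lymphseg_report <- function(x, ...) {
  cat(sprintf("<lymphseg_report> %d cases, %d folds%s\n",
              nrow(x$per_case), length(unique(x$folds)),
              if (x$single_cnn_mode) " [single-CNN mode]" else ""))
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE,
                                    names = FALSE)
  d <- qs(x$per_case$dsc); s <- qs(x$per_case$sensitivity)
  p <- qs(x$per_case$ppv)
  cat(sprintf("  DSC median %.3f (IQR %.3f-%.3f); sensitivity %.3f; PPV %.3f\n",
              d[2], d[1], d[3], s[2], p[2]))
  for (nm in names(x$agreement)) {
    if (is.null(x$agreement[[nm]])) next
    cat(sprintf("  %-10s ", nm)); print(x$agreement[[nm]])
  }
  invisible(x)
}

#' @export
summary.lymphseg_report <- function(object, ...) {
  print(object)
  for (sg in object$subgroups) if (!is.null(sg)) print(sg)
  invisible(object)
}
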