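# Multi-resolution-pathway 3D patch network for voxelwise lymphoma
# classification. Each pathway applies 8 valid (unpadded) 3x3x3
# convolutions; downsampled pathways see the image average-pooled by their
# factor, and their outputs are upsampled by nearest-neighbour repetition
# and cropped to the normal pathway's output tile. Concatenated features
# pass through two 1x1x1 "fully connected" layers and a 2-class softmax
# per voxel. Training minimises voxelwise cross-entropy with Adam on
# class-balanced patches.

#' Network configuration
#'
#' Describes one network: pathways, per-layer feature counts, patch
#' geometry and training hyper-parameters. The defaults follow the
#' published multi-resolution architecture: three pathways at resolution
#' factors 1, 3 and 5; eight 3x3x3 convolutional layers with 90, 90, 110,
#' 110, 110, 110, 130 and 130 features; two fully connected layers of 250
#' features; 25-voxel input patches (so the output tile is 9^3).
#'
#' @param n_pathways number of resolution pathways.
#' @param downsample_factors integer per pathway; first must be 1.
#' @param conv_features feature count per convolutional layer.
#' @param fc_features features in each of the two fully connected layers.
#' @param n_classes number of output classes (2: background / lymphoma).
#' @param in_channels input channels (2: PET and CT).
#' @param patch_size training patch edge length in voxels; must exceed
#'   twice the number of convolutional layers so a valid-convolution
#'   output tile remains.
#' @param seed RNG seed controlling initialisation and sampling.
#' @param learning_rate,epochs,batch_size,steps_per_epoch,positive_fraction
#'   training hyper-parameters; `positive_fraction` is the fraction of
#'   patches centred on a lymphoma voxel (class balancing, default 0.5).
#' @return An object of class `deepmedic_config`.
#' @export
deepmedic_config <- function(n_pathways = 3,
                             downsample_factors = c(1, 3, 5),
                             conv_features = c(90, 90, 110, 110, 110, 110, 130, 130),
                             fc_features = 250,
                             n_classes = 2,
                             in_channels = 2,
                             patch_size = 25,
                             seed = 1L,
                             learning_rate = 1e-3,
                             epochs = 10,
                             batch_size = 10,
                             steps_per_epoch = 20,
                             positive_fraction = 0.5) {
  if (length(downsample_factors) != n_pathways)
    stop("downsample_factors must have one entry per pathway")
  if (downsample_factors[1] != 1)
    stop("the first pathway must be at full resolution (factor 1)")
  if (any(downsample_factors < 1 | downsample_factors != round(downsample_factors)))
    stop("downsample factors must be positive integers")
  if (any(conv_features < 1))
    stop("conv_features must be positive")
  if (patch_size <= 2 * length(conv_features))
    stop("patch_size must exceed 2 * number of conv layers ",
         "(valid convolutions must leave a non-empty output tile)")
  if (n_classes != 2) stop("only 2-class output is supported")
  if (positive_fraction < 0 || positive_fraction > 1)
    stop("positive_fraction must be in [0, 1]")
  structure(list(
    n_pathways = as.integer(n_pathways),
    downsample_factors = as.integer(downsample_factors),
    conv_features = as.integer(conv_features),
    fc_features = as.integer(fc_features),
    n_classes = 2L,
    in_channels = as.integer(in_channels),
    patch_size = as.integer(patch_size),
    seed = as.integer(seed),
    train = list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 positive_fraction = positive_fraction,
                 loss = "cross_entropy")
  ), class = "deepmedic_config")
}

#' @export
print.deepmedic_config <- function(x, ...) {
  cat("<deepmedic_config>\n")
  cat(sprintf("  pathways: %d (factors %s)\n", x$n_pathways,
              paste(x$downsample_factors, collapse = ", ")))
  cat(sprintf("  conv features: %s (3x3x3, valid)\n",
              paste(x$conv_features, collapse = ", ")))
  cat(sprintf("  fc features: %d x2; classes: %d; input channels: %d\n",
              x$fc_features, x$n_classes, x$in_channels))
  cat(sprintf("  patch %d^3 -> output tile %d^3; seed %d\n",
              x$patch_size, output_tile_size(x), x$seed))
  invisible(x)
}

#' Output tile edge length for a configuration
#'
#' Each valid 3x3x3 convolution trims one voxel per side, so the output
#' tile is `patch_size - 2 * n_conv_layers`.
#' @param config a [deepmedic_config()].
#' @return Integer edge length.
#' @export
output_tile_size <- function(config) {
  config$patch_size - 2L * length(config$conv_features)
}

relu <- function(x) { x[x < 0] <- 0; x }

## ---- parameters -----------------------------------------------------------

init_params <- function(config) {
  # He-scaled Gaussian initialisation; iteration order fixed so a given
  # RNG state always yields the same weights
  p <- list()
  for (pw in seq_len(config$n_pathways)) {
    cin <- config$in_channels
    for (l in seq_along(config$conv_features)) {
      cout <- config$conv_features[l]
      p[[sprintf("p%d.l%d.W", pw, l)]] <-
        matrix(rnorm(27 * cin * cout, 0, sqrt(2 / (27 * cin))), 27 * cin, cout)
      p[[sprintf("p%d.l%d.b", pw, l)]] <- rep(0, cout)
      cin <- cout
    }
  }
  ctot <- config$n_pathways * utils::tail(config$conv_features, 1)
  fcn <- config$fc_features
  p[["fc1.W"]] <- matrix(rnorm(ctot * fcn, 0, sqrt(2 / ctot)), ctot, fcn)
  p[["fc1.b"]] <- rep(0, fcn)
  p[["fc2.W"]] <- matrix(rnorm(fcn * fcn, 0, sqrt(2 / fcn)), fcn, fcn)
  p[["fc2.b"]] <- rep(0, fcn)
  p[["out.W"]] <- matrix(rnorm(fcn * config$n_classes, 0, sqrt(1 / fcn)),
                         fcn, config$n_classes)
  p[["out.b"]] <- rep(0, config$n_classes)
  p
}

zero_like <- function(params) lapply(params, function(x) x * 0)

## ---- input preparation ----------------------------------------------------

pool_volume <- function(arr, k) {
  # average-pool by factor k on a global grid anchored at index 0,
  # edge-replicating partial blocks; returns ceil(n/k)-sized array
  if (k == 1L) return(arr)
  d <- dim(arr)
  nl <- as.integer(ceiling(d / k))
  idx <- lapply(1:3, function(a) pmin(seq_len(nl[a] * k) - 1L, d[a] - 1L) + 1L)
  b <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  b <- array(b, c(k, nl[1], k, nl[2], k, nl[3]))
  b <- colMeans(b)                               # (nl1, k, nl2, k, nl3)
  b <- colMeans(aperm(b, c(2, 1, 3, 4, 5)))      # (nl1, nl2, k, nl3)
  b <- colMeans(aperm(b, c(3, 1, 2, 4)))         # (nl1, nl2, nl3)
  b
}

prepare_network_inputs <- function(pet_in, ct_in, config) {
  # pet_in/ct_in: normalized input volumes (same grid); precomputes the
  # per-pathway pooled images used for segment extraction
  chans <- list(pet_in$data, ct_in$data)
  pooled <- lapply(config$downsample_factors, function(k)
    lapply(chans, pool_volume, k = k))
  list(dim = dim(pet_in$data), pooled = pooled)
}

clamp_idx <- function(i, n) pmin(pmax(i, 0L), n - 1L) + 1L

extract_tile_inputs <- function(prep, o, tsz, config) {
  # o: 0-based tile start (length 3); tsz: tile size per axis.
  # Pathway segments are read from the globally pooled images with
  # edge-clamped indices, which makes dense tiled inference and
  # patch-wise training read identical values for identical voxels.
  R <- length(config$conv_features)
  paths <- vector("list", config$n_pathways)
  offs <- vector("list", config$n_pathways)
  for (pw in seq_len(config$n_pathways)) {
    k <- config$downsample_factors[pw]
    pooled <- prep$pooled[[pw]]
    np <- dim(pooled[[1]])
    j0 <- as.integer(floor(o / k)) - R
    j1 <- as.integer(ceiling((o + tsz) / k)) + R
    ix <- clamp_idx(j0[1]:(j1[1] - 1L), np[1])
    iy <- clamp_idx(j0[2]:(j1[2] - 1L), np[2])
    iz <- clamp_idx(j0[3]:(j1[3] - 1L), np[3])
    seg <- array(0, c(length(ix), length(iy), length(iz), length(pooled)))
    for (ch in seq_along(pooled))
      seg[, , , ch] <- pooled[[ch]][ix, iy, iz]
    paths[[pw]] <- seg
    offs[[pw]] <- o - k * as.integer(floor(o / k))
  }
  list(paths = paths, offsets = offs, tsz = as.integer(tsz))
}

## ---- forward / backward ---------------------------------------------------

forward_tile <- function(params, config, tile, keep = FALSE) {
  nl <- length(config$conv_features)
  tsz <- tile$tsz
  N <- prod(tsz)
  feats <- vector("list", config$n_pathways)
  cache <- if (keep) list(acts = vector("list", config$n_pathways),
                          up = vector("list", config$n_pathways)) else NULL
  for (pw in seq_len(config$n_pathways)) {
    a <- tile$paths[[pw]]
    acts <- if (keep) vector("list", nl + 1) else NULL
    if (keep) acts[[1]] <- a
    for (l in seq_len(nl)) {
      a <- relu(conv3d_forward_cpp(a, params[[sprintf("p%d.l%d.W", pw, l)]],
                                   params[[sprintf("p%d.l%d.b", pw, l)]]))
      if (keep) acts[[l + 1]] <- a
    }
    k <- config$downsample_factors[pw]
    if (k > 1L) {
      off <- tile$offsets[[pw]]
      ux <- floor((off[1] + 0:(tsz[1] - 1L)) / k) + 1L
      uy <- floor((off[2] + 0:(tsz[2] - 1L)) / k) + 1L
      uz <- floor((off[3] + 0:(tsz[3] - 1L)) / k) + 1L
      up <- a[ux, uy, uz, , drop = FALSE]
      if (keep) cache$up[[pw]] <- list(ux = ux, uy = uy, uz = uz,
                                       low_dim = dim(a))
    } else {
      up <- a
    }
    feats[[pw]] <- matrix(up, nrow = N)
    if (keep) cache$acts[[pw]] <- acts
  }
  M <- do.call(cbind, feats)
  h1 <- relu(sweep(M %*% params$fc1.W, 2, params$fc1.b, `+`))
  h2 <- relu(sweep(h1 %*% params$fc2.W, 2, params$fc2.b, `+`))
  logits <- sweep(h2 %*% params$out.W, 2, params$out.b, `+`)
  mx <- pmax(logits[, 1], logits[, 2])
  e <- exp(logits - mx)
  prob <- e / rowSums(e)
  if (keep) {
    cache$M <- M; cache$h1 <- h1; cache$h2 <- h2; cache$N <- N
  }
  list(prob = prob, cache = cache)
}

backward_tile <- function(params, config, tile, fw, labels) {
  # labels: integer vector (0/1), length N; returns list(loss, grads)
  cache <- fw$cache
  N <- cache$N
  prob <- fw$prob
  eps <- 1e-12
  loss <- -mean(log(prob[cbind(seq_len(N), labels + 1L)] + eps))
  g <- prob
  g[cbind(seq_len(N), labels + 1L)] <- g[cbind(seq_len(N), labels + 1L)] - 1
  g <- g / N

  grads <- list()
  grads$out.W <- crossprod(cache$h2, g)
  grads$out.b <- colSums(g)
  dh2 <- g %*% t(params$out.W)
  dh2[cache$h2 <= 0] <- 0
  grads$fc2.W <- crossprod(cache$h1, dh2)
  grads$fc2.b <- colSums(dh2)
  dh1 <- dh2 %*% t(params$fc2.W)
  dh1[cache$h1 <= 0] <- 0
  grads$fc1.W <- crossprod(cache$M, dh1)
  grads$fc1.b <- colSums(dh1)
  dM <- dh1 %*% t(params$fc1.W)

  nl <- length(config$conv_features)
  nfeat <- utils::tail(config$conv_features, 1)
  tsz <- tile$tsz
  for (pw in seq_len(config$n_pathways)) {
    cols <- ((pw - 1) * nfeat + 1):(pw * nfeat)
    dUp <- dM[, cols, drop = FALSE]
    k <- config$downsample_factors[pw]
    if (k > 1L) {
      u <- cache$up[[pw]]
      ld <- u$low_dim
      # linear index of each tile voxel's source low-res voxel
      lin <- (rep(u$uz, each = tsz[1] * tsz[2]) - 1L) * (ld[1] * ld[2]) +
        (rep(rep(u$uy, each = tsz[1]), times = tsz[3]) - 1L) * ld[1] +
        rep(u$ux, times = tsz[2] * tsz[3])
      s <- rowsum(dUp, group = lin)
      da_mat <- matrix(0, prod(ld[1:3]), nfeat)
      da_mat[as.integer(rownames(s)), ] <- s
      da <- array(da_mat, ld)
    } else {
      da <- array(dUp, c(tsz, nfeat))
    }
    acts <- cache$acts[[pw]]
    for (l in rev(seq_len(nl))) {
      da[acts[[l + 1]] <= 0] <- 0
      bw <- conv3d_backward_cpp(acts[[l]], params[[sprintf("p%d.l%d.W", pw, l)]], da)
      grads[[sprintf("p%d.l%d.W", pw, l)]] <- bw$gw
      grads[[sprintf("p%d.l%d.b", pw, l)]] <- as.numeric(bw$gb)
      da <- bw$gx
    }
  }
  list(loss = loss, grads = grads)
}

## ---- patch sampling -------------------------------------------------------

case_center_pools <- function(case) {
  ref <- case$reference$data != 0
  body <- if (!is.null(case$body)) case$body$data != 0 else array(TRUE, dim(ref))
  list(pos = which(ref), neg = which(body & !ref), dim = dim(ref))
}

center_to_ijk <- function(lin, d) {
  lin <- lin - 1L
  z <- lin %/% (d[1] * d[2])
  r <- lin %% (d[1] * d[2])
  cbind(r %% d[1], r %/% d[1], z)
}

#' Sample class-balanced training patches from one case
#'
#' Draws `round(n * positive_fraction)` patches centred on reference-
#' positive voxels and the remainder centred on body voxels outside the
#' reference. Patch context beyond the volume border is edge-padded.
#' Deterministic given `seed`.
#'
#' @param case a preprocessed case (see [preprocess_case()]) with
#'   `reference` and `body` masks and normalized `pet_in` / `ct_in`.
#' @param n number of patches.
#' @param positive_fraction fraction of lesion-centred patches.
#' @param seed RNG seed.
#' @param config a [deepmedic_config()].
#' @return List of patches, each with `center` (0-based voxel index),
#'   `center_is_positive`, per-pathway input arrays in `paths`, and the
#'   binary `label` tile matching the network output size.
#' @export
sample_patches <- function(case, n, positive_fraction = 0.5, seed = 1L,
                           config = deepmedic_config()) {
  pools <- case_center_pools(case)
  n_pos <- round(n * positive_fraction)
  if (n_pos > 0 && length(pools$pos) == 0)
    stop("case has no positive reference voxels to sample from")
  if (n - n_pos > 0 && length(pools$neg) == 0)
    stop("case has no negative (body minus reference) voxels to sample from")
  set.seed(seed)
  lin <- c(if (n_pos > 0) sample(pools$pos, n_pos, replace = TRUE),
           if (n - n_pos > 0) sample(pools$neg, n - n_pos, replace = TRUE))
  flags <- rep(c(TRUE, FALSE), c(n_pos, n - n_pos))
  centers <- center_to_ijk(lin, pools$dim)
  prep <- prepare_network_inputs(case$pet_in, case$ct_in, config)
  tsz <- rep(output_tile_size(config), 3)
  ref <- case$reference$data != 0
  d <- pools$dim
  lapply(seq_len(n), function(i) {
    o <- centers[i, ] - (tsz - 1L) %/% 2L
    tile <- extract_tile_inputs(prep, o, tsz, config)
    ix <- clamp_idx(o[1]:(o[1] + tsz[1] - 1L), d[1])
    iy <- clamp_idx(o[2]:(o[2] + tsz[2] - 1L), d[2])
    iz <- clamp_idx(o[3]:(o[3] + tsz[3] - 1L), d[3])
    list(center = centers[i, ], center_is_positive = flags[i],
         paths = tile$paths, offsets = tile$offsets, tsz = tile$tsz,
         label = array(as.integer(ref[ix, iy, iz]), tsz))
  })
}

## ---- training -------------------------------------------------------------

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

draw_epoch_centers <- function(pools, cases_with_pos, n, positive_fraction) {
  # balanced across the training set: each patch picks a case uniformly
  # (positives only from cases that have them), then a voxel from the
  # appropriate pool
  n_pos <- round(n * positive_fraction)
  draws <- vector("list", n)
  flags <- rep(c(TRUE, FALSE), c(n_pos, n - n_pos))
  for (i in seq_len(n)) {
    ci <- if (flags[i]) cases_with_pos[sample.int(length(cases_with_pos), 1)]
          else sample.int(length(pools), 1)
    pool <- if (flags[i]) pools[[ci]]$pos else pools[[ci]]$neg
    draws[[i]] <- list(case = ci, lin = pool[sample.int(length(pool), 1)],
                       positive = flags[i])
  }
  draws
}

#' Train one multi-resolution patch network
#'
#' Fits the network to replicate the reference segmentations of the
#' training cases, minimising voxelwise cross-entropy with Adam on
#' class-balanced patches (default 50% centred on lymphoma voxels, 50%
#' on body voxels outside the reference). When validation cases are
#' supplied, the returned model carries the weights from the epoch with
#' the lowest validation loss.
#'
#' @param cases list of preprocessed cases ([preprocess_case()]) with
#'   non-empty `reference` masks.
#' @param config a [deepmedic_config()]; `config$seed` controls weight
#'   initialisation and patch sampling, so training is reproducible.
#' @param validation optional list of cases for per-epoch validation loss.
#' @param verbose print per-epoch losses.
#' @return An object of class `deepmedic` with elements `params`,
#'   `config`, `history` (per-epoch training/validation loss) and
#'   `best_epoch`.
#' @export
deepmedic_fit <- function(cases, config = deepmedic_config(),
                          validation = NULL, verbose = FALSE) {
  if (length(cases) == 0) stop("empty training set")
  pools <- lapply(cases, case_center_pools)
  cases_with_pos <- which(vapply(pools, function(p) length(p$pos) > 0, TRUE))
  if (config$train$positive_fraction > 0 && length(cases_with_pos) == 0)
    stop("no training case has positive reference voxels")
  set.seed(config$seed)
  params <- init_params(config)
  state <- list(m = zero_like(params), v = zero_like(params))
  preps <- lapply(cases, function(cs)
    prepare_network_inputs(cs$pet_in, cs$ct_in, config))
  refs <- lapply(cases, function(cs) cs$reference$data != 0)
  tsz <- rep(output_tile_size(config), 3)
  half <- (tsz - 1L) %/% 2L

  val_patches <- NULL
  if (!is.null(validation) && length(validation)) {
    val_patches <- unlist(lapply(seq_along(validation), function(i)
      sample_patches(validation[[i]], n = 20,
                     positive_fraction = config$train$positive_fraction,
                     seed = config$seed + 7919L * i, config = config)),
      recursive = FALSE)
    set.seed(config$seed + 1L)  # reset stream after validation sampling
  }

  tr <- config$train
  n_per_epoch <- tr$batch_size * tr$steps_per_epoch
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = params, epoch = 0L)
  t_adam <- 0L
  for (epoch in seq_len(tr$epochs)) {
    draws <- draw_epoch_centers(pools, cases_with_pos, n_per_epoch,
                                tr$positive_fraction)
    draws <- draws[sample.int(length(draws))]  # shuffle pos/neg within epoch
    ep_loss <- 0
    for (step in seq_len(tr$steps_per_epoch)) {
      idx <- ((step - 1) * tr$batch_size + 1):(step * tr$batch_size)
      acc <- NULL
      step_loss <- 0
      for (dr in draws[idx]) {
        d <- pools[[dr$case]]$dim
        ctr <- center_to_ijk(dr$lin, d)[1, ]
        o <- ctr - half
        tile <- extract_tile_inputs(preps[[dr$case]], o, tsz, config)
        fw <- forward_tile(params, config, tile, keep = TRUE)
        ix <- clamp_idx(o[1]:(o[1] + tsz[1] - 1L), d[1])
        iy <- clamp_idx(o[2]:(o[2] + tsz[2] - 1L), d[2])
        iz <- clamp_idx(o[3]:(o[3] + tsz[3] - 1L), d[3])
        lbl <- as.integer(refs[[dr$case]][ix, iy, iz])
        bw <- backward_tile(params, config, tile, fw, lbl)
        step_loss <- step_loss + bw$loss
        acc <- if (is.null(acc)) bw$grads
               else mapply(`+`, acc, bw$grads, SIMPLIFY = FALSE)
      }
      acc <- lapply(acc, function(g) g / tr$batch_size)
      step_loss <- step_loss / tr$batch_size
      if (!is.finite(step_loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             ", step ", step, "; lower the learning rate")
      t_adam <- t_adam + 1L
      up <- adam_step(params, acc, state, tr$learning_rate, t_adam)
      params <- up$params
      state <- up$state
      ep_loss <- ep_loss + step_loss
    }
    ep_loss <- ep_loss / tr$steps_per_epoch
    vl <- NA_real_
    if (!is.null(val_patches)) {
      vl <- mean(vapply(val_patches, function(pt) {
        fw <- forward_tile(params, config, pt, keep = FALSE)
        -mean(log(fw$prob[cbind(seq_len(prod(pt$tsz)),
                                as.integer(pt$label) + 1L)] + 1e-12))
      }, numeric(1)))
      if (vl < best$loss) best <- list(loss = vl, params = params, epoch = epoch)
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = ep_loss, val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f%s", epoch, ep_loss,
                      if (is.na(vl)) "" else sprintf(" val %.4f", vl)))
  }
  if (!is.null(val_patches) && best$epoch > 0) params <- best$params
  structure(list(params = params, config = config, history = history,
                 best_epoch = if (is.null(val_patches)) nrow(history)
                              else best$epoch),
            class = "deepmedic")
}

#' @export
print.deepmedic <- function(x, ...) {
  cat("<deepmedic> multi-resolution 3D patch network\n")
  print(x$config)
  n <- nrow(x$history)
  if (n) cat(sprintf("  trained %d epochs; final loss %.4f%s\n", n,
                     x$history$loss[n],
                     if (all(is.na(x$history$val_loss))) ""
                     else sprintf(" (best val epoch %d)", x$best_epoch)))
  invisible(x)
}

#' @export
summary.deepmedic <- function(object, ...) {
  npar <- sum(vapply(object$params, length, numeric(1)))
  cat(sprintf("Multi-resolution patch network: %d pathways, %s parameters\n",
              object$config$n_pathways, format(npar, big.mark = ",")))
  print(object$history)
  invisible(object$history)
}

#' @export
plot.deepmedic <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                 ylab = "cross-entropy loss", ...)
  if (!all(is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, type = "b", lty = 2)
  invisible(x)
}

## ---- checkpoints -----------------------------------------------------------

#' Save a trained network to disk
#'
#' Writes a JSON header (`<path>.json`: configuration, training history,
#' parameter names and shapes) plus a little-endian float64 weights blob
#' (`<path>.bin`).
#'
#' @param model a fitted `deepmedic` model.
#' @param path file stem; two files `<path>.json` and `<path>.bin` are
#'   written.
#' @export
save_deepmedic <- function(model, path) {
  stopifnot(inherits(model, "deepmedic"))
  shapes <- lapply(model$params, function(p)
    if (is.matrix(p)) dim(p) else length(p))
  header <- list(config = unclass(model$config),
                 history = model$history,
                 best_epoch = model$best_epoch,
                 param_names = names(model$params),
                 param_shapes = shapes)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (p in model$params)
    writeBin(as.numeric(p), con, size = 8, endian = "little")
  invisible(path)
}

#' Load a network checkpoint written by [save_deepmedic()]
#'
#' @param path file stem used when saving.
#' @return A `deepmedic` model.
#' @export
load_deepmedic <- function(path) {
  h <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- h$config
  config <- deepmedic_config(
    n_pathways = cfg$n_pathways, downsample_factors = cfg$downsample_factors,
    conv_features = cfg$conv_features, fc_features = cfg$fc_features,
    in_channels = cfg$in_channels, patch_size = cfg$patch_size,
    seed = cfg$seed, learning_rate = cfg$train$learning_rate,
    epochs = cfg$train$epochs, batch_size = cfg$train$batch_size,
    steps_per_epoch = cfg$train$steps_per_epoch,
    positive_fraction = cfg$train$positive_fraction)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  params <- list()
  for (i in seq_along(h$param_names)) {
    shp <- unlist(h$param_shapes[[i]])
    n <- prod(shp)
    v <- readBin(con, "numeric", n = n, size = 8, endian = "little")
    params[[h$param_names[i]]] <- if (length(shp) == 2)
      matrix(v, shp[1], shp[2]) else v
  }
  structure(list(params = params, config = config,
                 history = as.data.frame(h$history),
                 best_epoch = h$best_epoch),
            class = "deepmedic")
}

## ---- inference ------------------------------------------------------------

#' Dense whole-volume probability inference
#'
#' Assembles the per-voxel lymphoma probability over the full grid from
#' non-overlapping output tiles; the input context needed by the valid
#' convolutions is edge-padded at volume borders. Voxels outside the body
#' mask (when given) are set to probability 0.
#'
#' @param object a fitted `deepmedic` model.
#' @param pet,ct normalized input volumes on a common grid (2 mm
#'   isotropic, z-scored inside the body).
#' @param body optional binary `LABEL` [volume()]; probabilities outside
#'   it are zeroed.
#' @param tile output-tile edge length used for inference (any positive
#'   integer; the result is independent of the tiling).
#' @param ... unused.
#' @return A `PROBABILITY` [volume()] on the input grid.
#' @export
predict.deepmedic <- function(object, pet, ct, body = NULL, tile = 32L, ...) {
  stopifnot(is_volume(pet), is_volume(ct))
  stopifnot_same_grid(pet, ct, "PET and CT")
  config <- object$config
  prep <- prepare_network_inputs(pet, ct, config)
  d <- dim(pet$data)
  out <- array(0, d)
  starts <- lapply(d, function(n) seq.int(0L, n - 1L, by = tile))
  for (oz in starts[[3]]) for (oy in starts[[2]]) for (ox in starts[[1]]) {
    o <- c(ox, oy, oz)
    tsz <- pmin(tile, d - o)
    tl <- extract_tile_inputs(prep, o, tsz, config)
    fw <- forward_tile(object$params, config, tl, keep = FALSE)
    out[o[1] + 1:tsz[1], o[2] + 1:tsz[2], o[3] + 1:tsz[3]] <-
      array(fw$prob[, 2], tsz)
  }
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(body)) {
    stopifnot_same_grid(pet, body, "PET and body mask")
    out[body$data == 0] <- 0
  }
  volume(array(out, d), spacing = pet$spacing, origin = pet$origin,
         modality = "PROBABILITY")
}

#' Binarize a probability volume
#'
#' @param prob a `PROBABILITY` [volume()].
#' @param cut_point probability cut point in \[0, 1\] (default 0.5).
#' @return Logical 3D array, `prob >= cut_point`.
#' @export
binarize <- function(prob, cut_point = 0.5) {
  stopifnot(is_volume(prob))
  if (!is.finite(cut_point) || cut_point < 0 || cut_point > 1)
    stop("cut_point must be in [0, 1]")
  array(prob$data >= cut_point, dim(prob$data))
}
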