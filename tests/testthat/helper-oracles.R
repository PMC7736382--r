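# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package
# internals: plain loops over voxel lists, exhaustive enumeration for
# rank statistics, and sum-formula correlation.

vol3 <- function(arr, spacing = c(2, 2, 2), modality = "PET_SUV") {
  volume(arr, spacing = spacing, origin = c(0, 0, 0), modality = modality)
}

rand_mask <- function(d, p = 0.05) {
  array(runif(prod(d)) < p, d)
}

# flood-fill labeling over the positive voxel list (26- or 6-neighbour)
oracle_components <- function(mask, connectivity = 26) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  key <- function(v) paste(v, collapse = ",")
  lookup <- new.env(hash = TRUE)
  for (i in seq_len(nrow(idx))) assign(key(idx[i, ]), i, envir = lookup)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  seen <- logical(nrow(idx))
  comps <- list()
  for (i in seq_len(nrow(idx))) {
    if (seen[i]) next
    queue <- i
    seen[i] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      members <- c(members, cur)
      for (r in seq_len(nrow(offs))) {
        nb <- idx[cur, ] + c(offs$dx[r], offs$dy[r], offs$dz[r])
        j <- mget(key(nb), envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && !seen[j]) {
          seen[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
    comps[[length(comps) + 1]] <- idx[members, , drop = FALSE]
  }
  comps
}

oracle_mtv <- function(mask, spacing) {
  nrow(which(mask != 0, arr.ind = TRUE)) * prod(spacing) / 1000
}

oracle_tlg <- function(pet_arr, mask, spacing) {
  idx <- which(mask != 0, arr.ind = TRUE)
  s <- 0
  for (i in seq_len(nrow(idx)))
    s <- s + pet_arr[idx[i, 1], idx[i, 2], idx[i, 3]]
  s * prod(spacing) / 1000
}

# exposed 6-neighbour faces, counted voxel by voxel
oracle_faces <- function(mask) {
  d <- dim(mask)
  idx <- which(mask != 0, arr.ind = TRUE)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  faces <- 0L
  for (i in seq_len(nrow(idx))) {
    for (r in 1:6) {
      nb <- idx[i, ] + offs[r, ]
      outside <- any(nb < 1) || any(nb > d)
      if (outside || mask[nb[1], nb[2], nb[3]] == 0) faces <- faces + 1L
    }
  }
  faces
}

oracle_surface_area <- function(mask, spacing) {
  stopifnot(length(unique(spacing)) == 1)  # oracle assumes cubic voxels
  oracle_faces(mask) * spacing[1]^2 / 100
}

oracle_dmax <- function(mask, spacing) {
  comps <- oracle_components(mask, 26)
  if (length(comps) < 2) return(0)
  cents <- t(vapply(comps, function(m) colMeans((m - 1) %*% diag(spacing)),
                    numeric(3)))
  best <- 0
  for (i in seq_len(nrow(cents) - 1))
    for (j in (i + 1):nrow(cents))
      best <- max(best, sqrt(sum((cents[i, ] - cents[j, ])^2)))
  best / 10
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# exact two-sided rank-sum p by enumerating every group assignment,
# mirroring the doubling rule used for the exact Mann-Whitney U
oracle_wilcox_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  p1 <- if (u_obs > nx * ny / 2) mean(us >= u_obs) else mean(us <= u_obs)
  min(2 * p1, 1)
}

small_net_config <- function(...) {
  args <- list(n_pathways = 2, downsample_factors = c(1, 3),
               conv_features = rep(4, 8), fc_features = 8,
               epochs = 2, steps_per_epoch = 3, batch_size = 4, seed = 7)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(deepmedic_config, args)
}

# geometry scaled to small unit-test grids (the package defaults target
# whole 64^3 volumes, where several 15 mm lesions fit)
small_phantom_config <- function(grid = 32, ...) {
  args <- list(grid_size = grid, n_lesions = c(1, 3),
               lesion_radius = c(4, 9), n_benign_hot = c(0, 1),
               benign_radius = c(2.5, 4.5), bone_structures = 1,
               bone_radius = c(3, 6), roi_margin = 2)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(phantom_config, args)
}

small_phantom_cases <- function(n, seed, grid = 32, ...) {
  cohort <- generate_cohort(n, small_phantom_config(grid, ...), seed = seed)
  lapply(cohort, function(ph)
    preprocess_case(ph$pet, ph$ct, reference = ph$reference,
                    case_id = ph$case_id))
}
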