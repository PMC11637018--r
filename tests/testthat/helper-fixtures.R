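# Shared fixtures: tiny specs, random masks, small trained datasets.

tiny_network_spec <- function(...) {
  args <- utils::modifyList(
    list(levels = 2L, base_channels = 2L, cam_reduction = 2L, sam_kernel = 3L,
         dropout_rate = 0, dropout_bottleneck = 0),
    list(...))
  do.call(network_spec, args)
}

tiny_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(volume_shape = c(16L, 16L, 8L), spacing = c(1, 1, 2), n_cases = 6L,
         labeled_fraction = 0.5, test_fraction = 0.2, seed = 7L),
    list(...))
  do.call(phantom_spec, args)
}

random_mask <- function(dims, p = 0.3) {
  array(stats::rbinom(prod(dims), 1L, p), dims)
}

random_prob_map <- function(dims, C = 2L) {
  e <- array(stats::rexp(prod(dims) * C), c(dims, C))
  s <- array(rep(apply(e, 1:3, sum), C), c(dims, C))
  e / s
}

# Independent brute-force surface extraction: a foreground voxel survives
# erosion iff all six face neighbours are foreground (outside = background).
brute_surface <- function(mask) {
  m <- mask > 0
  d <- dim(m)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k]) next
    nb <- c(
      if (i > 1) m[i - 1, j, k] else FALSE,
      if (i < d[1]) m[i + 1, j, k] else FALSE,
      if (j > 1) m[i, j - 1, k] else FALSE,
      if (j < d[2]) m[i, j + 1, k] else FALSE,
      if (k > 1) m[i, j, k - 1] else FALSE,
      if (k < d[3]) m[i, j, k + 1] else FALSE)
    out[i, j, k] <- !all(nb)
  }
  out
}

# Exhaustive pairwise directed nearest-surface distances (oracle).
brute_surface_dists <- function(a, b, spacing) {
  pa <- sweep(which(brute_surface(a), arr.ind = TRUE), 2, spacing, `*`)
  pb <- sweep(which(brute_surface(b), arr.ind = TRUE), 2, spacing, `*`)
  dmat <- sqrt(outer(pa[, 1], pb[, 1], `-`)^2 +
                 outer(pa[, 2], pb[, 2], `-`)^2 +
                 outer(pa[, 3], pb[, 3], `-`)^2)
  list(ab = apply(dmat, 1, min), ba = apply(dmat, 2, min))
}

# A mask guaranteed non-empty
nonempty_mask <- function(dims, p = 0.3) {
  m <- random_mask(dims, p)
  if (sum(m) == 0) m[ceiling(dims[1] / 2), ceiling(dims[2] / 2),
                     ceiling(dims[3] / 2)] <- 1L
  m
}

# Max absolute elementwise difference between two parameter sets, ignoring
# the structural kernel-size markers.
param_max_diff <- function(a, b) {
  v <- unlist(uamt3d:::param_map2(a, b, function(x, y) max(abs(x - y))))
  max(v[!grepl("(^|\\.)k$", names(v))])
}
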