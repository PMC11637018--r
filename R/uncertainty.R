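# Monte-Carlo-dropout uncertainty estimation.
#
# The teacher network is run N times on independently perturbed inputs with
# dropout active; the per-voxel softmax maps are stacked, averaged into the
# mean class-probability map M, and condensed into a voxelwise Shannon
# entropy U (nats, 0 <= U <= ln c). Voxels with U below a threshold count
# as reliable and gate the consistency loss.

#' Construct / validate a stack of stochastic probability maps
#'
#' @param probs 5D array `[x, y, z, classes, passes]`; every voxel's class
#'   vector in every pass must be a probability vector (tolerance 1e-6).
#' @return Object of class `probability_stack` with fields `probs`,
#'   `n_passes`, `num_classes`.
#' @export
probability_stack <- function(probs) {
  d <- dim(probs)
  if (length(d) != 5L) stop("probs must be [x, y, z, classes, passes]",
                            call. = FALSE)
  if (d[5] < 1L) stop("at least one forward pass is required", call. = FALSE)
  if (any(probs < -1e-9))
    stop("probabilities must be nonnegative", call. = FALSE)
  nvox <- prod(d[1:3])
  pm <- matrix(probs, nvox, d[4] * d[5])   # columns: class within pass
  s <- matrix(0, nvox, d[5])
  for (cl in seq_len(d[4])) s <- s + pm[, cl + d[4] * (seq_len(d[5]) - 1L),
                                        drop = FALSE]
  if (max(abs(s - 1)) > 1e-6)
    stop("class probabilities must sum to 1 per voxel (tolerance 1e-6)",
         call. = FALSE)
  structure(list(probs = probs, n_passes = d[5], num_classes = d[4]),
            class = "probability_stack")
}

#' Monte-Carlo forward passes through the (teacher) network
#'
#' Each pass adds an independent noise draw to the input and runs the
#' network with dropout active, yielding an independent stochastic softmax
#' map. The default of 8 passes trades uncertainty-map fidelity against
#' inference cost.
#'
#' @param net A `unet3d` network.
#' @param volume Input 3D array (normalized intensities).
#' @param n_passes Number of stochastic passes (>= 1). Default 8.
#' @param noise Input perturbation as a [noise_spec()]; `NULL` disables it.
#' @param params Optional parameter set overriding `net$params` (the teacher
#'   parameters during training).
#' @param dropout Run with dropout active (the Monte-Carlo ingredient);
#'   disable together with `noise = NULL` for a degenerate deterministic
#'   stack.
#' @return A [probability_stack()].
#' @export
mc_forward <- function(net, volume, n_passes = 8L, noise = noise_spec(),
                       params = NULL, dropout = TRUE) {
  if (n_passes < 1) stop("n_passes must be >= 1", call. = FALSE)
  C <- net$spec$num_classes
  d <- dim(volume)[1:3]
  probs <- array(NA_real_, c(d, C, n_passes))
  for (t in seq_len(n_passes)) {
    xt <- if (is.null(noise)) volume else volume + draw_noise(noise, dim(volume))
    logits <- net_forward(net, xt, params = params, dropout = dropout)
    probs[, , , , t] <- softmax_channels(logits)
  }
  probability_stack(probs)
}

#' Mean probability map over Monte-Carlo passes
#' @param stack A [probability_stack()].
#' @return Array `[x, y, z, classes]`: voxelwise arithmetic mean per class.
#' @export
mean_probability <- function(stack) {
  stopifnot(inherits(stack, "probability_stack"))
  d <- dim(stack$probs)
  m <- rowMeans(matrix(stack$probs, prod(d[1:4]), d[5]))
  dim(m) <- d[1:4]
  m
}

#' Voxelwise Shannon entropy of a mean probability map
#'
#' Entropy in nats with the convention 0 * log(0) = 0, so
#' 0 <= U <= log(num_classes) everywhere.
#'
#' @param mean_prob Array `[x, y, z, classes]`, normalized per voxel.
#' @param tol Normalization tolerance.
#' @return 3D entropy array.
#' @export
entropy_uncertainty <- function(mean_prob, tol = 1e-6) {
  d <- dim(mean_prob)
  stopifnot(length(d) == 4L)
  pm <- matrix(mean_prob, prod(d[1:3]), d[4])
  if (max(abs(rowSums(pm) - 1)) > tol)
    stop("mean_prob is not normalized per voxel", call. = FALSE)
  # 0 * log(0) = 0: the clamp keeps log finite and the product zeroes it out
  u <- -rowSums(pm * log(pmax(pm, .Machine$double.xmin)))
  array(pmax(u, 0), d[1:3])
}

#' Reliability mask from an entropy map
#'
#' Indicator of reliable voxels: 1 where `entropy < threshold` (strictly),
#' 0 otherwise; ties at the threshold count as uncertain.
#'
#' @param entropy 3D entropy array.
#' @param threshold Nonnegative uncertainty threshold.
#' @return Binary (0/1) array of the same shape.
#' @export
reliability_mask <- function(entropy, threshold) {
  if (threshold < 0) stop("threshold must be nonnegative", call. = FALSE)
  array(as.numeric(entropy < threshold), dim(entropy))
}

#' Uncertainty-threshold schedule
#'
#' Ramps the gating threshold from (3/4) log(c) to log(c) over training with
#' the same Gaussian ramp as the consistency weight, admitting only
#' confidently-predicted voxels early and nearly all voxels late.
#'
#' @param step Global training step (>= 0).
#' @param rampup_length Ramp duration in steps.
#' @param num_classes Number of classes c.
#' @return Threshold in nats.
#' @export
uncertainty_threshold <- function(step, rampup_length, num_classes = 2L) {
  log(num_classes) * (0.75 + 0.25 * sigmoid_rampup(step, rampup_length))
}
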