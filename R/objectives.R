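# Loss terms and schedules.
#
# Supervised loss: unweighted mean of soft-Dice loss (smoothed, on softmax
# foreground probabilities) and voxelwise cross-entropy. Consistency loss:
# mean squared difference between student and teacher class probabilities
# over reliable voxels only (entropy below threshold), averaged over
# classes so probability inputs keep it in [0, 1]. Joint objective:
# L = L_sup + lambda(step) * L_con with a Gaussian ramp-up on lambda.

#' Consistency-training configuration
#'
#' @param lambda_max Peak consistency weight, reached after the ramp.
#' @param rampup_length Ramp duration in steps.
#' @param smooth Dice smoothing constant.
#' @return Object of class `loss_config`.
#' @export
loss_config <- function(lambda_max = 0.1, rampup_length = 1000L,
                        smooth = 1e-5) {
  stopifnot(lambda_max >= 0, rampup_length >= 1, smooth > 0)
  structure(list(lambda_max = lambda_max,
                 rampup_length = as.integer(rampup_length), smooth = smooth),
            class = "loss_config")
}

#' Gaussian ramp-up weight
#'
#' `exp(-5 (1 - t/T)^2)` for `t < T`, 1 afterwards; the standard
#' consistency-weight schedule of mean-teacher training.
#'
#' @param step Current step t (>= 0).
#' @param rampup_length Ramp length T in steps.
#' @return Scalar in (0, 1].
#' @export
sigmoid_rampup <- function(step, rampup_length) {
  if (rampup_length <= 0) return(1)
  phase <- 1 - min(step, rampup_length) / rampup_length
  exp(-5 * phase^2)
}

#' Consistency weight at a training step
#' @param step Global step.
#' @param cfg A [loss_config()].
#' @return `lambda_max * exp(-5 (1 - min(step, T)/T)^2)`.
#' @export
lambda_schedule <- function(step, cfg) {
  cfg$lambda_max * sigmoid_rampup(step, cfg$rampup_length)
}

one_hot <- function(labels, C) {
  n <- length(labels)
  oh <- matrix(0, n, C)
  oh[cbind(seq_len(n), as.integer(labels) + 1L)] <- 1
  oh
}

#' Supervised segmentation loss (Dice + cross-entropy)
#'
#' Unweighted mean of (1 - smoothed soft Dice of the softmax foreground
#' probabilities against the label mask, averaged over foreground classes)
#' and the voxelwise cross-entropy.
#'
#' @param logits Raw network scores `[x, y, z, classes]`.
#' @param labels Integer array in `{0, ..., classes-1}` with matching
#'   spatial shape.
#' @param smooth Dice smoothing constant.
#' @param with_grad Also return the gradient w.r.t. `logits`.
#' @return List: `loss`, `dice_loss`, `ce`, and `dlogits` if requested.
#' @export
supervised_loss <- function(logits, labels, smooth = 1e-5, with_grad = FALSE) {
  d <- dim(logits)
  C <- d[4]
  if (!all(dim(labels) == d[1:3]))
    stop("label shape does not match logits", call. = FALSE)
  lab <- as.integer(labels)
  if (any(lab < 0L | lab >= C))
    stop("labels must lie in {0, ..., ", C - 1L, "}", call. = FALSE)
  nvox <- prod(d[1:3])
  probs <- softmax_channels(logits)
  pm <- matrix(probs, nvox, C)
  oh <- one_hot(lab, C)
  ce <- -mean(log(pmax(pm[cbind(seq_len(nvox), lab + 1L)],
                       .Machine$double.xmin)))
  # soft Dice over foreground classes
  fg <- 2:C
  num <- 2 * colSums(pm[, fg, drop = FALSE] * oh[, fg, drop = FALSE]) + smooth
  den <- colSums(pm[, fg, drop = FALSE]) + colSums(oh[, fg, drop = FALSE]) +
    smooth
  dice <- num / den
  dice_loss <- 1 - mean(dice)
  out <- list(loss = 0.5 * (dice_loss + ce), dice_loss = dice_loss, ce = ce)
  if (with_grad) {
    dce <- (pm - oh) / nvox
    ddice_dp <- matrix(0, nvox, C)
    for (j in seq_along(fg)) {
      k <- fg[j]
      # d(num/den)/dp = (2 y den - num) / den^2 ; loss takes -mean over classes
      ddice_dp[, k] <- -(2 * oh[, k] * den[j] - num[j]) / den[j]^2 /
        length(fg)
    }
    dl <- 0.5 * (array(dce, d) + softmax_bwd(probs, array(ddice_dp, d)))
    out$dlogits <- dl
  }
  out
}

#' Uncertainty-gated consistency loss
#'
#' Mean squared difference between student and teacher class probabilities,
#' averaged over classes, over voxels whose teacher-side entropy lies
#' strictly below the threshold; 0 when no voxel qualifies.
#'
#' @param student_probs Array `[x, y, z, classes]` (student softmax).
#' @param teacher_probs Same shape (teacher mean probability).
#' @param entropy 3D entropy array from the teacher.
#' @param threshold Uncertainty threshold.
#' @param with_grad Also return the gradient w.r.t. `student_probs`.
#' @return List: `loss`, `n_reliable`, and `dprobs` if requested.
#' @export
consistency_loss <- function(student_probs, teacher_probs, entropy, threshold,
                             with_grad = FALSE) {
  d <- dim(student_probs)
  if (!identical(d, dim(teacher_probs)) || !all(dim(entropy) == d[1:3]))
    stop("student, teacher and entropy shapes do not agree", call. = FALSE)
  C <- d[4]
  H <- as.numeric(entropy < threshold)
  n <- sum(H)
  if (n == 0) {
    out <- list(loss = 0, n_reliable = 0)
    if (with_grad) out$dprobs <- array(0, d)
    return(out)
  }
  diff <- student_probs - teacher_probs
  err <- rowMeans(matrix(diff^2, prod(d[1:3]), C))
  out <- list(loss = sum(H * err) / n, n_reliable = n)
  if (with_grad) out$dprobs <- array(2 * as.numeric(H) * diff / (C * n), d)
  out
}

#' Joint semi-supervised objective
#' @param sup Supervised loss value.
#' @param con Consistency loss value.
#' @param step Global training step.
#' @param cfg A [loss_config()].
#' @return `sup + lambda(step) * con`.
#' @export
joint_loss <- function(sup, con, step, cfg) {
  sup + lambda_schedule(step, cfg) * con
}
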