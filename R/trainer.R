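# Mean-teacher training loop.
#
# Student and teacher share one architecture. The student is trained by SGD
# on Dice+cross-entropy over labeled cases plus an uncertainty-gated
# consistency penalty against the teacher on unlabeled cases; the teacher
# receives no gradients and is updated only as an exponential moving
# average (EMA) of the student after every step.

#' Input perturbation specification
#' @param distribution Only `"gaussian"` is implemented.
#' @param sigma Noise standard deviation (normalized-intensity units).
#' @param clip Symmetric clipping bound on the draws.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(distribution = "gaussian", sigma = 0.1, clip = 0.2) {
  distribution <- match.arg(distribution, "gaussian")
  stopifnot(sigma >= 0, clip >= 0)
  structure(list(distribution = distribution, sigma = sigma, clip = clip),
            class = "noise_spec")
}

draw_noise <- function(ns, dims) {
  if (is.null(ns) || ns$sigma == 0) return(array(0, dims))
  n <- stats::rnorm(prod(dims), sd = ns$sigma)
  if (ns$clip > 0) n <- pmin(pmax(n, -ns$clip), ns$clip)
  array(n, dims)
}

#' Initialize mean-teacher trainer state
#'
#' The teacher starts as an exact copy of the student and is thereafter
#' updated only by [ema_update()].
#'
#' @param student_params Nested parameter list (from [build_network()]).
#' @param ema_decay EMA decay epsilon in `[0, 1]`; 0.99 keeps 99% of the
#'   teacher and transfers 1% from the student per step.
#' @return Object of class `trainer_state`.
#' @export
trainer_state <- function(student_params, ema_decay = 0.99) {
  stopifnot(ema_decay >= 0, ema_decay <= 1)
  structure(list(student_params = student_params,
                 teacher_params = student_params, ema_decay = ema_decay,
                 step = 0L), class = "trainer_state")
}

#' Exponential-moving-average teacher update
#'
#' Every teacher parameter becomes
#' `ema_decay * teacher + (1 - ema_decay) * student`. Errors if the two
#' parameter sets are incongruent.
#'
#' @param state A [trainer_state()].
#' @return Updated state.
#' @export
ema_update <- function(state) {
  e <- state$ema_decay
  state$teacher_params <- param_map2(state$teacher_params,
                                     state$student_params,
                                     function(t, s) e * t + (1 - e) * s)
  state
}

#' Load a phantom dataset into memory
#'
#' Reads every case referenced by a manifest and applies z-score intensity
#' normalization to the volumes (masks untouched).
#'
#' @param manifest Manifest tibble (see [generate_dataset()]).
#' @param normalize Intensity normalization mode, or `NULL` for none.
#' @return List of cases with `clean`, `degraded`, `mask`, `labeled`,
#'   `split`, `case_id`, `spacing`.
#' @export
load_dataset <- function(manifest, normalize = "zscore") {
  purrr::pmap(manifest, function(case_id, clean_path, degraded_path,
                                 mask_path, labeled, split, ...) {
    cl <- load_volume(clean_path)
    dg <- load_volume(degraded_path)
    mk <- load_volume(mask_path)
    if (!is.null(normalize)) {
      cl$data <- normalize_intensity(cl$data, normalize)
      dg$data <- normalize_intensity(dg$data, normalize)
    }
    list(case_id = case_id, clean = cl$data, degraded = dg$data,
         mask = round(mk$data), labeled = labeled, split = split,
         spacing = cl$spacing)
  })
}

#' Draw one training batch (1 labeled + 1 unlabeled item)
#'
#' The labeled item is a uniformly drawn labeled training case, presented
#' as its clean (CT-like) volume with probability `clean_prob` and as its
#' degraded (CBCT-like) volume otherwise — the 5:3 clean:degraded labeled
#' mix holds in expectation. The unlabeled item is a uniformly drawn
#' unlabeled training case, always degraded. When the unlabeled pool is
#' empty (fully-supervised mode) the unlabeled slot is `NULL`.
#'
#' @param dataset List of cases from [load_dataset()].
#' @param clean_prob Probability that the labeled item is the clean volume.
#' @return List with `labeled` (`volume`, `mask`, `modality`, `case_id`) and
#'   `unlabeled` (`volume`, `case_id`, or `NULL`).
#' @export
make_batch <- function(dataset, clean_prob = 5 / 8) {
  train <- purrr::keep(dataset, ~ .x$split == "train")
  lab <- purrr::keep(train, ~ isTRUE(.x$labeled))
  unl <- purrr::keep(train, ~ !isTRUE(.x$labeled))
  if (length(lab) == 0) stop("no labeled training cases", call. = FALSE)
  lc <- lab[[sample.int(length(lab), 1L)]]
  modality <- if (stats::runif(1) < clean_prob) "clean" else "degraded"
  labeled <- list(volume = lc[[modality]], mask = lc$mask,
                  modality = modality, case_id = lc$case_id)
  unlabeled <- NULL
  if (length(unl) > 0) {
    uc <- unl[[sample.int(length(unl), 1L)]]
    unlabeled <- list(volume = uc$degraded, case_id = uc$case_id)
  }
  list(labeled = labeled, unlabeled = unlabeled)
}

sgd_init <- function(params) param_map(params, function(p) p * 0)

sgd_update <- function(params, grads, velocity, lr, momentum, weight_decay) {
  gw <- param_map2(grads, params, function(g, p) g + weight_decay * p)
  velocity <- param_map2(velocity, gw, function(v, g) momentum * v + g)
  params <- param_map2(params, velocity, function(p, v) p - lr * v)
  list(params = params, velocity = velocity)
}

add_grads <- function(a, b) param_map2(a, b, `+`)

#' Train a mean-teacher segmentation model
#'
#' One epoch is a pass over the unlabeled training pool (over the labeled
#' pool in fully-supervised mode). Each step composes a 1 labeled +
#' 1 unlabeled batch, center-crops to the training window, adds independent
#' input noise to every network input, computes Dice+CE on the labeled item
#' and — when unlabeled data and a positive consistency weight exist — the
#' uncertainty-gated consistency loss between the student softmax and the
#' teacher Monte-Carlo mean on the unlabeled item, backpropagates the joint
#' objective through the student only, applies SGD with momentum, and
#' finally EMA-updates the teacher. Aborts with the step number if a loss
#' goes non-finite.
#'
#' @param config Nested configuration list; see [default_config()]. Must
#'   contain `data$manifest` (path or tibble).
#' @return Object of class `uamt_fit`: the network skeleton, student and
#'   teacher parameters, per-step `log` tibble and the resolved config.
#' @export
train <- function(config) {
  cfg <- merge_config(default_config(), config)
  tc <- cfg$trainer
  set.seed(tc$seed)
  manifest <- cfg$data$manifest
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dataset <- load_dataset(manifest, normalize = cfg$data$normalize)
  train_cases <- purrr::keep(dataset, ~ .x$split == "train")
  n_unl <- sum(purrr::map_lgl(train_cases, ~ !isTRUE(.x$labeled)))
  n_lab <- sum(purrr::map_lgl(train_cases, ~ isTRUE(.x$labeled)))
  if (n_lab == 0) stop("no labeled training cases", call. = FALSE)

  mspec <- do.call(network_spec, cfg$model)
  lcfg <- do.call(loss_config, cfg$loss)
  ns <- do.call(noise_spec, cfg$trainer$noise)
  window <- as.integer(cfg$data$window)
  use_unlabeled <- n_unl > 0 && lcfg$lambda_max > 0

  net <- build_network(mspec)
  state <- trainer_state(net$params, ema_decay = tc$ema_decay)
  velocity <- sgd_init(net$params)
  # an epoch is one pass over the unlabeled pool whenever one exists (this
  # also step-count-matches a lambda = 0 baseline against consistency runs);
  # purely supervised datasets fall back to the labeled pool
  steps_per_epoch <- if (n_unl > 0) n_unl else n_lab
  total_steps <- tc$epochs * steps_per_epoch
  log_rows <- vector("list", total_steps)

  crop_vol <- function(v) center_crop(v, window)$data
  step <- 0L
  for (epoch in seq_len(tc$epochs)) {
    for (it in seq_len(steps_per_epoch)) {
      batch <- make_batch(dataset, clean_prob = tc$clean_prob)
      xl <- crop_vol(batch$labeled$volume) + draw_noise(ns, window)
      yl <- crop_vol(batch$labeled$mask)
      fl <- net_forward(net, xl, params = state$student_params,
                        dropout = TRUE, with_cache = TRUE)
      sup <- supervised_loss(fl$logits, yl, smooth = lcfg$smooth,
                             with_grad = TRUE)
      grads <- net_backward(net, fl$cache, sup$dlogits,
                            params = state$student_params)
      con_val <- 0; lam <- 0; thr <- NA_real_
      if (use_unlabeled && !is.null(batch$unlabeled)) {
        xu <- crop_vol(batch$unlabeled$volume)
        fu <- net_forward(net, xu + draw_noise(ns, window),
                          params = state$student_params, dropout = TRUE,
                          with_cache = TRUE)
        f_student <- softmax_channels(fu$logits)
        stack <- mc_forward(net, xu, n_passes = tc$mc_passes, noise = ns,
                            params = state$teacher_params, dropout = TRUE)
        f_teacher <- mean_probability(stack)
        u <- entropy_uncertainty(f_teacher)
        thr <- uncertainty_threshold(step, lcfg$rampup_length,
                                     mspec$num_classes)
        con <- consistency_loss(f_student, f_teacher, u, thr,
                                with_grad = TRUE)
        con_val <- con$loss
        lam <- lambda_schedule(step, lcfg)
        if (lam > 0 && con$n_reliable > 0) {
          dlog_con <- softmax_bwd(f_student, lam * con$dprobs)
          grads <- add_grads(grads, net_backward(net, fu$cache, dlog_con,
                                                 params = state$student_params))
        }
      }
      total <- joint_loss(sup$loss, con_val, step, lcfg)
      if (!is.finite(total))
        stop("non-finite loss at step ", step, " (sup=", sup$loss, ", con=",
             con_val, ")", call. = FALSE)
      lr_t <- tc$lr
      if (!is.null(tc$warmup_steps) && tc$warmup_steps > 0)
        lr_t <- lr_t * min(1, (step + 1) / tc$warmup_steps)
      upd <- sgd_update(state$student_params, grads, velocity, lr = lr_t,
                        momentum = tc$momentum,
                        weight_decay = tc$weight_decay)
      state$student_params <- upd$params
      velocity <- upd$velocity
      state <- ema_update(state)
      step <- step + 1L
      state$step <- step
      log_rows[[step]] <- tibble::tibble(
        step = step, epoch = epoch, sup = !!sup$loss,
        dice_loss = !!sup$dice_loss, ce = !!sup$ce, con = con_val,
        lambda = lam, threshold = thr, total = total)
    }
    if (!is.null(cfg$out_dir) && !is.null(tc$checkpoint_every) &&
        (epoch %% tc$checkpoint_every == 0 || epoch == tc$epochs)) {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      save_checkpoint(list(spec = mspec, state = state, config = cfg),
                      file.path(cfg$out_dir,
                                sprintf("checkpoint_epoch%03d.rds", epoch)))
    }
  }
  log <- dplyr::bind_rows(log_rows)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(log, file.path(cfg$out_dir, "training_log.csv"),
                     row.names = FALSE)
  }
  structure(list(spec = mspec, student_params = state$student_params,
                 teacher_params = state$teacher_params, state = state,
                 log = log, config = cfg), class = "uamt_fit")
}

#' Extract a forward-ready network from a fit or checkpoint
#' @param fit A `uamt_fit` or loaded checkpoint list.
#' @param use `"teacher"` (EMA-smoothed, default) or `"student"`.
#' @return A `unet3d` object carrying the chosen parameters.
#' @export
fit_network <- function(fit, use = c("teacher", "student")) {
  use <- match.arg(use)
  params <- if (!is.null(fit$state))
    fit$state[[paste0(use, "_params")]]
  else fit[[paste0(use, "_params")]]
  structure(list(spec = fit$spec, params = params), class = "unet3d")
}

#' Save a training checkpoint
#'
#' Bundles the architecture spec with both parameter sets and the trainer
#' state, so inference needs no separate configuration.
#' @param ckpt List with `spec`, `state` (and optionally `config`).
#' @param path Output `.rds` path.
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' Load a training checkpoint
#' @param path Checkpoint `.rds` path.
#' @return The checkpoint list.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  readRDS(path)
}
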