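# Configuration plumbing: nested defaults, YAML loading, recursive merge.

#' Default training configuration
#'
#' Sections: `data` (manifest, training window, normalization), `model`
#' (passed to [network_spec()]), `loss` (passed to [loss_config()]) and
#' `trainer` (SGD and mean-teacher settings). The defaults follow the
#' usual mean-teacher recipe: SGD with learning rate 0.001, momentum 0.9,
#' weight decay 1e-4, one labeled + one unlabeled item per step, EMA decay
#' 0.99, 8 Monte-Carlo passes, Gaussian input noise (sigma 0.1 of the
#' normalized intensity scale, clipped at 0.2).
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    data = list(manifest = NULL, window = c(64L, 64L, 16L),
                normalize = "zscore"),
    model = list(in_channels = 1L, num_classes = 2L, levels = 4L,
                 base_channels = 16L, use_residual = TRUE, use_cbam = TRUE,
                 cam_reduction = 8L, sam_kernel = 7L, dropout_rate = 0.1,
                 dropout_bottleneck = 0.5),
    loss = list(lambda_max = 0.1, rampup_length = 1000L, smooth = 1e-5),
    trainer = list(lr = 0.001, warmup_steps = 0L, momentum = 0.9,
                   weight_decay = 1e-4,
                   epochs = 100L, ema_decay = 0.99, mc_passes = 8L,
                   clean_prob = 5 / 8, seed = 1L, checkpoint_every = 50L,
                   noise = list(sigma = 0.1, clip = 0.2)),
    out_dir = NULL
  )
}

#' Recursively merge a user configuration over defaults
#' @param base Default nested list.
#' @param override User-supplied nested list (may be partial).
#' @return Merged list.
#' @export
merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML configuration file (merged over defaults)
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  merge_config(default_config(), yaml::read_yaml(path))
}
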