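# Residual + CBAM 3D U-Net backbone.
#
# The encoder-decoder follows the usual 3D U-Net layout: per level two
# (3x3x3 conv -> InstanceNorm -> leaky ReLU) operations, max-pool
# downsampling, trilinear upsampling with skip concatenation on the way up,
# and a final 1x1x1 convolution to raw class scores. Two switchable
# features define the ablation axis: a residual skip across each block
# (identity, or a 1x1x1 projection when channel counts change) and a CBAM
# attention block (channel attention, then spatial attention) appended to
# each block's output.

#' Network architecture specification
#'
#' Describes the backbone so that networks can be built, serialized in
#' checkpoints and ablated. With `use_residual = FALSE, use_cbam = FALSE`
#' the network is a plain 3D U-Net; enabling `use_residual` adds per-block
#' residual skips; enabling both gives the full residual+attention backbone.
#'
#' @param in_channels Number of input image channels (1 for grayscale).
#' @param num_classes Number of output classes (2: background / target).
#' @param levels Encoder depth (number of resolution levels).
#' @param base_channels Feature channels at the first level; doubled per level.
#' @param use_residual Add residual skips across each conv block.
#' @param use_cbam Append channel-then-spatial attention to each block.
#' @param cam_reduction Channel-attention bottleneck reduction ratio.
#' @param sam_kernel Spatial-attention convolution kernel size (odd).
#' @param dropout_rate Dropout rate after encoder/decoder blocks.
#' @param dropout_bottleneck Dropout rate after the bottleneck block.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(in_channels = 1L, num_classes = 2L, levels = 4L,
                         base_channels = 16L, use_residual = TRUE,
                         use_cbam = TRUE, cam_reduction = 8L, sam_kernel = 7L,
                         dropout_rate = 0.1, dropout_bottleneck = 0.5) {
  stopifnot(in_channels >= 1, num_classes >= 2, levels >= 1, base_channels >= 1)
  if (sam_kernel %% 2 == 0) stop("sam_kernel must be odd", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1 || dropout_bottleneck < 0 ||
      dropout_bottleneck >= 1)
    stop("dropout rates must lie in [0, 1)", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 use_residual = isTRUE(use_residual),
                 use_cbam = isTRUE(use_cbam),
                 cam_reduction = as.integer(cam_reduction),
                 sam_kernel = as.integer(sam_kernel),
                 dropout_rate = dropout_rate,
                 dropout_bottleneck = dropout_bottleneck),
            class = "network_spec")
}

## ---- channel attention (CAM) ----

cam_init <- function(C, reduction) {
  if (reduction > C)
    stop("cam_reduction (", reduction, ") exceeds channel count (", C, ")",
         call. = FALSE)
  Cr <- max(1L, C %/% reduction)
  sd1 <- sqrt(2 / C)
  sd2 <- sqrt(2 / Cr)
  list(W1 = matrix(stats::rnorm(C * Cr, sd = sd1), C, Cr), b1 = numeric(Cr),
       W2 = matrix(stats::rnorm(Cr * C, sd = sd2), Cr, C), b2 = numeric(C))
}

cam_mlp <- function(v, p) {
  z1 <- drop(v %*% p$W1) + p$b1
  r1 <- pmax(z1, 0)
  list(z2 = drop(r1 %*% p$W2) + p$b2, r1 = r1, mask = z1 > 0)
}

cam_fwd <- function(x, p) {
  d <- dim(x)
  nvox <- prod(d[1:3])
  xm <- matrix(x, nvox, d[4])
  imax <- apply(xm, 2L, which.max)
  vmax <- xm[cbind(imax, seq_len(d[4]))]
  vavg <- colMeans(xm)
  bmax <- cam_mlp(vmax, p)
  bavg <- cam_mlp(vavg, p)
  s <- sigmoid(bmax$z2 + bavg$z2)
  y <- sweep(xm, 2L, s, `*`)
  dim(y) <- d
  list(y = y, weights = s,
       cache = list(xm = xm, s = s, imax = imax, vmax = vmax, vavg = vavg,
                    bmax = bmax, bavg = bavg, d = d))
}

cam_bwd <- function(p, cache, dy) {
  d <- cache$d
  nvox <- prod(d[1:3])
  dym <- matrix(dy, nvox, d[4])
  ds <- colSums(dym * cache$xm)
  dxm <- sweep(dym, 2L, cache$s, `*`)
  dpre <- ds * cache$s * (1 - cache$s)
  g <- list(W1 = 0 * p$W1, b1 = 0 * p$b1, W2 = 0 * p$W2, b2 = 0 * p$b2)
  branch_bwd <- function(v, br) {
    g$W2 <<- g$W2 + outer(br$r1, dpre)
    g$b2 <<- g$b2 + dpre
    dz1 <- drop(dpre %*% t(p$W2)) * br$mask
    g$W1 <<- g$W1 + outer(v, dz1)
    g$b1 <<- g$b1 + dz1
    drop(dz1 %*% t(p$W1))
  }
  dvmax <- branch_bwd(cache$vmax, cache$bmax)
  dvavg <- branch_bwd(cache$vavg, cache$bavg)
  dxm[cbind(cache$imax, seq_len(d[4]))] <-
    dxm[cbind(cache$imax, seq_len(d[4]))] + dvmax
  dxm <- sweep(dxm, 2L, dvavg / nvox, `+`)
  dim(dxm) <- d
  list(dx = dxm, grads = g)
}

## ---- spatial attention (SAM) ----

sam_init <- function(k) conv3d_init(2L, 1L, k)

sam_fwd <- function(x, p) {
  d <- dim(x)
  nvox <- prod(d[1:3])
  xm <- matrix(x, nvox, d[4])
  iarg <- max.col(xm, ties.method = "first")
  vmax <- xm[cbind(seq_len(nvox), iarg)]
  vavg <- rowMeans(xm)
  f2 <- array(c(vmax, vavg), c(d[1:3], 2L))
  cv <- conv3d_fwd(f2, p)
  s <- sigmoid(as.numeric(cv$y))
  y <- xm * s
  dim(y) <- d
  list(y = y, weights = array(s, d[1:3]),
       cache = list(xm = xm, s = s, iarg = iarg, cv = cv$cache, d = d))
}

sam_bwd <- function(p, cache, dy) {
  d <- cache$d
  nvox <- prod(d[1:3])
  dym <- matrix(dy, nvox, d[4])
  ds <- rowSums(dym * cache$xm)
  dxm <- dym * cache$s
  dpre <- ds * cache$s * (1 - cache$s)
  cb <- conv3d_bwd(p, cache$cv, array(dpre, c(d[1:3], 1L)))
  df2 <- matrix(cb$dx, nvox, 2L)
  dxm[cbind(seq_len(nvox), cache$iarg)] <-
    dxm[cbind(seq_len(nvox), cache$iarg)] + df2[, 1L]
  dxm <- dxm + df2[, 2L] / d[4]
  dim(dxm) <- d
  list(dx = dxm, grads = cb$grads)
}

#' Channel attention weighting
#'
#' Squeezes a feature map to per-channel descriptors by global max- and
#' average-pooling, passes both through a shared two-layer bottleneck and a
#' sigmoid, and rescales every channel by the resulting weight in (0, 1).
#'
#' @param features 4D array `[x, y, z, channels]`.
#' @param reduction Bottleneck reduction ratio (must not exceed the channel
#'   count).
#' @param params Optional parameter list (`W1`, `b1`, `W2`, `b2`) as produced
#'   internally; freshly initialized from the current RNG when `NULL`.
#' @return List with `output` (rescaled features), `weights` (per-channel
#'   vector in (0,1)) and `params`.
#' @export
channel_attention <- function(features, reduction = 8L, params = NULL) {
  stopifnot(length(dim(features)) == 4L)
  if (is.null(params)) params <- cam_init(dim(features)[4], reduction)
  r <- cam_fwd(features, params)
  list(output = r$y, weights = r$weights, params = params)
}

#' Spatial attention weighting
#'
#' Collapses a feature map to channelwise max and mean maps, convolves the
#' two-channel stack with a shape-preserving kernel, applies a sigmoid, and
#' rescales every voxel by the resulting weight in (0, 1).
#'
#' @param features 4D array `[x, y, z, channels]`.
#' @param kernel Odd convolution kernel size.
#' @param params Optional convolution parameters (`W`, `b`, `k`); freshly
#'   initialized when `NULL`.
#' @return List with `output`, `weights` (3D map in (0,1)) and `params`.
#' @export
spatial_attention <- function(features, kernel = 7L, params = NULL) {
  stopifnot(length(dim(features)) == 4L)
  if (kernel %% 2 == 0) stop("spatial attention kernel must be odd", call. = FALSE)
  if (is.null(params)) params <- sam_init(as.integer(kernel))
  r <- sam_fwd(features, params)
  list(output = r$y, weights = r$weights, params = params)
}

## ---- conv block ----

block_init <- function(cin, cout, spec) {
  p <- list(conv1 = conv3d_init(cin, cout, 3L), in1 = instnorm_init(cout),
            conv2 = conv3d_init(cout, cout, 3L), in2 = instnorm_init(cout))
  if (spec$use_residual && cin != cout)
    p$proj <- conv3d_init(cin, cout, 1L)
  if (spec$use_cbam) {
    p$cam <- cam_init(cout, spec$cam_reduction)
    p$sam <- sam_init(spec$sam_kernel)
  }
  p
}

block_fwd <- function(x, p, spec) {
  c1 <- conv3d_fwd(x, p$conv1); n1 <- instnorm_fwd(c1$y, p$in1)
  a1 <- lrelu_fwd(n1$y)
  c2 <- conv3d_fwd(a1$y, p$conv2); n2 <- instnorm_fwd(c2$y, p$in2)
  a2 <- lrelu_fwd(n2$y)
  y <- a2$y
  cam <- sam <- NULL
  if (spec$use_cbam) {
    # attention refines the convolutional branch only (channel strictly
    # before spatial); the identity/projection path below stays unattenuated
    cam <- cam_fwd(y, p$cam)
    sam <- sam_fwd(cam$y, p$sam)
    y <- sam$y
  }
  pr <- NULL
  if (spec$use_residual) {
    if (!is.null(p$proj)) {
      pr <- conv3d_fwd(x, p$proj)
      y <- y + pr$y
    } else y <- y + x
  }
  list(y = y, cache = list(c1 = c1$cache, n1 = n1$cache, a1 = a1$cache,
                           c2 = c2$cache, n2 = n2$cache, a2 = a2$cache,
                           pr = if (!is.null(pr)) pr$cache,
                           cam = if (!is.null(cam)) cam$cache,
                           sam = if (!is.null(sam)) sam$cache))
}

block_bwd <- function(p, spec, cache, dy) {
  g <- list()
  dx_res <- NULL
  if (spec$use_residual) {
    if (!is.null(cache$pr)) {
      pb <- conv3d_bwd(p$proj, cache$pr, dy)
      g$proj <- pb$grads
      dx_res <- pb$dx
    } else dx_res <- dy
  }
  if (spec$use_cbam) {
    sb <- sam_bwd(p$sam, cache$sam, dy); g$sam <- sb$grads
    cb <- cam_bwd(p$cam, cache$cam, sb$dx); g$cam <- cb$grads
    dy <- cb$dx
  }
  da2 <- lrelu_bwd(cache$a2, dy)
  n2 <- instnorm_bwd(p$in2, cache$n2, da2); g$in2 <- n2$grads
  c2 <- conv3d_bwd(p$conv2, cache$c2, n2$dx); g$conv2 <- c2$grads
  da1 <- lrelu_bwd(cache$a1, c2$dx)
  n1 <- instnorm_bwd(p$in1, cache$n1, da1); g$in1 <- n1$grads
  c1 <- conv3d_bwd(p$conv1, cache$c1, n1$dx); g$conv1 <- c1$grads
  dx <- c1$dx
  if (!is.null(dx_res)) dx <- dx + dx_res
  list(dx = dx, grads = g)
}

## ---- full network ----

#' Build a backbone network
#'
#' Instantiates parameters for the residual/CBAM 3D U-Net described by a
#' [network_spec()]. Initialization draws from the current RNG
#' (Kaiming-style for convolutions), so `set.seed()` makes construction
#' reproducible.
#'
#' @param spec A [network_spec()].
#' @return An object of class `unet3d`: list with `spec` and nested `params`.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  L <- spec$levels
  width <- spec$base_channels * 2^(seq_len(L) - 1L)
  params <- list(enc = list(), dec = list())
  cin <- spec$in_channels
  for (i in seq_len(L)) {
    params$enc[[i]] <- block_init(cin, width[i], spec)
    cin <- width[i]
  }
  if (L > 1L)
    for (i in seq_len(L - 1L))
      params$dec[[i]] <- block_init(width[i] + width[i + 1L], width[i], spec)
  params$final <- conv3d_init(width[1L], spec$num_classes, 1L)
  structure(list(spec = spec, params = params), class = "unet3d")
}

check_volume_depth <- function(d, levels) {
  f <- 2^(levels - 1L)
  if (any(d %% f != 0L) || any(d %/% f < 1L))
    stop("volume shape (", paste(d, collapse = "x"), ") is not divisible by 2^",
         levels - 1L, "; network too deep for this input", call. = FALSE)
}

as_input_array <- function(x, in_channels) {
  if (length(dim(x)) == 3L) {
    stopifnot(in_channels == 1L)
    dim(x) <- c(dim(x), 1L)
  }
  stopifnot(length(dim(x)) == 4L, dim(x)[4] == in_channels)
  x
}

#' Forward pass through a backbone network
#'
#' @param net A `unet3d` object (or its parameter list via `params`).
#' @param x Input volume: 3D array (single channel) or 4D array.
#' @param params Optional parameter list overriding `net$params` (used for
#'   teacher-parameter forward passes).
#' @param dropout Apply dropout (stochastic forward). Off by default, giving
#'   a deterministic pass.
#' @param with_cache Keep layer caches for a subsequent backward pass.
#' @return If `with_cache`, list(`logits`, `cache`); otherwise the raw-score
#'   array `[x, y, z, num_classes]`.
#' @export
net_forward <- function(net, x, params = NULL, dropout = FALSE,
                        with_cache = FALSE) {
  spec <- net$spec
  if (is.null(params)) params <- net$params
  x <- as_input_array(x, spec$in_channels)
  check_volume_depth(dim(x)[1:3], spec$levels)
  L <- spec$levels
  enc_cache <- vector("list", L)
  drop_cache <- vector("list", L)
  pool_cache <- vector("list", L - 1L)
  skips <- vector("list", L - 1L)
  h <- x
  for (i in seq_len(L)) {
    b <- block_fwd(h, params$enc[[i]], spec)
    rate <- if (i == L) spec$dropout_bottleneck else spec$dropout_rate
    dr <- dropout_fwd(b$y, rate, dropout)
    enc_cache[[i]] <- b$cache
    drop_cache[i] <- list(dr$cache)
    h <- dr$y
    if (i < L) {
      skips[[i]] <- h
      pl <- maxpool_fwd(h)
      pool_cache[[i]] <- pl$cache
      h <- pl$y
    }
  }
  dec_cache <- vector("list", max(L - 1L, 0L))
  up_cache <- vector("list", max(L - 1L, 0L))
  dec_drop <- vector("list", max(L - 1L, 0L))
  if (L > 1L) for (i in rev(seq_len(L - 1L))) {
    up <- upsample_fwd(h, dim(skips[[i]])[1:3])
    ccat <- array(c(skips[[i]], up$y),
                  c(dim(up$y)[1:3], dim(skips[[i]])[4] + dim(up$y)[4]))
    b <- block_fwd(ccat, params$dec[[i]], spec)
    dr <- dropout_fwd(b$y, spec$dropout_rate, dropout)
    up_cache[[i]] <- up$cache
    dec_cache[[i]] <- b$cache
    dec_drop[i] <- list(dr$cache)
    h <- dr$y
  }
  fin <- conv3d_fwd(h, params$final)
  if (!with_cache) return(fin$y)
  list(logits = fin$y,
       cache = list(enc = enc_cache, drop = drop_cache, pool = pool_cache,
                    dec = dec_cache, up = up_cache, dec_drop = dec_drop,
                    fin = fin$cache,
                    skip_ch = if (L > 1L) vapply(skips, function(s) dim(s)[4],
                                                 integer(1))))
}

#' Backward pass: gradients of a scalar loss w.r.t. all parameters
#'
#' @param net A `unet3d` object.
#' @param cache Cache from `net_forward(..., with_cache = TRUE)`.
#' @param dlogits Gradient of the loss w.r.t. the raw scores.
#' @param params Optional parameter list overriding `net$params`.
#' @return Nested gradient list congruent with `net$params`.
#' @export
net_backward <- function(net, cache, dlogits, params = NULL) {
  spec <- net$spec
  if (is.null(params)) params <- net$params
  L <- spec$levels
  g <- list(enc = vector("list", L), dec = vector("list", max(L - 1L, 0L)))
  fb <- conv3d_bwd(params$final, cache$fin, dlogits)
  g$final <- fb$grads
  dh <- fb$dx
  dskip <- vector("list", max(L - 1L, 0L))
  if (L > 1L) for (i in seq_len(L - 1L)) {
    dh <- dropout_bwd(cache$dec_drop[[i]], dh)
    bb <- block_bwd(params$dec[[i]], spec, cache$dec[[i]], dh)
    g$dec[[i]] <- bb$grads
    nc <- cache$skip_ch[i]
    d <- dim(bb$dx)
    dskip[[i]] <- bb$dx[, , , seq_len(nc), drop = FALSE]
    dup <- bb$dx[, , , nc + seq_len(d[4] - nc), drop = FALSE]
    dh <- upsample_bwd(cache$up[[i]], dup)
  }
  for (i in rev(seq_len(L))) {
    if (i < L) {
      dh <- maxpool_bwd(cache$pool[[i]], dh)
      dh <- dh + dskip[[i]]
    }
    dh <- dropout_bwd(cache$drop[[i]], dh)
    bb <- block_bwd(params$enc[[i]], spec, cache$enc[[i]], dh)
    g$enc[[i]] <- bb$grads
    dh <- bb$dx
  }
  g
}

## ---- parameter utilities ----

is_param_leaf <- function(x) is.numeric(x)

#' Apply a function over every parameter tensor
#'
#' Kernel-size markers (elements named `"k"`) are structural, not trainable,
#' and are left untouched.
#' @param p Nested parameter (or gradient) list.
#' @param f Function applied to each numeric leaf.
#' @return Structure-congruent list.
#' @keywords internal
param_map <- function(p, f) {
  if (is.list(p)) {
    out <- p
    if (!is.null(names(p))) {
      for (nm in names(p)) out[[nm]] <- if (nm == "k") p[[nm]] else
        param_map(p[[nm]], f)
    } else for (i in seq_along(p)) out[[i]] <- param_map(p[[i]], f)
    out
  } else if (is_param_leaf(p)) f(p) else p
}

# Elementwise combine two congruent parameter structures, matching named
# entries by name (gradient lists may omit "k" and order groups differently).
param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    if (!is.null(names(a))) {
      # b may carry structural "k" markers a gradient list omits; any other
      # name mismatch means the parameter sets are incongruent
      bad <- union(setdiff(names(a), c(names(b), "k")),
                   setdiff(names(b), c(names(a), "k")))
      if (length(bad))
        stop("incongruent parameter sets: '", paste(bad, collapse = "', '"),
             "'", call. = FALSE)
      for (nm in names(a)) {
        if (nm == "k" || is.null(b[[nm]])) next
        out[[nm]] <- param_map2(a[[nm]], b[[nm]], f)
      }
    } else {
      if (length(a) != length(b))
        stop("incongruent parameter sets", call. = FALSE)
      for (i in seq_along(a)) out[[i]] <- param_map2(a[[i]], b[[i]], f)
    }
    out
  } else if (is_param_leaf(a)) {
    if (!is_param_leaf(b) || length(a) != length(b))
      stop("incongruent parameter sets", call. = FALSE)
    f(a, b)
  } else a
}

param_reduce <- function(p, f, acc = 0) {
  if (is.list(p)) {
    for (el in p) acc <- param_reduce(el, f, acc)
    acc
  } else if (is_param_leaf(p)) f(acc, p) else acc
}

#' Total number of trainable parameters
#' @param net A `unet3d` object or parameter list.
#' @return Integer count.
#' @export
count_params <- function(net) {
  p <- if (inherits(net, "unet3d")) net$params else net
  # kernel-size markers ("k") are structural, not trainable
  count <- function(q) {
    if (is.list(q)) {
      n <- 0
      for (nm in names(q)) if (nm != "k") n <- n + count(q[[nm]])
      if (is.null(names(q))) for (el in q) n <- n + count(el)
      n
    } else if (is.numeric(q)) length(q) else 0
  }
  count(p)
}

#' Names of parameter groups present in a network
#'
#' Used to check the ablation wiring: attention parameter groups (`cam`,
#' `sam`) exist iff `use_cbam`; projection convolutions (`proj`) exist iff
#' `use_residual`.
#' @param net A `unet3d` object.
#' @return Character vector of unique parameter-group names.
#' @export
param_group_names <- function(net) {
  nm <- character(0)
  walk <- function(q) {
    if (is.list(q)) {
      nm <<- union(nm, names(q))
      for (el in q) walk(el)
    }
  }
  walk(net$params)
  setdiff(nm, "")
}
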