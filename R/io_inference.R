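# Volume I/O, preprocessing and sliding-window whole-volume inference.

#' Load a 3D volume from NIfTI
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return List with `data` (3D array), `spacing` (mm triple).
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D: ", path, call. = FALSE)
  list(data = array(as.numeric(img), d), spacing = RNifti::pixdim(img)[1:3])
}

#' Save a 3D volume as NIfTI
#' @param data 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing mm-per-voxel triple stored in the header.
#' @export
save_volume <- function(data, path, spacing = c(1, 1, 1)) {
  img <- structure(data, pixdim = as.numeric(spacing))
  RNifti::writeNifti(RNifti::asNifti(img, datatype = "double"), path)
  invisible(path)
}

#' Intensity normalization
#'
#' `zscore` maps to zero mean, unit variance (a constant volume maps to all
#' zeros); `minmax` maps the observed range to exactly [0, 1].
#'
#' @param volume 3D array.
#' @param mode `"zscore"` or `"minmax"`.
#' @return Normalized array of the same shape.
#' @export
normalize_intensity <- function(volume, mode = c("zscore", "minmax")) {
  mode <- match.arg(mode)
  if (mode == "zscore") {
    s <- stats::sd(volume)
    if (!is.finite(s) || s == 0) return(array(0, dim(volume)))
    (volume - mean(volume)) / s
  } else {
    rng <- range(volume)
    if (rng[1] == rng[2]) return(array(0, dim(volume)))
    (volume - rng[1]) / (rng[2] - rng[1])
  }
}

#' Center crop (with symmetric background padding)
#'
#' Extracts the centered `target_shape` sub-volume; axes smaller than the
#' target are padded symmetrically with a constant background (left pad
#' `floor`, right pad `ceil`). The returned bookkeeping allows predictions
#' on the crop to be re-embedded into the original geometry.
#'
#' @param volume 3D array.
#' @param target_shape Integer triple.
#' @param fill Background fill value for padding.
#' @return List: `data` (cropped/padded array), `crop` (offsets bookkeeping).
#' @export
center_crop <- function(volume, target_shape, fill = 0) {
  stopifnot(length(target_shape) == 3L, all(target_shape > 0))
  d <- dim(volume)
  t <- as.integer(target_shape)
  off <- pmax(0L, (d - t) %/% 2L)          # crop offset in the source
  ext <- pmin(d, t)                        # copied extent
  pad <- pmax(0L, (t - d) %/% 2L)          # left pad in the target
  out <- array(fill, t)
  src <- lapply(1:3, function(i) off[i] + seq_len(ext[i]))
  dst <- lapply(1:3, function(i) pad[i] + seq_len(ext[i]))
  out[dst[[1]], dst[[2]], dst[[3]]] <- volume[src[[1]], src[[2]], src[[3]]]
  list(data = out,
       crop = list(offset = off, extent = ext, pad = pad, orig_shape = d,
                   target_shape = t))
}

#' Re-embed a cropped prediction into the original geometry
#' @param data Array on the crop grid (3D, or 4D with trailing channels).
#' @param crop Bookkeeping list from [center_crop()].
#' @param fill Fill value outside the crop.
#' @return Array on the original grid.
#' @export
embed_crop <- function(data, crop, fill = 0) {
  nd <- length(dim(data))
  ch <- if (nd == 4L) dim(data)[4] else 1L
  out <- array(fill, c(crop$orig_shape, ch))
  src <- lapply(1:3, function(i) crop$pad[i] + seq_len(crop$extent[i]))
  dst <- lapply(1:3, function(i) crop$offset[i] + seq_len(crop$extent[i]))
  if (nd == 4L) {
    out[dst[[1]], dst[[2]], dst[[3]], ] <- data[src[[1]], src[[2]], src[[3]], ]
  } else {
    out[dst[[1]], dst[[2]], dst[[3]], 1L] <- data[src[[1]], src[[2]], src[[3]]]
    dim(out) <- crop$orig_shape
  }
  out
}

#' Window start positions covering one axis
#' @noRd
window_starts <- function(n, w, s) {
  if (w >= n) return(1L)
  st <- seq.int(1L, n - w + 1L, by = s)
  if (st[length(st)] != n - w + 1L) st <- c(st, n - w + 1L)
  st
}

#' Sliding-window whole-volume prediction
#'
#' Runs the network in deterministic mode (dropout off) over overlapping
#' windows and averages the per-window softmax maps where windows overlap,
#' so the aggregated class probabilities remain on the simplex at every
#' voxel. Volumes smaller than the window are padded with background and
#' cropped back. The label map breaks argmax ties toward background
#' (class 0).
#'
#' @param net A `unet3d` network.
#' @param volume 3D array.
#' @param window Integer triple; window spatial shape.
#' @param stride Integer triple; defaults to half the window.
#' @param params Optional parameters overriding `net$params` (e.g. the
#'   teacher parameter set).
#' @return List: `probs` (`[x, y, z, num_classes]`) and `labels`
#'   (integer array, 0 = background).
#' @export
sliding_window_predict <- function(net, volume, window,
                                   stride = pmax(1L, window %/% 2L),
                                   params = NULL) {
  window <- as.integer(window); stride <- as.integer(stride)
  check_volume_depth(window, net$spec$levels)
  d0 <- dim(volume)
  cr <- NULL
  if (any(d0 < window)) {
    cr <- center_crop(volume, pmax(d0, window))
    volume <- cr$data
  }
  d <- dim(volume)
  C <- net$spec$num_classes
  acc <- array(0, c(d, C))
  cnt <- array(0, d)
  sx <- window_starts(d[1], window[1], stride[1])
  sy <- window_starts(d[2], window[2], stride[2])
  sz <- window_starts(d[3], window[3], stride[3])
  for (x0 in sx) for (y0 in sy) for (z0 in sz) {
    ix <- x0:(x0 + window[1] - 1L)
    iy <- y0:(y0 + window[2] - 1L)
    iz <- z0:(z0 + window[3] - 1L)
    logits <- net_forward(net, volume[ix, iy, iz], params = params,
                          dropout = FALSE)
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, , drop = FALSE] +
      softmax_channels(logits)
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  probs <- acc / as.numeric(cnt)
  if (!is.null(cr)) probs <- embed_crop(probs, cr$crop)
  pm <- matrix(probs, prod(dim(probs)[1:3]), C)
  labels <- max.col(pm, ties.method = "first") - 1L  # ties -> background
  dim(labels) <- dim(probs)[1:3]
  list(probs = probs, labels = labels)
}
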