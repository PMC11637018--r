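# Overlap and surface-distance segmentation metrics.
#
# Surface voxels are mask voxels with at least one face-adjacent
# (6-connectivity) background neighbour; voxels on the array border count
# as surface. Distances are Euclidean in physical units (voxel indices
# scaled by spacing). The 95th-percentile Hausdorff distance and the
# average surface distance are symmetric: directed nearest-surface
# distances are pooled over both directions before the percentile / mean.

check_masks <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask shapes do not agree", call. = FALSE)
  list(a = a > 0, b = b > 0)
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks count as perfect agreement (1).
#' @param a,b Binary masks (same shape; nonzero = foreground).
#' @return Scalar in [0, 1].
#' @export
dsc <- function(a, b) {
  m <- check_masks(a, b)
  sa <- sum(m$a); sb <- sum(m$b)
  if (sa + sb == 0) return(1)
  2 * sum(m$a & m$b) / (sa + sb)
}

#' Jaccard index
#'
#' `|A n B| / |A u B|`; two empty masks give 1.
#' @inheritParams dsc
#' @return Scalar in [0, 1].
#' @export
jaccard <- function(a, b) {
  m <- check_masks(a, b)
  u <- sum(m$a | m$b)
  if (u == 0) return(1)
  sum(m$a & m$b) / u
}

#' Surface voxels of a binary mask
#'
#' A mask voxel is a surface voxel when at least one of its six
#' face-adjacent neighbours is background; outside the array counts as
#' background.
#' @param mask Binary 3D array.
#' @return Logical array marking surface voxels.
#' @export
surface_voxels <- function(mask) {
  m <- mask > 0
  d <- dim(m)
  interior <- array(TRUE, d)
  shift <- function(arr, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by == 1) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1, 1)) {
    if (d[ax] == 1) { interior[] <- FALSE; next }
    interior <- interior & shift(m, ax, by)
  }
  m & !interior
}

surface_points <- function(mask, spacing) {
  idx <- which(surface_voxels(mask), arr.ind = TRUE)
  sweep(idx, 2L, spacing, `*`)
}

pooled_surface_dists <- function(a, b, spacing) {
  m <- check_masks(a, b)
  sa <- sum(m$a); sb <- sum(m$b)
  if (sa + sb == 0) return(numeric(0))      # both empty: distance 0 upstream
  if (sa == 0 || sb == 0)
    stop("surface distance undefined for an empty mask", call. = FALSE)
  pa <- surface_points(m$a, spacing)
  pb <- surface_points(m$b, spacing)
  list(ab = min_dists(pa, pb), ba = min_dists(pb, pa))
}

#' 95th-percentile Hausdorff distance
#'
#' 95th percentile (linear interpolation) of the pooled directed
#' nearest-surface distances in both directions.
#' @inheritParams dsc
#' @param spacing mm-per-voxel triple.
#' @return Distance in the units of `spacing`; 0 when both masks are empty;
#'   error when exactly one mask is empty.
#' @export
hd95 <- function(a, b, spacing = c(1, 1, 1)) {
  d <- pooled_surface_dists(a, b, spacing)
  if (length(d) == 0) return(0)
  unname(stats::quantile(c(d$ab, d$ba), 0.95, type = 7))
}

#' Full (symmetric) Hausdorff distance
#' @inheritParams hd95
#' @return Maximum of all directed nearest-surface distances.
#' @export
hausdorff <- function(a, b, spacing = c(1, 1, 1)) {
  d <- pooled_surface_dists(a, b, spacing)
  if (length(d) == 0) return(0)
  max(c(d$ab, d$ba))
}

#' Average surface distance
#'
#' `(sum_a min_b ||a-b|| + sum_b min_a ||b-a||) / (|S(A)| + |S(B)|)` over
#' surface voxels.
#' @inheritParams hd95
#' @return Distance in the units of `spacing`.
#' @export
asd <- function(a, b, spacing = c(1, 1, 1)) {
  d <- pooled_surface_dists(a, b, spacing)
  if (length(d) == 0) return(0)
  (sum(d$ab) + sum(d$ba)) / (length(d$ab) + length(d$ba))
}

#' Relative change in percent
#'
#' `(proposed - reference) / reference * 100`; positive means increase.
#' @param reference Baseline value (nonzero).
#' @param proposed New value.
#' @return Signed percentage.
#' @export
relative_change <- function(reference, proposed) {
  if (any(reference == 0)) stop("reference must be nonzero", call. = FALSE)
  (proposed - reference) / reference * 100
}

#' Relative-change table between methods
#'
#' For a tibble of per-method metric values (long format produced here from
#' wide columns `dsc`, `jaccard`, `hd95`, `asd`), computes the percent
#' change of `proposed` relative to every other method, per metric and per
#' grouping value.
#'
#' @param values Tibble with columns `method`, `dsc`, `jaccard`, `hd95`,
#'   `asd`, and optionally a grouping column named by `group`.
#' @param proposed Name of the proposed method (the numerator).
#' @param group Optional grouping column (e.g. labeled-data setting).
#' @return Tibble: grouping column (if any), `metric`, `reference_method`,
#'   `reference`, `proposed`, `change_pct`.
#' @export
relative_change_table <- function(values, proposed, group = NULL) {
  long <- tidyr::pivot_longer(values, cols = c("dsc", "jaccard", "hd95",
                                               "asd"),
                              names_to = "metric", values_to = "value")
  keys <- c(group, "metric")
  prop <- dplyr::select(dplyr::filter(long, .data$method == proposed),
                        dplyr::all_of(keys), proposed_value = "value")
  refs <- dplyr::filter(long, .data$method != proposed)
  out <- dplyr::inner_join(refs, prop, by = keys)
  out <- dplyr::mutate(out,
                       change_pct = relative_change(.data$value,
                                                    .data$proposed_value))
  dplyr::select(out, dplyr::all_of(group), "metric",
                reference_method = "method", reference = "value",
                proposed = "proposed_value", "change_pct")
}

#' Evaluate a trained model on the test split
#'
#' Sliding-window inference on each test case's degraded (CBCT-like)
#' volume, compared against its ground-truth mask. Distance metrics for a
#' case with an empty prediction or ground truth (but not both) are
#' reported as `NA` with a warning; both-empty cases score overlap 1 and
#' distance 0.
#'
#' @param fit A `uamt_fit` (or checkpoint) from [train()].
#' @param manifest Manifest tibble or path.
#' @param window Sliding-window shape; defaults to the training window.
#' @param stride Window stride; defaults to half the window.
#' @param use `"teacher"` (default) or `"student"` network.
#' @param units `"mm"` (uses voxel spacing) or `"voxel"`.
#' @param split Which split to evaluate (default `"test"`).
#' @return Object of class `metric_report`: `per_case` tibble, `aggregate`
#'   tibble (mean and sd per metric), `units`.
#' @export
evaluate <- function(fit, manifest, window = NULL, stride = NULL,
                     use = "teacher", units = c("mm", "voxel"),
                     split = "test") {
  units <- match.arg(units)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  cfg <- fit$config
  if (is.null(window)) window <- cfg$data$window
  if (is.null(window)) stop("window must be given", call. = FALSE)
  window <- as.integer(window)
  if (is.null(stride)) stride <- pmax(1L, window %/% 2L)
  net <- fit_network(fit, use = use)
  cases <- dplyr::filter(manifest, .data$split == !!split)
  if (nrow(cases) == 0) stop("no cases in split '", split, "'", call. = FALSE)
  norm_mode <- if (!is.null(cfg$data$normalize)) cfg$data$normalize else "zscore"
  rows <- purrr::pmap(cases, function(case_id, degraded_path, mask_path, ...) {
    vol <- load_volume(degraded_path)
    if (!file.exists(mask_path)) {
      warning("no ground truth for ", case_id, "; case skipped")
      return(NULL)
    }
    gt <- round(load_volume(mask_path)$data)
    x <- normalize_intensity(vol$data, norm_mode)
    pred <- sliding_window_predict(net, x, window, stride)$labels
    spc <- if (units == "mm") vol$spacing else c(1, 1, 1)
    h <- av <- NA_real_
    if (sum(pred > 0) == 0 || sum(gt > 0) == 0) {
      if (sum(pred > 0) + sum(gt > 0) == 0) { h <- 0; av <- 0 }
      else warning("empty prediction or truth for ", case_id,
                   "; distance metrics reported as NA")
    } else {
      h <- hd95(pred, gt, spc)
      av <- asd(pred, gt, spc)
    }
    tibble::tibble(case_id = case_id, dsc = dsc(pred, gt),
                   jaccard = jaccard(pred, gt), hd95 = h, asd = av)
  })
  per_case <- dplyr::bind_rows(rows)
  aggregate <- tidyr::pivot_longer(per_case, cols = c("dsc", "jaccard",
                                                      "hd95", "asd"),
                                   names_to = "metric", values_to = "value")
  aggregate <- dplyr::summarise(dplyr::group_by(aggregate, .data$metric),
                                mean = mean(.data$value, na.rm = TRUE),
                                sd = stats::sd(.data$value, na.rm = TRUE),
                                n = sum(!is.na(.data$value)),
                                .groups = "drop")
  structure(list(per_case = per_case, aggregate = aggregate, units = units),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Segmentation metric report (", x$units, ")\n", sep = "")
  print(x$aggregate)
  invisible(x)
}

#' Published benchmark metric values shipped with the package
#'
#' Reference mean DSC / Jaccard / 95HD / ASD values reported for
#' mean-teacher-family semi-supervised methods on a clinical breast-CBCT
#' target-volume benchmark, at 5/10/20% labeled data plus a backbone
#' ablation (plain, +residual, +residual+CBAM). Used to recompute the
#' published relative-improvement percentages with
#' [relative_change_table()].
#'
#' @return Tibble with columns `setting`, `method`, `dsc`, `jaccard`,
#'   `hd95`, `asd`.
#' @export
benchmark_metrics <- function() {
  path <- system.file("extdata", "benchmark_metrics.csv", package = "uamt3d")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
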