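# Synthetic CT/CBCT-like phantom volumes.
#
# Each case is a half-ellipsoidal soft-tissue target ("breast") of
# intermediate intensity sitting on the anterior face of a high-intensity
# planar slab ("chest wall"), on a zero-intensity background. The clean
# volume emulates planning CT; the degraded sibling emulates CBCT of the
# same anatomy: a low-frequency multiplicative shading field, additive
# Gaussian noise, and lateral truncation (outermost columns zeroed).
# Intensities are abstract units, not HU; normalization happens downstream.

#' Phantom dataset specification
#'
#' @param volume_shape Integer triple, voxels per axis (x = lateral,
#'   y = anterior-posterior, z = axial).
#' @param spacing Positive mm-per-voxel triple.
#' @param n_cases Number of cases to generate.
#' @param labeled_fraction Fraction of cases carrying labels, in (0, 1].
#' @param noise_sigma Additive Gaussian noise s.d. in the degraded volume
#'   (abstract intensity units; clean tissue contrast is 0.5).
#' @param shading_amp Amplitude of the low-frequency multiplicative shading
#'   field (field ranges over `1 +/- shading_amp`).
#' @param truncation_fraction Fraction of lateral (x) columns zeroed on one
#'   side of the degraded volume, in [0, 0.5).
#' @param test_fraction Fraction of cases held out as the test split.
#' @param seed Integer seed; each case draws from a stream derived from
#'   `(seed, case_index)` so any single case regenerates independently.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(64L, 64L, 16L), spacing = c(1, 1, 3),
                         n_cases = 40L, labeled_fraction = 0.1,
                         noise_sigma = 0.1, shading_amp = 0.2,
                         truncation_fraction = 0.1, test_fraction = 0.2,
                         seed = 1L) {
  if (length(volume_shape) != 3L || any(volume_shape <= 0))
    stop("volume_shape must be a positive integer triple", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be a positive triple", call. = FALSE)
  if (n_cases < 1) stop("n_cases must be positive", call. = FALSE)
  if (labeled_fraction <= 0 || labeled_fraction > 1)
    stop("labeled_fraction must lie in (0, 1]", call. = FALSE)
  if (noise_sigma < 0 || shading_amp < 0)
    stop("noise_sigma and shading_amp must be nonnegative", call. = FALSE)
  if (truncation_fraction < 0 || truncation_fraction >= 0.5)
    stop("truncation_fraction must lie in [0, 0.5)", call. = FALSE)
  if (test_fraction < 0 || test_fraction >= 1)
    stop("test_fraction must lie in [0, 1)", call. = FALSE)
  structure(list(volume_shape = as.integer(volume_shape),
                 spacing = as.numeric(spacing),
                 n_cases = as.integer(n_cases),
                 labeled_fraction = labeled_fraction,
                 noise_sigma = noise_sigma, shading_amp = shading_amp,
                 truncation_fraction = truncation_fraction,
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "phantom_spec")
}

# intensity levels (abstract units)
PHANTOM_BG <- 0
PHANTOM_TARGET <- 0.5
PHANTOM_SLAB <- 1.0

case_seed <- function(spec, case_index) {
  as.integer((as.double(spec$seed) * 10007 + as.double(case_index) * 7919 + 1) %%
               2147483647)
}

#' Generate one phantom case
#'
#' Deterministic in `(spec, case_index)`: the case draws from its own RNG
#' stream, so regenerating any single case gives bit-identical volumes. The
#' target mask never touches the outermost two-voxel border slab.
#'
#' @param spec A [phantom_spec()].
#' @param case_index 0-based case index in `[0, n_cases)`.
#' @return Object of class `phantom_case`: `clean_volume`, `degraded_volume`,
#'   `mask` (0/1 array), `spacing`, `labeled`, `case_id`.
#' @export
generate_case <- function(spec, case_index) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (case_index < 0 || case_index >= spec$n_cases)
    stop("case_index must lie in [0, n_cases)", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(case_seed(spec, case_index))
  d <- spec$volume_shape
  nx <- d[1]; ny <- d[2]; nz <- d[3]

  # geometry: slab posterior, half-ellipsoid target on its anterior face
  y_slab <- round(0.62 * ny)
  slab_thick <- max(2L, round(0.08 * ny))
  cx <- nx / 2 + stats::runif(1, -0.05, 0.05) * nx
  cz <- nz / 2 + stats::runif(1, -0.05, 0.05) * nz
  a <- stats::runif(1, 0.22, 0.28) * nx
  b <- stats::runif(1, 0.28, 0.35) * ny
  cc <- stats::runif(1, 0.20, 0.26) * nz

  xs <- seq_len(nx); ys <- seq_len(ny); zs <- seq_len(nz)
  ex <- ((xs - cx) / a)^2
  ey <- ((ys - y_slab) / b)^2
  ez <- ((zs - cz) / cc)^2
  e3 <- outer(outer(ex, ey, `+`), ez, `+`)
  half <- outer(outer(rep(TRUE, nx), ys < y_slab, `&`), rep(TRUE, nz), `&`)
  mask <- (e3 <= 1) & half
  # clamp to the reserved 2-voxel background border
  border <- array(TRUE, d)
  border[3:(nx - 2), 3:(ny - 2), 3:(nz - 2)] <- FALSE
  mask[border] <- FALSE

  clean <- array(PHANTOM_BG, d)
  slab_idx <- ys >= y_slab & ys < y_slab + slab_thick
  clean[, slab_idx, ] <- PHANTOM_SLAB
  clean[mask] <- PHANTOM_TARGET

  # degraded sibling: multiplicative shading x clean + additive noise,
  # then lateral truncation
  ph <- stats::runif(3, 0, 2 * pi)
  fx <- cos(2 * pi * xs / nx + ph[1])
  fy <- cos(2 * pi * ys / ny + ph[2])
  fz <- cos(2 * pi * zs / nz + ph[3])
  shading <- 1 + spec$shading_amp * outer(outer(fx, fy), fz)
  degraded <- clean * shading
  if (spec$noise_sigma > 0)
    degraded <- degraded + stats::rnorm(length(degraded), sd = spec$noise_sigma)
  ntrunc <- floor(spec$truncation_fraction * nx)
  if (ntrunc > 0) degraded[(nx - ntrunc + 1):nx, , ] <- PHANTOM_BG

  structure(list(clean_volume = clean, degraded_volume = degraded,
                 mask = array(as.numeric(mask), d), spacing = spec$spacing,
                 labeled = NA, case_id = sprintf("case_%03d", case_index)),
            class = "phantom_case")
}

#' Generate and write a phantom dataset
#'
#' Writes every case as NIfTI volume pairs plus mask, and a JSON manifest.
#' The first `ceiling(labeled_fraction * n_cases)` cases are labeled; the
#' last `floor(test_fraction * n_cases)` cases form the test split (all
#' labeled cases are training cases).
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a tibble (invisibly also written as
#'   `manifest.json`): `case_id`, `clean_path`, `degraded_path`, `mask_path`,
#'   `labeled`, `split`.
#' @export
generate_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  n <- spec$n_cases
  n_labeled <- ceiling(spec$labeled_fraction * n)
  n_test <- floor(spec$test_fraction * n)
  rows <- vector("list", n)
  for (i in seq_len(n) - 1L) {
    cs <- generate_case(spec, i)
    paths <- file.path(out_dir, paste0(cs$case_id,
                                       c("_clean.nii.gz", "_degraded.nii.gz",
                                         "_mask.nii.gz")))
    save_volume(cs$clean_volume, paths[1], spacing = spec$spacing)
    save_volume(cs$degraded_volume, paths[2], spacing = spec$spacing)
    save_volume(cs$mask, paths[3], spacing = spec$spacing)
    rows[[i + 1L]] <- tibble::tibble(
      case_id = cs$case_id, clean_path = paths[1], degraded_path = paths[2],
      mask_path = paths[3], labeled = i < n_labeled,
      split = if (i >= n - n_test) "test" else "train")
  }
  manifest <- dplyr::bind_rows(rows)
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  manifest
}

#' Write a dataset manifest as JSON
#' @param manifest Manifest tibble as returned by [generate_dataset()].
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dataset manifest
#' @param path Manifest JSON path.
#' @return Manifest tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  tibble::as_tibble(jsonlite::fromJSON(path))
}
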