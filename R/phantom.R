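#' Parameters of the synthetic bilateral-breast DCE-MRI phantom
#'
#' Collects and validates every knob of the phantom generator. Defaults emulate
#' a desk-scale early-phase breast DCE-MRI acquisition: a 64^3 grid at 1 mm
#' isotropic spacing, an FGT volume fraction of 10% of the breast (the cohort
#' mean quantitative FGT), a moderate enhancing fraction, a smooth
#' multiplicative bias field peaking 30% from unity, 2 mm of inter-scan
#' translation and additive noise at 3% of the mean FGT intensity.
#'
#' @param grid_shape integer length-3, voxels per axis (each >= 8).
#' @param spacing mm per voxel along each axis, all > 0.
#' @param fgt_fraction target V_FGT / V_Breast in [0, 1].
#' @param enhancing_fraction target fraction of FGT voxels whose true
#'   enhancement ratio is `enhancement_ratio_high` (i.e. at or above the 20%
#'   threshold), in [0, 1].
#' @param enhancement_ratio_low,enhancement_ratio_high true post/pre relative
#'   enhancement assigned to non-enhancing and enhancing FGT voxels;
#'   `high > low >= 0`.
#' @param bias_amplitude peak multiplicative deviation of the bias field from
#'   1 (0 disables it).
#' @param motion_translation mm per axis of rigid translation applied to the
#'   post-contrast volume only.
#' @param noise_sigma additive Gaussian noise scale, relative to the mean FGT
#'   intensity.
#' @param fat_intensity,fgt_intensity pre-contrast tissue levels. The default
#'   fat-bright / FGT-darker contrast is configurable; the segmentation
#'   polarity flag must match (see [segment_fgt()]).
#' @param seed integer RNG seed; a fixed seed gives byte-identical volumes.
#' @return a validated list of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(64, 64, 64),
                           spacing = c(1, 1, 1),
                           fgt_fraction = 0.10,
                           enhancing_fraction = 0.5,
                           enhancement_ratio_low = 0.05,
                           enhancement_ratio_high = 0.5,
                           bias_amplitude = 0.3,
                           motion_translation = c(2, 0, 0),
                           noise_sigma = 0.03,
                           fat_intensity = 400,
                           fgt_intensity = 150,
                           seed = 1L) {
  p <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
            fgt_fraction = fgt_fraction, enhancing_fraction = enhancing_fraction,
            enhancement_ratio_low = enhancement_ratio_low,
            enhancement_ratio_high = enhancement_ratio_high,
            bias_amplitude = bias_amplitude,
            motion_translation = as.numeric(motion_translation),
            noise_sigma = noise_sigma,
            fat_intensity = fat_intensity, fgt_intensity = fgt_intensity,
            seed = as.integer(seed))
  if (length(p$grid_shape) != 3L || any(p$grid_shape < 8L)) {
    stop("degenerate grid: every axis needs at least 8 voxels", call. = FALSE)
  }
  if (length(p$spacing) != 3L || any(p$spacing <= 0)) {
    stop("spacing must be strictly positive on all axes", call. = FALSE)
  }
  for (f in c("fgt_fraction", "enhancing_fraction")) {
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]", call. = FALSE)
  }
  if (p$enhancement_ratio_low < 0 ||
      p$enhancement_ratio_high <= p$enhancement_ratio_low) {
    stop("need enhancement_ratio_high > enhancement_ratio_low >= 0",
         call. = FALSE)
  }
  if (p$noise_sigma < 0 || p$bias_amplitude < 0) {
    stop("noise_sigma and bias_amplitude must be non-negative", call. = FALSE)
  }
  class(p) <- "phantom_params"
  p
}

#' Generate a synthetic pre/post-contrast breast volume pair with ground truth
#'
#' Builds two half-ellipsoidal breasts against a planar chest wall on an axial
#' grid. FGT is carved out of the breast as spatially correlated blobs
#' (smoothed-noise quantile thresholding, so the realised volume fraction hits
#' the target exactly); enhancing FGT voxels are selected the same way within
#' FGT. The noise-free construction is `post = pre * (1 + ratio_true)`
#' voxel-wise; a smooth multiplicative bias field is then applied to both
#' volumes, rigid translation to the post volume only, and Gaussian noise last.
#'
#' @param params a [phantom_params()] object.
#' @return a list with elements `pre` and `post` ([volume_grid()]s) and
#'   `truth`, itself a list carrying `breast_mask_true`, `fgt_mask_true`,
#'   `ratio_true`, `bias_field_true`, `chest_wall_y` (the planar wall's voxel
#'   coordinate along axis 2; breast is at lower coordinates), and the exact
#'   scalars `bpe20_true` and `fgt_pct_true` (percent).
#' @examples
#' ph <- generate_phantom(phantom_params(grid_shape = c(16, 16, 16), seed = 1))
#' ph$truth$bpe20_true
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  d <- p$grid_shape
  set.seed(p$seed)

  g <- expand_grid_idx(d)
  # planar chest wall at 72% depth along axis 2; breast anterior (lower y)
  y_wall <- 0.72 * d[2]
  # lateral margin keeps the breasts inside the field of view even after the
  # simulated inter-scan motion
  cx <- c(0.28, 0.72) * d[1]
  rx <- 0.22 * d[1]; ry <- 0.62 * y_wall; rz <- 0.42 * d[3]
  cz <- 0.5 * d[3]
  inside <- rep(FALSE, prod(d))
  for (c1 in cx) {
    e <- ((g$x - c1) / rx)^2 + ((g$y - y_wall) / ry)^2 + ((g$z - cz) / rz)^2
    inside <- inside | (e <= 1 & g$y <= y_wall)
  }
  breast <- array(inside, d)
  n_breast <- sum(breast)

  # FGT blobs: smoothed white noise, top fgt_fraction quantile inside breast
  fgt <- array(FALSE, d)
  n_fgt <- round(p$fgt_fraction * n_breast)
  if (n_fgt > 0) {
    field <- gauss_smooth3(array(stats::rnorm(prod(d)), d),
                           sigma = 0.06 * mean(d))
    vals <- field[breast]
    cut <- sort(vals, decreasing = TRUE)[n_fgt]
    sel <- breast & field >= cut
    # ties at the cut could overshoot; trim deterministically
    if (sum(sel) > n_fgt) {
      idx <- which(sel)
      sel[idx[order(field[idx], decreasing = TRUE)][-seq_len(n_fgt)]] <- FALSE
    }
    fgt <- sel
  }
  n_fgt <- sum(fgt)

  # enhancing blobs within FGT, exact count by quantile selection
  n_enh <- round(p$enhancing_fraction * n_fgt)
  if (p$enhancing_fraction > 0 && n_fgt == 0) {
    stop("enhancing_fraction unreachable: phantom has no FGT voxels",
         call. = FALSE)
  }
  enh <- array(FALSE, d)
  if (n_enh > 0) {
    field2 <- gauss_smooth3(array(stats::rnorm(prod(d)), d),
                            sigma = 0.04 * mean(d))
    idx <- which(fgt)
    ord <- idx[order(field2[idx], decreasing = TRUE)]
    enh[ord[seq_len(n_enh)]] <- TRUE
  }

  ratio_true <- array(0, d)
  ratio_true[breast & !fgt] <- p$enhancement_ratio_low
  ratio_true[fgt] <- p$enhancement_ratio_low
  ratio_true[enh] <- p$enhancement_ratio_high

  pre0 <- array(0, d)
  pre0[breast] <- p$fat_intensity
  pre0[fgt] <- p$fgt_intensity
  post0 <- pre0 * (1 + ratio_true)

  # smooth multiplicative bias: random quadratic in normalised coords,
  # peak |deviation| = bias_amplitude; identical field on pre and post
  bias <- array(1, d)
  if (p$bias_amplitude > 0) {
    xn <- (g$x - 1) / (d[1] - 1) - 0.5
    yn <- (g$y - 1) / (d[2] - 1) - 0.5
    zn <- (g$z - 1) / (d[3] - 1) - 0.5
    cf <- stats::rnorm(9)
    f <- cf[1] * xn + cf[2] * yn + cf[3] * zn + cf[4] * xn * yn +
         cf[5] * xn * zn + cf[6] * yn * zn + cf[7] * xn^2 + cf[8] * yn^2 +
         cf[9] * zn^2
    f <- f / max(abs(f))
    bias <- array(1 + p$bias_amplitude * f, d)
  }
  pre_b <- pre0 * bias
  post_b <- post0 * bias

  # rigid translation of the post volume only (mm -> voxels)
  shift_vox <- p$motion_translation / p$spacing
  post_m <- if (any(shift_vox != 0)) shift_array(post_b, shift_vox) else post_b

  sigma_abs <- p$noise_sigma * p$fgt_intensity
  if (sigma_abs > 0) {
    pre_b <- pre_b + array(stats::rnorm(prod(d), sd = sigma_abs), d)
    post_m <- post_m + array(stats::rnorm(prod(d), sd = sigma_abs), d)
  }
  pre_b <- pmax(pre_b, 0)
  post_m <- pmax(post_m, 0)

  bpe20_true <- if (n_fgt > 0) 100 * sum(ratio_true[fgt] >= 0.20) / n_fgt else 0
  truth <- list(breast_mask_true = breast, fgt_mask_true = fgt,
                ratio_true = ratio_true, bias_field_true = bias,
                chest_wall_y = y_wall,
                bpe20_true = bpe20_true,
                fgt_pct_true = if (n_breast > 0) 100 * n_fgt / n_breast else 0)
  list(pre = volume_grid(pre_b, p$spacing),
       post = volume_grid(post_m, p$spacing),
       truth = truth, params = p)
}

#' Write a phantom to disk as NIfTI volumes plus a JSON manifest
#'
#' Emits `pre.nii.gz`, `post.nii.gz`, `breast_mask.nii.gz`, `fgt_mask.nii.gz`,
#' `ratio_true.nii.gz` and `manifest.json` (parameters, seed and the truth
#' scalars) into `directory`. Round-trips losslessly through [read_volume()]
#' up to float precision.
#'
#' @param phantom result of [generate_phantom()].
#' @param directory output directory, created if absent.
#' @return path of the manifest file, invisibly.
#' @export
write_phantom <- function(phantom, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  sp <- phantom$params$spacing
  paths <- list(
    pre = file.path(directory, "pre.nii.gz"),
    post = file.path(directory, "post.nii.gz"),
    breast_mask = file.path(directory, "breast_mask.nii.gz"),
    fgt_mask = file.path(directory, "fgt_mask.nii.gz"),
    ratio_true = file.path(directory, "ratio_true.nii.gz"))
  write_volume(phantom$pre, paths$pre)
  write_volume(phantom$post, paths$post)
  write_volume(volume_grid(phantom$truth$breast_mask_true * 1, sp),
               paths$breast_mask)
  write_volume(volume_grid(phantom$truth$fgt_mask_true * 1, sp),
               paths$fgt_mask)
  write_volume(volume_grid(phantom$truth$ratio_true, sp), paths$ratio_true)
  manifest <- list(
    params = unclass(phantom$params),
    seed = phantom$params$seed,
    truth = list(bpe20_true = phantom$truth$bpe20_true,
                 fgt_pct_true = phantom$truth$fgt_pct_true,
                 chest_wall_y = phantom$truth$chest_wall_y),
    files = lapply(paths, basename))
  mpath <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}
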