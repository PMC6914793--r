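#' Voxel-wise relative enhancement ratio map
#'
#' For each voxel the enhancement ratio is the subtracted early-phase intensity
#' over the pre-contrast intensity, `(I_post - I_pre) / I_pre`. Fat-suppressed
#' images contain near-zero pre-contrast voxels where this ratio explodes, so
#' voxels with `I_pre <= floor` are marked invalid rather than emitted as
#' non-finite values.
#'
#' @param pre pre-contrast [volume_grid()].
#' @param post_warped post-contrast volume already registered onto the
#'   pre-contrast grid.
#' @param floor intensity floor (>= 0) below which the ratio is undefined.
#'   Default `NULL` applies 1% of the median positive pre-contrast intensity;
#'   pass a `mask` to take the median in-mask.
#' @param mask optional logical array restricting the median used by the
#'   default floor (typically the breast mask).
#' @return list of class `enhancement_map`: `ratio` (array, 0 where invalid),
#'   `valid` (logical array), `floor`.
#' @examples
#' pre <- volume_grid(array(100, c(8, 8, 8)))
#' post <- volume_grid(array(130, c(8, 8, 8)))
#' em <- enhancement_ratio_map(pre, post)
#' em$ratio[1, 1, 1]  # 0.30
#' @export
enhancement_ratio_map <- function(pre, post_warped, floor = NULL, mask = NULL) {
  stopifnot(inherits(pre, "volume_grid"), inherits(post_warped, "volume_grid"))
  stopifnot_same_grid(pre, post_warped)
  if (is.null(floor)) {
    ref <- if (is.null(mask)) pre$data else pre$data[as.logical(mask)]
    ref <- ref[ref > 0]
    floor <- if (length(ref)) 0.01 * stats::median(ref) else 0
  }
  if (floor < 0) stop("floor must be non-negative", call. = FALSE)
  valid <- pre$data > floor
  ratio <- array(0, dim(pre$data))
  ratio[valid] <- (post_warped$data[valid] - pre$data[valid]) / pre$data[valid]
  structure(list(ratio = ratio, valid = valid, floor = floor),
            class = "enhancement_map")
}

#' BPE20%: thresholded enhancing volume over the FGT region
#'
#' Computes the component volumes and the two headline percentages of the
#' quantification:
#' `FGT% = V_FGT / V_Breast * 100` and `BPE20% = V_BPE / V_FGT * 100`, where
#' `V_BPE` sums the voxel volume over FGT voxels whose enhancement ratio is at
#' or above the threshold (inclusive) and is valid. FGT voxels with an
#' undefined ratio are counted in `n_invalid` and, by default, removed from
#' both the numerator and the denominator of BPE20%.
#'
#' @param map an [enhancement_ratio_map()] result.
#' @param masks a `segmentation_masks` object (or a list with `breast_mask`
#'   and `fgt_mask` logical arrays on the map's grid).
#' @param spacing mm per voxel, length 3.
#' @param threshold enhancement-ratio threshold, default 0.20 (inclusive).
#' @param denominator `"valid"` (default: valid FGT voxels) or `"all"` (all
#'   FGT voxels).
#' @return a one-row [tibble::tibble()] of class `bpe_result` with columns
#'   `v_breast`, `v_fgt`, `v_bpe` (mm^3), `fgt_pct`, `bpe20_pct`, `threshold`,
#'   `n_invalid`.
#' @export
compute_bpe <- function(map, masks, spacing, threshold = 0.20,
                        denominator = c("valid", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(map, "enhancement_map"))
  fgt <- as.logical(masks$fgt_mask); dim(fgt) <- dim(map$ratio)
  breast <- as.logical(masks$breast_mask); dim(breast) <- dim(map$ratio)
  vv <- voxel_volume(spacing)
  n_fgt <- sum(fgt)
  if (n_fgt == 0) {
    stop("empty FGT mask (v_fgt = 0): BPE20% undefined", call. = FALSE)
  }
  fgt_valid <- fgt & map$valid
  n_invalid <- n_fgt - sum(fgt_valid)
  n_bpe <- sum(fgt_valid & map$ratio >= threshold)
  n_denom <- if (denominator == "valid") sum(fgt_valid) else n_fgt
  if (n_denom == 0) {
    stop("no valid FGT voxels: every FGT voxel is below the intensity floor",
         call. = FALSE)
  }
  v_breast <- sum(breast) * vv
  v_fgt <- n_denom * vv
  v_bpe <- n_bpe * vv
  res <- tibble::tibble(
    v_breast = v_breast, v_fgt = v_fgt, v_bpe = v_bpe,
    fgt_pct = sum(fgt) * vv / v_breast * 100,
    bpe20_pct = v_bpe / v_fgt * 100,
    threshold = threshold, n_invalid = n_invalid)
  class(res) <- c("bpe_result", class(res))
  res
}

#' FGT volume fraction of the breast, in percent
#'
#' `FGT% = V_FGT / V_Breast * 100`; with a fixed voxel grid the spacing cancels
#' and the percentage reduces to a voxel-count ratio.
#'
#' @param masks `segmentation_masks` (or list with `breast_mask`, `fgt_mask`).
#' @param spacing mm per voxel, length 3.
#' @return scalar percent.
#' @export
compute_fgt_pct <- function(masks, spacing) {
  breast <- as.logical(masks$breast_mask)
  fgt <- as.logical(masks$fgt_mask)
  if (!any(breast)) stop("breast mask is empty", call. = FALSE)
  vv <- voxel_volume(spacing)
  sum(fgt) * vv / (sum(breast) * vv) * 100
}

#' Intrasubject change in BPE20% between two timepoints
#'
#' `dBPE20% = (BPE20%_post - BPE20%_pre) / BPE20%_pre * 100`; negative values
#' are decreases. Undefined when the pre-therapy BPE20% is zero.
#'
#' @param pre,post `bpe_result` rows (or any list with `bpe20_pct`) for the
#'   pre- and post-therapy studies.
#' @return a one-row tibble with `bpe20_pre`, `bpe20_post`, `delta_pct`.
#' @export
delta_bpe <- function(pre, post) {
  b0 <- pre$bpe20_pct; b1 <- post$bpe20_pct
  if (!is.finite(b0) || b0 <= 0) {
    stop("pre-therapy BPE20% is zero: intrasubject change undefined",
         call. = FALSE)
  }
  tibble::tibble(bpe20_pre = b0, bpe20_post = b1,
                 delta_pct = (b1 - b0) / b0 * 100)
}

#' Plot an axial slice of an enhancement-ratio map
#'
#' @param object an `enhancement_map`.
#' @param slice axial slice index (default: middle).
#' @param threshold ratio threshold to outline (default 0.20).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.enhancement_map <- function(object, slice = NULL, threshold = 0.20,
                                     ...) {
  d <- dim(object$ratio)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$ratio <- as.vector(object$ratio[, , slice])
  df$ratio[!as.vector(object$valid[, , slice])] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$ratio)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = "R") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Enhancement ratio, slice %d (threshold %.2f)",
                                  slice, threshold)) +
    ggplot2::theme_minimal()
}
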