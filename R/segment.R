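#' Chest-wall specification
#'
#' The chest-wall delimitation is supervised: the operator supplies either an
#' explicit exclusion mask (voxels posterior to the wall) or control points on
#' the wall surface in physical coordinates (mm). From control points a smooth
#' surface `y = f(x, z)` is fitted (polynomial least squares) along the
#' anterior-posterior axis (axis 2; smaller coordinate = anterior), and the
#' grid is partitioned gap-free into an anterior breast region and a posterior
#' excluded region.
#'
#' @param exclusion_mask logical array marking voxels to exclude (posterior),
#'   or `NULL`.
#' @param control_points data frame / matrix with columns `x`, `y`, `z`
#'   (physical mm), or `NULL`.
#' @param surface_order polynomial degree of the fitted surface (default 2).
#' @return an object of class `chest_wall_spec`.
#' @export
chest_wall_spec <- function(exclusion_mask = NULL, control_points = NULL,
                            surface_order = 2) {
  if (is.null(exclusion_mask) && is.null(control_points)) {
    stop("supply either an exclusion mask or control points", call. = FALSE)
  }
  if (!is.null(control_points)) {
    control_points <- as.data.frame(control_points)
    if (!all(c("x", "y", "z") %in% names(control_points))) {
      stop("control points need columns x, y, z (physical mm)", call. = FALSE)
    }
    n_coef <- (surface_order + 1) * (surface_order + 2) / 2
    if (nrow(control_points) < n_coef) {
      stop(sprintf("need at least %d control points for a degree-%d surface, got %d",
                   n_coef, surface_order, nrow(control_points)), call. = FALSE)
    }
  }
  structure(list(exclusion_mask = exclusion_mask,
                 control_points = control_points,
                 surface_order = surface_order),
            class = "chest_wall_spec")
}

#' Build the breast mask from a chest-wall delimitation
#'
#' Intersects the region anterior to the chest wall with body voxels (intensity
#' above a background-air threshold) and removes an optional tumor mask, since
#' FGT and BPE are quantified over the non-tumor breast.
#'
#' @param volume pre-contrast [volume_grid()].
#' @param chest a [chest_wall_spec()].
#' @param background_quantile air/body intensity cut as a fraction of the 99th
#'   percentile in-volume intensity (default 0.1).
#' @param tumor_mask optional logical array of tumor voxels to exclude.
#' @return logical array: the breast mask.
#' @export
build_breast_mask <- function(volume, chest, background_quantile = 0.1,
                              tumor_mask = NULL) {
  stopifnot(inherits(volume, "volume_grid"), inherits(chest, "chest_wall_spec"))
  d <- dim(volume$data)
  if (!is.null(chest$exclusion_mask)) {
    excl <- as.logical(chest$exclusion_mask)
    dim(excl) <- d
    anterior <- !excl
  } else {
    cp <- chest$control_points
    sp <- volume$spacing
    # fit y = f(x, z) in physical mm
    xs <- cp$x; zs <- cp$z
    X <- surf_basis(xs, zs, chest$surface_order)
    coef <- stats::lm.fit(X, cp$y)$coefficients
    coef[is.na(coef)] <- 0
    g <- expand_grid_idx(d)
    xw <- g$x * sp[1]; zw <- g$z * sp[3]
    ywall <- as.numeric(surf_basis(xw, zw, chest$surface_order) %*% coef)
    anterior <- array(g$y * sp[2] <= ywall, d)
  }
  thr <- background_quantile * stats::quantile(volume$data, 0.99, names = FALSE)
  body <- volume$data > thr
  mask <- anterior & body
  if (!is.null(tumor_mask)) {
    tm <- as.logical(tumor_mask); dim(tm) <- d
    mask <- mask & !tm
  }
  if (!any(mask)) {
    stop("empty breast mask: no body voxels anterior to the chest wall",
         call. = FALSE)
  }
  mask
}

surf_basis <- function(x, z, order) {
  cols <- list(rep(1, length(x)))
  for (i in 0:order) for (j in 0:(order - i)) {
    if (i + j == 0) next
    cols[[length(cols) + 1L]] <- x^i * z^j
  }
  do.call(cbind, cols)
}

#' Fuzzy C-means clustering of a 1-D intensity sample
#'
#' Standard FCM fixed-point iteration: memberships
#' `u_ij = (1/d_ij^2)^(1/(m-1))`, row-normalised, and centers as
#' `u^m`-weighted means; the objective `sum u^m d^2` is non-increasing per
#' iteration. A value exactly at a center receives membership 1 for that
#' cluster (singularity rule). Initialisation is deterministic: centers start
#' at the `(i - 0.5)/k` quantiles of the sample.
#'
#' @param values numeric vector (at least `k` distinct values).
#' @param k number of clusters (>= 2).
#' @param m fuzzifier (> 1; default 2).
#' @param tol convergence tolerance on maximal center movement (default 1e-5,
#'   relative to the data range).
#' @param max_iter iteration cap (default 300).
#' @return list with `centers` (ascending), `memberships` (n x k matrix,
#'   columns ordered by center), `objective` (per-iteration trace),
#'   `iterations`, `converged`.
#' @examples
#' fz <- fuzzy_cmeans(c(0, 0, 0, 10, 10, 10), k = 2)
#' fz$centers
#' @export
fuzzy_cmeans <- function(values, k = 2, m = 2, tol = 1e-5, max_iter = 300) {
  values <- as.numeric(values)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must exceed 1", call. = FALSE)
  if (length(unique(values)) < k) {
    stop("need at least k distinct values to form k clusters", call. = FALSE)
  }
  rng <- diff(range(values))
  centers <- stats::quantile(values, (seq_len(k) - 0.5) / k, names = FALSE)
  if (length(unique(centers)) < k) {
    # heavily skewed class sizes can collapse the quantile init; spread instead
    centers <- seq(min(values), max(values), length.out = k)
  }
  n <- length(values)
  obj <- numeric(0)
  converged <- FALSE
  U <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(values, centers, function(v, c) (v - c)^2)
    U <- matrix(0, n, k)
    zero <- d2 < .Machine$double.eps
    has_zero <- rowSums(zero) > 0
    if (any(has_zero)) {
      U[has_zero, ] <- zero[has_zero, , drop = FALSE] /
        rowSums(zero[has_zero, , drop = FALSE])
    }
    if (any(!has_zero)) {
      w <- (1 / d2[!has_zero, , drop = FALSE])^(1 / (m - 1))
      U[!has_zero, ] <- w / rowSums(w)
    }
    obj <- c(obj, sum(U^m * d2))
    um <- U^m
    new_centers <- colSums(um * values) / colSums(um)
    delta <- max(abs(new_centers - centers))
    centers <- new_centers
    if (delta < tol * max(rng, .Machine$double.eps)) {converged <- TRUE; break}
  }
  if (!converged) {
    warning(sprintf("fuzzy c-means did not converge in %d iterations (last objective delta %.3g)",
                    max_iter, if (length(obj) > 1) diff(utils::tail(obj, 2)) else NA_real_))
  }
  ord <- order(centers)
  list(centers = centers[ord], memberships = U[, ord, drop = FALSE],
       objective = obj, iterations = length(obj), converged = converged)
}

#' Segment fibroglandular tissue within the breast mask
#'
#' Two-class fuzzy C-means on the (bias-corrected) in-mask pre-contrast
#' intensities, followed by membership thresholding. Which intensity class is
#' FGT depends on the acquisition contrast: under the default fat-bright
#' convention FGT is the darker class (`fgt_polarity = "darker"`); set
#' `"brighter"` when fat suppression leaves FGT as the brighter class. The
#' binary FGT mask is `membership >= cutoff` (default 0.5). Segmentation is
#' invariant to global intensity scaling.
#'
#' @param volume pre-contrast, bias-corrected [volume_grid()].
#' @param breast_mask logical array (the result of [build_breast_mask()]).
#' @param fgt_polarity `"darker"` (default) or `"brighter"`.
#' @param cutoff membership binarisation threshold in (0, 1), default 0.5.
#' @param min_mask_voxels minimum breast-mask size accepted (default 100).
#' @param min_separation minimum |center difference| relative to the mean
#'   in-mask intensity below which the two classes are declared degenerate
#'   (default 0.05): a homogeneous breast raises an error rather than being
#'   split arbitrarily.
#' @param ... passed to [fuzzy_cmeans()] (`m`, `tol`, `max_iter`).
#' @return list of class `segmentation_masks`: `breast_mask`, `fgt_mask`,
#'   `memberships` (array; FGT membership, `NA` outside the breast mask),
#'   `centers`, `cutoff`.
#' @export
segment_fgt <- function(volume, breast_mask, fgt_polarity = c("darker", "brighter"),
                        cutoff = 0.5, min_mask_voxels = 100,
                        min_separation = 0.05, ...) {
  fgt_polarity <- match.arg(fgt_polarity)
  stopifnot(inherits(volume, "volume_grid"))
  breast_mask <- as.logical(breast_mask)
  dim(breast_mask) <- dim(volume$data)
  n_in <- sum(breast_mask)
  if (n_in < min_mask_voxels) {
    stop(sprintf("breast mask has %d voxels; at least %d required",
                 n_in, min_mask_voxels), call. = FALSE)
  }
  vals <- volume$data[breast_mask]
  fz <- fuzzy_cmeans(vals, k = 2, ...)
  sep <- abs(diff(fz$centers)) / max(mean(abs(vals)), .Machine$double.eps)
  if (sep < min_separation) {
    stop(sprintf(
      "degenerate tissue classes: centers %.4g and %.4g are not separable (relative separation %.3g)",
      fz$centers[1], fz$centers[2], sep), call. = FALSE)
  }
  fgt_col <- if (fgt_polarity == "darker") 1L else 2L
  u_fgt <- fz$memberships[, fgt_col]
  memb <- array(NA_real_, dim(volume$data))
  memb[breast_mask] <- u_fgt
  fgt_mask <- array(FALSE, dim(volume$data))
  fgt_mask[breast_mask] <- u_fgt >= cutoff
  structure(list(breast_mask = breast_mask, fgt_mask = fgt_mask,
                 memberships = memb, centers = fz$centers, cutoff = cutoff),
            class = "segmentation_masks")
}

#' @export
print.segmentation_masks <- function(x, ...) {
  cat("<segmentation_masks> breast: ", sum(x$breast_mask), " voxels; FGT: ",
      sum(x$fgt_mask), " voxels (", signif(100 * sum(x$fgt_mask) /
      sum(x$breast_mask), 4), "% of breast)\n", sep = "")
  invisible(x)
}
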