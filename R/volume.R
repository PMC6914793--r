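#' 3-D volume grid
#'
#' The unit every pipeline stage consumes and produces: a 3-D scalar intensity
#' array together with its physical voxel spacing in millimetres. Voxel indices
#' are 1-based in R; physical coordinates follow index * spacing along each
#' axis (a diagonal NIfTI affine). All masks and maps produced by the pipeline
#' live on the pre-contrast grid.
#'
#' @param data numeric 3-D array of intensities (finite).
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @return An object of class `volume_grid`: a list with elements `data` and
#'   `spacing`.
#' @examples
#' v <- volume_grid(array(runif(8^3), c(8, 8, 8)), spacing = c(1, 1, 2))
#' voxel_volume(v)  # mm^3 per voxel
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive numbers (mm)", call. = FALSE)
  }
  if (any(!is.finite(data))) stop("intensities must be finite", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  rng <- range(x$data)
  cat("  intensity range [", signif(rng[1], 5), ", ", signif(rng[2], 5), "]\n",
      sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' Volume of one voxel in mm^3
#' @param volume a `volume_grid` (or a numeric length-3 spacing vector).
#' @return scalar, product of the spacing components.
#' @export
voxel_volume <- function(volume) {
  sp <- if (inherits(volume, "volume_grid")) volume$spacing else as.numeric(volume)
  prod(sp)
}

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-8) {
    stop("volumes are not on the same grid (shape/spacing mismatch)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' @param path path to a .nii or .nii.gz file.
#' @return a [volume_grid()] with spacing taken from the header pixdim.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  volume_grid(array(as.numeric(img), dim(img)[1:3]), spacing = sp[1:3])
}

#' Write a NIfTI volume
#'
#' @param volume a [volume_grid()] (logical arrays are written as 0/1).
#' @param path output .nii or .nii.gz path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_grid"))
  img <- RNifti::asNifti(volume$data, pixdim = volume$spacing)
  ok <- tryCatch({RNifti::writeNifti(img, path); TRUE},
                 error = function(e) FALSE)
  if (!ok || !file.exists(path)) {
    stop("failed to write NIfTI volume to ", path, call. = FALSE)
  }
  invisible(path)
}

## ---- numeric helpers shared by phantom / preprocess -----------------------

#' Trilinear interpolation of a 3-D array at fractional voxel coordinates
#'
#' Samples `arr` at (possibly fractional) 1-based voxel coordinates; points
#' outside the grid take `fill`.
#'
#' @param arr 3-D numeric array.
#' @param xi,yi,zi equal-length numeric vectors of 1-based voxel coordinates.
#' @param fill value used outside the array extent.
#' @return numeric vector of sampled values.
#' @keywords internal
interp_trilinear <- function(arr, xi, yi, zi, fill = 0) {
  d <- dim(arr)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  out <- numeric(length(xi))
  inside <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  out[!inside] <- fill
  if (!any(inside)) return(out)
  x0 <- pmin(pmax(x0[inside], 1L), d[1] - 1L)
  y0 <- pmin(pmax(y0[inside], 1L), d[2] - 1L)
  z0 <- pmin(pmax(z0[inside], 1L), d[3] - 1L)
  fx <- xi[inside] - x0; fy <- yi[inside] - y0; fz <- zi[inside] - z0
  idx <- function(i, j, k) arr[cbind(i, j, k)]
  v <- idx(x0,     y0,     z0    ) * (1 - fx) * (1 - fy) * (1 - fz) +
       idx(x0 + 1, y0,     z0    ) * fx       * (1 - fy) * (1 - fz) +
       idx(x0,     y0 + 1, z0    ) * (1 - fx) * fy       * (1 - fz) +
       idx(x0 + 1, y0 + 1, z0    ) * fx       * fy       * (1 - fz) +
       idx(x0,     y0,     z0 + 1) * (1 - fx) * (1 - fy) * fz       +
       idx(x0 + 1, y0,     z0 + 1) * fx       * (1 - fy) * fz       +
       idx(x0,     y0 + 1, z0 + 1) * (1 - fx) * fy       * fz       +
       idx(x0 + 1, y0 + 1, z0 + 1) * fx       * fy       * fz
  out[inside] <- v
  out
}

#' Shift a 3-D array by a (fractional) voxel translation
#'
#' Returns `out[x] = arr[x - shift_vox]` with trilinear interpolation, i.e. the
#' array content moves by `+shift_vox`.
#' @keywords internal
shift_array <- function(arr, shift_vox, fill = 0) {
  d <- dim(arr)
  g <- expand_grid_idx(d)
  vals <- interp_trilinear(arr, g$x - shift_vox[1], g$y - shift_vox[2],
                           g$z - shift_vox[3], fill = fill)
  array(vals, d)
}

expand_grid_idx <- function(d) {
  list(x = rep(seq_len(d[1]), times = d[2] * d[3]),
       y = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
       z = rep(seq_len(d[3]), each = d[1] * d[2]))
}

#' Separable 3-D Gaussian smoothing
#'
#' Convolves along each axis with a truncated, renormalised Gaussian kernel
#' (reflecting edge handling via kernel renormalisation). Used for the
#' phantom's spatially correlated blobs and the demons displacement smoother.
#'
#' @param arr 3-D numeric array.
#' @param sigma standard deviation in voxels, scalar or length-3.
#' @return smoothed array of the same dimension.
#' @keywords internal
gauss_smooth3 <- function(arr, sigma) {
  sigma <- rep(as.numeric(sigma), length.out = 3)
  d <- dim(arr)
  conv_axis <- function(a, axis) {
    s <- sigma[axis]
    if (s <= 0) return(a)
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    n <- d[axis]
    # dense band matrix: column j holds kernel centred at j, renormalised at edges
    K <- matrix(0, n, n)
    for (j in seq_len(n)) {
      lo <- max(1L, j - r); hi <- min(n, j + r)
      w <- k[(lo - j + r + 1L):(hi - j + r + 1L)]
      K[lo:hi, j] <- w / sum(w)
    }
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = d[axis])
    res <- K %*% m
    ap2 <- array(res, dim(ap))
    aperm(ap2, order(perm))
  }
  for (ax in 1:3) arr <- conv_axis(arr, ax)
  arr
}

#' Dice overlap coefficient between two masks
#' @param a,b logical arrays of equal dimension.
#' @return scalar in [0, 1]; `NaN` when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  2 * sum(a & b) / (sum(a) + sum(b))
}
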