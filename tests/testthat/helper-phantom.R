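# Shared fixtures: phantoms are generated in code at test time.

# Small fast phantom for unit tests (32^3 unless a test needs 64^3).
make_phantom <- function(seed = 1, grid = c(32, 32, 32), ...) {
  generate_phantom(phantom_params(grid_shape = grid, seed = seed, ...))
}

# Chest-wall control points sampled from the phantom's true planar wall.
true_chest_spec <- function(phantom) {
  p <- phantom$params
  d <- p$grid_shape
  cp <- expand.grid(x = seq(2, d[1] - 2, length.out = 6) * p$spacing[1],
                    z = seq(2, d[3] - 2, length.out = 6) * p$spacing[3])
  cp$y <- phantom$truth$chest_wall_y * p$spacing[2]
  chest_wall_spec(control_points = cp)
}

# Brute-force voxel-loop oracle for the volume metrics: plain loops, no
# vectorised shortcuts, independent of the implementation under test.
bpe_bruteforce <- function(ratio, valid, breast, fgt, spacing, threshold) {
  d <- dim(ratio)
  vv <- prod(spacing)
  v_breast <- 0; n_fgt <- 0; n_valid <- 0; n_bpe <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (breast[i, j, k]) v_breast <- v_breast + vv
    if (fgt[i, j, k]) {
      n_fgt <- n_fgt + 1
      if (valid[i, j, k]) {
        n_valid <- n_valid + 1
        if (ratio[i, j, k] >= threshold) n_bpe <- n_bpe + 1
      }
    }
  }
  list(v_breast = v_breast,
       fgt_pct = n_fgt * vv / v_breast * 100,
       bpe20_pct = if (n_valid > 0) 100 * n_bpe / n_valid else NA_real_,
       v_bpe = n_bpe * vv, n_invalid = n_fgt - n_valid)
}

# Exhaustive two-class hard-threshold oracle: the split of sorted values that
# minimises total within-class variance (k-means objective for k = 2 in 1-D).
best_two_class_split <- function(values) {
  v <- sort(values)
  n <- length(v)
  best <- Inf; cut <- NA
  for (s in 1:(n - 1)) {
    a <- v[1:s]; b <- v[(s + 1):n]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best) {best <- ss; cut <- (v[s] + v[s + 1]) / 2}
  }
  cut
}
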