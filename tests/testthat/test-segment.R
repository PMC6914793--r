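test_that("an explicit exclusion mask passes through to the breast mask", {
  ph <- make_phantom(seed = 21, noise_sigma = 0)
  d <- dim(ph$pre$data)
  excl <- array(FALSE, d)
  excl[, 24:d[2], ] <- TRUE    # exclude everything at/behind the wall
  mask <- build_breast_mask(ph$pre, chest_wall_spec(exclusion_mask = excl))
  body <- ph$pre$data > 0.1 * stats::quantile(ph$pre$data, 0.99)
  expect_identical(mask, !excl & body)
})

test_that("control points on the true wall give a near-perfect breast mask", {
  ph <- make_phantom(seed = 21, noise_sigma = 0.03)
  mask <- build_breast_mask(ph$pre, true_chest_spec(ph))
  expect_gte(dice_coefficient(mask, ph$truth$breast_mask_true), 0.98)
})

test_that("degenerate chest-wall input is rejected", {
  ph <- make_phantom(seed = 21)
  # too few control points for the requested surface
  expect_error(chest_wall_spec(control_points = data.frame(x = 1, y = 1, z = 1)),
               "at least")
  # everything excluded -> error, not an empty mask
  d <- dim(ph$pre$data)
  expect_error(build_breast_mask(ph$pre,
                                 chest_wall_spec(exclusion_mask = array(TRUE, d))),
               "empty breast mask")
  # tumor exclusion removes the given voxels
  tm <- array(FALSE, d); tm[10:12, 10:12, 10:12] <- TRUE
  m0 <- build_breast_mask(ph$pre, true_chest_spec(ph))
  m1 <- build_breast_mask(ph$pre, true_chest_spec(ph), tumor_mask = tm)
  expect_identical(m1, m0 & !tm)
})

test_that("fuzzy C-means solves the symmetric two-point problem", {
  fz <- fuzzy_cmeans(c(0, 0, 0, 10, 10, 10), k = 2)
  expect_equal(fz$centers, c(0, 10), tolerance = 1e-6)
  expect_true(all(fz$memberships[1:3, 1] >= 0.99))
  expect_true(all(fz$memberships[4:6, 2] >= 0.99))
  # memberships sum to one per value
  expect_equal(rowSums(fz$memberships), rep(1, 6))
  # singularity rule: a value exactly at a center has membership 1 there
  fz2 <- suppressWarnings(fuzzy_cmeans(c(0, 0, 5, 10, 10), k = 2, max_iter = 1))
  at_center <- which(abs(c(0, 0, 5, 10, 10) - fz2$centers[1]) < 1e-12)
  expect_true(all(fz2$memberships[at_center, 1] == 1))
})

test_that("the FCM objective is non-increasing across iterations", {
  set.seed(42)
  for (rep in 1:5) {
    vals <- c(stats::rnorm(150, 0, 1), stats::rnorm(100, 4, 1.5))
    fz <- fuzzy_cmeans(vals, k = 2)
    expect_true(all(diff(fz$objective) <= 1e-9 * max(abs(fz$objective))))
  }
})

test_that("FCM near the crisp limit agrees with the optimal hard split", {
  set.seed(7)
  for (rep in 1:5) {
    vals <- c(stats::runif(30, 0, 1), stats::runif(30, 5, 6))
    fz <- fuzzy_cmeans(vals, k = 2, m = 1.05)
    cut <- best_two_class_split(vals)   # exhaustive threshold oracle
    hard_fcm <- fz$memberships[, 2] > 0.5
    expect_identical(hard_fcm, vals > cut)
  }
})

test_that("FCM input validation", {
  expect_error(fuzzy_cmeans(c(1, 1, 1), k = 2), "distinct")
  expect_error(fuzzy_cmeans(c(1, 2, 3), k = 1), "k must be")
  expect_error(fuzzy_cmeans(c(1, 2, 3), k = 2, m = 1), "fuzzifier")
})

test_that("FGT segmentation recovers truth on phantoms", {
  # noise-free: classes are exactly separable
  ph0 <- make_phantom(seed = 22, noise_sigma = 0, bias_amplitude = 0)
  seg0 <- segment_fgt(ph0$pre, ph0$truth$breast_mask_true)
  expect_equal(dice_coefficient(seg0$fgt_mask, ph0$truth$fgt_mask_true), 1.0)
  expect_true(all(seg0$fgt_mask[!seg0$breast_mask] == FALSE))

  # moderate noise after bias correction
  ph <- make_phantom(seed = 22, noise_sigma = 0.05,
                     motion_translation = c(0, 0, 0))
  m <- ph$truth$breast_mask_true
  pre_c <- correct_bias(ph$pre, m)$corrected
  seg <- segment_fgt(pre_c, m)
  expect_gte(dice_coefficient(seg$fgt_mask, ph$truth$fgt_mask_true), 0.95)

  # memberships live in [0,1] inside the mask and the cutoff defines the mask
  u <- seg$memberships[seg$breast_mask]
  expect_true(all(u >= 0 & u <= 1))
  expect_identical(seg$fgt_mask[seg$breast_mask], u >= seg$cutoff)
})

test_that("FGT segmentation is invariant to global intensity scaling", {
  ph <- make_phantom(seed = 23, noise_sigma = 0.03)
  m <- ph$truth$breast_mask_true
  seg1 <- segment_fgt(ph$pre, m)
  scaled <- volume_grid(ph$pre$data * 7.3, ph$pre$spacing)
  seg2 <- segment_fgt(scaled, m)
  expect_identical(seg1$fgt_mask, seg2$fgt_mask)
})

test_that("a homogeneous breast raises a degenerate-class error", {
  d <- c(16, 16, 16)
  v <- volume_grid(array(100 + stats::rnorm(prod(d), sd = 0.01), d))
  m <- array(TRUE, d)
  expect_error(segment_fgt(v, m), "degenerate")
  expect_error(segment_fgt(v, array(c(TRUE, rep(FALSE, prod(d) - 1)), d)),
               "voxels")
})
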