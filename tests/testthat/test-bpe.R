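mask_list <- function(breast, fgt) list(breast_mask = breast, fgt_mask = fgt)

test_that("the enhancement ratio follows its defining formula", {
  d <- c(8, 8, 8)
  pre <- volume_grid(array(100, d))
  post <- volume_grid(array(130, d))
  em <- enhancement_ratio_map(pre, post, floor = 1)
  expect_true(all(em$ratio == 0.30))
  expect_true(all(em$valid))

  # identical volumes -> ratio identically zero
  em0 <- enhancement_ratio_map(pre, pre, floor = 1)
  expect_true(all(em0$ratio == 0))

  # a zero pre-contrast voxel is invalid, never +/-Inf
  pz <- array(100, d); pz[1, 1, 1] <- 0
  emz <- enhancement_ratio_map(volume_grid(pz), post, floor = 1)
  expect_false(emz$valid[1, 1, 1])
  expect_true(all(is.finite(emz$ratio)))

  # grids must match
  expect_error(enhancement_ratio_map(pre, volume_grid(array(1, c(8, 8, 9)))),
               "grid")
  expect_error(enhancement_ratio_map(
    pre, volume_grid(array(1, d), spacing = c(1, 1, 2))), "grid")
})

test_that("the ratio map is invariant to a common intensity scale", {
  set.seed(31)
  d <- c(10, 10, 10)
  pre <- array(stats::runif(prod(d), 50, 200), d)
  post <- pre * stats::runif(prod(d), 0.9, 1.6)
  e1 <- enhancement_ratio_map(volume_grid(pre), volume_grid(post), floor = 5)
  e2 <- enhancement_ratio_map(volume_grid(pre * 3), volume_grid(post * 3),
                              floor = 15)
  expect_equal(e1$ratio, e2$ratio, tolerance = 1e-12)
})

test_that("BPE20% counts the threshold inclusively over FGT", {
  d <- c(8, 8, 8)
  ratio <- array(0, d)
  fgt <- array(FALSE, d); fgt[1:10] <- TRUE
  breast <- array(TRUE, d)
  ratio[1:4] <- c(0.20, 0.25, 0.5, 0.9)
  ratio[5:10] <- 0.1
  em <- structure(list(ratio = ratio, valid = array(TRUE, d), floor = 0),
                  class = "enhancement_map")
  res <- compute_bpe(em, mask_list(breast, fgt), spacing = c(1, 1, 1))
  expect_equal(res$bpe20_pct, 40.0)   # the 0.20 voxel counts
  expect_equal(res$v_bpe, 4)
  expect_equal(res$n_invalid, 0)

  # all below threshold
  ratio[1:10] <- 0.19
  em$ratio <- ratio
  expect_equal(compute_bpe(em, mask_list(breast, fgt), c(1, 1, 1))$bpe20_pct, 0)

  # threshold zero with non-negative ratios saturates at 100
  expect_equal(compute_bpe(em, mask_list(breast, fgt), c(1, 1, 1),
                           threshold = 0)$bpe20_pct, 100)

  # empty FGT mask is an error, not a division by zero
  expect_error(compute_bpe(em, mask_list(breast, array(FALSE, d)), c(1, 1, 1)),
               "empty FGT")
})

test_that("raising the threshold never increases BPE", {
  set.seed(32)
  d <- c(12, 12, 12)
  ratio <- array(stats::rnorm(prod(d), 0.2, 0.2), d)
  breast <- array(TRUE, d)
  fgt <- array(stats::runif(prod(d)) < 0.3, d)
  em <- structure(list(ratio = ratio, valid = array(TRUE, d), floor = 0),
                  class = "enhancement_map")
  ths <- seq(0, 0.6, by = 0.05)
  vals <- vapply(ths, function(th)
    compute_bpe(em, mask_list(breast, fgt), c(1, 1, 1), threshold = th)$bpe20_pct,
    numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("metric core agrees exactly with the brute-force voxel loop", {
  set.seed(33)
  for (case in 1:25) {
    d <- sample(4:16, 3, replace = TRUE)
    sp <- stats::runif(3, 0.5, 3)
    breast <- array(stats::runif(prod(d)) < 0.7, d)
    if (!any(breast)) breast[1] <- TRUE
    fgt <- breast & array(stats::runif(prod(d)) < 0.4, d)
    if (!any(fgt)) fgt[which(breast)[1]] <- TRUE
    ratio <- array(stats::rnorm(prod(d), 0.2, 0.25), d)
    valid <- array(stats::runif(prod(d)) < 0.95, d)
    em <- structure(list(ratio = ratio, valid = valid, floor = 0),
                    class = "enhancement_map")
    oracle <- bpe_bruteforce(ratio, valid, breast, fgt, sp, 0.20)
    if (is.na(oracle$bpe20_pct)) next
    got <- compute_bpe(em, mask_list(breast, fgt), sp)
    expect_equal(got$bpe20_pct, oracle$bpe20_pct, tolerance = 1e-12)
    expect_equal(got$v_bpe, oracle$v_bpe)
    expect_equal(as.numeric(got$n_invalid), as.numeric(oracle$n_invalid))
    expect_equal(compute_fgt_pct(mask_list(breast, fgt), sp), oracle$fgt_pct,
                 tolerance = 1e-12)
  }
})

test_that("FGT percent behaves under mask and spacing changes", {
  d <- c(8, 8, 8)
  breast <- array(FALSE, d); breast[1:100] <- TRUE
  fgt <- array(FALSE, d); fgt[1:10] <- TRUE
  expect_equal(compute_fgt_pct(mask_list(breast, fgt), c(1, 1, 1)), 10)
  # spacing cancels out of the percentage
  expect_equal(compute_fgt_pct(mask_list(breast, fgt), c(1, 1, 3)), 10)
  # FGT == breast saturates at 100
  expect_equal(compute_fgt_pct(mask_list(breast, breast), c(1, 1, 1)), 100)
  expect_error(compute_fgt_pct(mask_list(array(FALSE, d), fgt), c(1, 1, 1)),
               "empty")
})

test_that("intrasubject BPE change is a signed percent difference", {
  pre <- list(bpe20_pct = 10); post <- list(bpe20_pct = 5)
  expect_equal(delta_bpe(pre, post)$delta_pct, -50)
  expect_equal(delta_bpe(pre, pre)$delta_pct, 0)
  expect_error(delta_bpe(list(bpe20_pct = 0), post), "undefined")
})
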