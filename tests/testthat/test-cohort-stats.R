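test_that("diagnostic accuracy reproduces hand-evaluated Wald intervals", {
  da <- diagnostic_accuracy(tp = 25, fn = 2, fp = 12, tn = 63)
  expect_equal(da$sensitivity, 100 * 25 / 27)
  expect_equal(round(da$sensitivity), 93)
  expect_equal(da$specificity, 84.0)
  # direct evaluation of p +/- 1.96 sqrt(p(1-p)/n), clipped to [0, 100]
  p <- 25 / 27
  half <- stats::qnorm(0.975) * sqrt(p * (1 - p) / 27)
  expect_equal(da$sens_ci_lo, 100 * (p - half))
  expect_equal(da$sens_ci_hi, 100)           # clipped
  q <- 63 / 75
  halfq <- stats::qnorm(0.975) * sqrt(q * (1 - q) / 75)
  expect_equal(da$spec_ci_lo, 100 * (q - halfq))
  expect_equal(da$spec_ci_hi, 100 * (q + halfq))

  # symmetric margin: tp == fn gives 50% sensitivity
  expect_equal(diagnostic_accuracy(5, 5, 3, 7)$sensitivity, 50)

  # transposing the table swaps sensitivity and specificity
  a <- diagnostic_accuracy(25, 2, 12, 63)
  b <- diagnostic_accuracy(63, 12, 2, 25)
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)

  expect_error(diagnostic_accuracy(0, 0, 3, 7), "diseased")
  # exact intervals stay inside [0, 100] too
  cp <- diagnostic_accuracy(25, 2, 12, 63, ci_method = "clopper-pearson")
  expect_true(all(cp[, c("sens_ci_lo", "sens_ci_hi")] >= 0 &
                  cp[, c("sens_ci_lo", "sens_ci_hi")] <= 100))
})

test_that("Cohen's kappa matches the contingency-table hand calculation", {
  a <- c(rep("yes", 40), rep("no", 40), rep("yes", 10), rep("no", 10))
  b <- c(rep("yes", 40), rep("no", 40), rep("no", 10), rep("yes", 10))
  k <- cohen_kappa(a, b)
  # po = 0.8, marginals 0.5/0.5 -> pe = 0.5 -> kappa = 0.6
  expect_equal(k$kappa, 0.6)
  expect_lt(k$p_value, 0.001)

  # perfect agreement
  expect_equal(cohen_kappa(a, a)$kappa, 1)

  # relabeling categories leaves kappa unchanged
  relab <- c(yes = "B", no = "A")
  expect_equal(cohen_kappa(relab[a], relab[b])$kappa, k$kappa)

  # independent ratings drift to zero (Monte-Carlo under independence)
  set.seed(99)
  ks <- replicate(20, {
    x <- sample(c("1", "2", "3"), 2000, replace = TRUE, prob = c(.5, .3, .2))
    cohen_kappa(x, sample(x))$kappa
  })
  expect_lt(abs(mean(ks)), 0.02)

  # constant ratings on both sides are undefined
  expect_warning(kk <- cohen_kappa(rep("a", 10), rep("a", 10)), "undefined")
  expect_true(is.na(kk$kappa))
})

test_that("Fleiss' kappa handles multiple raters and edge cases", {
  # three raters in perfect agreement
  m <- matrix(rep(c(1, 2, 1, 3, 2), 3), ncol = 3)
  expect_equal(fleiss_kappa(m)$kappa, 1)

  # two raters: agrees with a brute-force evaluation of the pooled-marginal
  # formula on a fixed table
  r1 <- c(1, 1, 2, 2, 1, 2, 1, 1, 2, 1)
  r2 <- c(1, 2, 2, 2, 1, 1, 1, 2, 2, 1)
  fk <- fleiss_kappa(cbind(r1, r2))
  n <- 10; r <- 2
  cnt <- cbind(rowSums(cbind(r1, r2) == 1), rowSums(cbind(r1, r2) == 2))
  pj <- colSums(cnt) / (n * r)
  Pbar <- mean((rowSums(cnt^2) - r) / (r * (r - 1)))
  Pe <- sum(pj^2)
  expect_equal(fk$kappa, (Pbar - Pe) / (1 - Pe))
})

test_that("Pearson correlation recovers exact and sampled relationships", {
  x <- c(1, 2, 3, 5, 8, 13)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(5)
  n <- 1e4
  z <- stats::rnorm(n); e <- stats::rnorm(n)
  y <- 0.5 * z + sqrt(1 - 0.25) * e   # true rho = 0.5
  expect_lt(abs(pearson_r(z, y)$r - 0.5), 0.03)
  expect_error(pearson_r(c(1, 2), c(1, 2)), "at least 3")
})

test_that("the two-sample t test behaves as Student's test", {
  x <- c(1, 2, 3, 4)
  r <- two_sample_t(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  # swapping groups flips the sign
  y <- c(2, 3, 4, 6)
  expect_equal(two_sample_t(x, y)$t, -two_sample_t(y, x)$t)
  # matches stats::t.test with pooled variance
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(two_sample_t(x, y)$p_value, ref$p.value)

  # power at a one-sigma shift, n = 50 per group
  set.seed(17)
  rej <- replicate(200, {
    a <- stats::rnorm(50); b <- stats::rnorm(50, 1)
    two_sample_t(a, b)$p_value < 0.01
  })
  expect_gte(mean(rej), 0.95)
})

test_that("the Cox wrapper recovers a known log hazard ratio", {
  set.seed(21)
  n <- 500
  grp <- rep(0:1, each = n / 2)
  t_event <- stats::rexp(n, 0.05 * exp(1 * grp))
  t_cens <- stats::runif(n, 0, 60)
  co <- tibble::tibble(rfs_months = pmin(t_event, t_cens),
                       recurrence = t_event <= t_cens, group = grp)
  fit <- fit_recurrence_model(co, "group")
  td <- tidy(fit)
  expect_lt(abs(td$log_hr - 1), 0.2)
  expect_equal(td$hazard_ratio, exp(td$log_hr))
  gl <- glance(fit)
  expect_lt(gl$lrt_p_value, 1e-6)

  # all-censored input is an explicit zero-event error
  co$recurrence <- FALSE
  expect_error(fit_recurrence_model(co, "group"), "zero recurrence events")

  # lost-to-followup rows are excluded from the fit
  co2 <- tibble::tibble(rfs_months = c(5, 10, 15, 20, 8, 12),
                        recurrence = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
                        x = c(0, 1, 0, 1, 0, 1),
                        lost_to_followup = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  fit2 <- fit_recurrence_model(co2, "x")
  expect_equal(fit2$n, 4)
})

test_that("confidence intervals from the Cox wrapper have nominal coverage", {
  set.seed(77)
  cover <- replicate(150, {
    co <- simulate_recurrence_cohort(n = 120, beta_bpe = 0,
                                     baseline_hazard = 0.02)
    td <- tidy(fit_recurrence_model(co, "bpe20_post"))
    td$hr_ci_lo <= 1 && 1 <= td$hr_ci_hi
  })
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})
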