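#' Diagnostic accuracy of a binary test from a 2x2 table
#'
#' Sensitivity and specificity, in percent, with 95% confidence intervals for
#' the binomial proportions. The default interval is the Wald normal
#' approximation `p +/- z * sqrt(p (1 - p) / n)`, clipped to [0, 100];
#' Clopper-Pearson exact intervals are available via `ci_method`. Estimates
#' carry full precision; round only at the display layer.
#'
#' @param tp,fn,fp,tn contingency counts (tp + fn > 0, fp + tn > 0).
#' @param conf_level confidence level (default 0.95).
#' @param ci_method `"wald"` (default) or `"clopper-pearson"`.
#' @return a one-row [tibble::tibble()] of class `diagnostic_accuracy`:
#'   `tp`, `fn`, `fp`, `tn`, `sensitivity`, `specificity`,
#'   `sens_ci_lo`, `sens_ci_hi`, `spec_ci_lo`, `spec_ci_hi` (all percents).
#' @examples
#' diagnostic_accuracy(tp = 25, fn = 2, fp = 12, tn = 63)
#' @export
diagnostic_accuracy <- function(tp, fn, fp, tn, conf_level = 0.95,
                                ci_method = c("wald", "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (tp + fn == 0) stop("no diseased subjects (tp + fn = 0)", call. = FALSE)
  if (fp + tn == 0) stop("no disease-free subjects (fp + tn = 0)", call. = FALSE)
  prop_ci <- function(x, n) {
    p <- x / n
    if (ci_method == "wald") {
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      half <- z * sqrt(p * (1 - p) / n)
      ci <- c(p - half, p + half)
    } else {
      ci <- as.numeric(stats::binom.test(x, n,
                                         conf.level = conf_level)$conf.int)
    }
    pmin(pmax(ci, 0), 1)
  }
  sci <- prop_ci(tp, tp + fn)
  pci <- prop_ci(tn, fp + tn)
  res <- tibble::tibble(
    tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (fp + tn),
    sens_ci_lo = 100 * sci[1], sens_ci_hi = 100 * sci[2],
    spec_ci_lo = 100 * pci[1], spec_ci_hi = 100 * pci[2])
  class(res) <- c("diagnostic_accuracy", class(res))
  res
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with `p_e` from the
#' product of the two raters' marginal distributions, plus a large-sample
#' z test of kappa = 0 (standard error under independence). When both raters
#' use a single constant category `p_e = 1` and kappa is undefined; this is
#' reported as `NA` with a warning rather than a value.
#'
#' @param ratings_a,ratings_b equal-length categorical vectors (length >= 2).
#' @return a one-row tibble: `kappa`, `z`, `p_value`, `n`, `p_observed`,
#'   `p_expected`.
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) < 2) {
    stop("need two rating vectors of equal length >= 2", call. = FALSE)
  }
  ok <- !is.na(ratings_a) & !is.na(ratings_b)
  a <- factor(ratings_a[ok]); lev <- union(levels(a), unique(ratings_b[ok]))
  a <- factor(ratings_a[ok], levels = lev)
  b <- factor(ratings_b[ok], levels = lev)
  n <- length(a)
  tab <- table(a, b) / n
  po <- sum(diag(tab))
  pa <- rowSums(tab); pb <- colSums(tab)
  pe <- sum(pa * pb)
  if (1 - pe < .Machine$double.eps) {
    warning("kappa undefined: expected agreement is 1 (constant ratings)")
    return(tibble::tibble(kappa = NA_real_, z = NA_real_, p_value = NA_real_,
                          n = n, p_observed = po, p_expected = pe))
  }
  kappa <- (po - pe) / (1 - pe)
  # SE under H0: kappa = 0 (Fleiss, Cohen & Everitt large-sample form)
  se0 <- sqrt((pe + pe^2 - sum(pa * pb * (pa + pb))) / (n * (1 - pe)^2))
  z <- kappa / se0
  tibble::tibble(kappa = kappa, z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 n = n, p_observed = po, p_expected = pe)
}

#' Fleiss' kappa for two or more raters
#'
#' Multi-rater chance-corrected agreement on a subjects x raters matrix of
#' categorical ratings, with the standard large-sample z test. For two raters
#' this differs from [cohen_kappa()] (Fleiss' expected agreement pools the
#' raters' marginals); both forms are provided because agreement studies
#' commonly name one and compute the other.
#'
#' @param ratings matrix or data frame, one row per subject, one column per
#'   rater.
#' @return a one-row tibble: `kappa`, `z`, `p_value`, `n_subjects`,
#'   `n_raters`.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2 || nrow(ratings) < 2) {
    stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  }
  lev <- sort(unique(as.vector(ratings)))
  N <- nrow(ratings); r <- ncol(ratings)
  counts <- vapply(lev, function(l) rowSums(ratings == l),
                   numeric(N))
  counts <- matrix(counts, nrow = N)
  pj <- colSums(counts) / (N * r)
  Pi <- (rowSums(counts^2) - r) / (r * (r - 1))
  Pbar <- mean(Pi)
  Pe <- sum(pj^2)
  if (1 - Pe < .Machine$double.eps) {
    warning("kappa undefined: expected agreement is 1 (constant ratings)")
    return(tibble::tibble(kappa = NA_real_, z = NA_real_, p_value = NA_real_,
                          n_subjects = N, n_raters = r))
  }
  kappa <- (Pbar - Pe) / (1 - Pe)
  se0 <- sqrt(2 / (N * r * (r - 1))) *
    sqrt(Pe - (2 * r - 3) * Pe^2 + 2 * (r - 2) * sum(pj^3)) / (1 - Pe)
  z <- kappa / se0
  tibble::tibble(kappa = kappa, z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 n_subjects = N, n_raters = r)
}

#' Pearson product-moment correlation with t-based p-value
#'
#' Thin wrapper over [stats::cor.test()] returning a tidy row; used for
#' visual-vs-quantitative agreement of FGT and BPE scores.
#'
#' @param x,y numeric vectors, n >= 3, finite.
#' @return a one-row tibble: `r`, `t`, `df`, `p_value`, `conf_lo`, `conf_hi`,
#'   `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), t = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 conf_lo = ct$conf.int[1], conf_hi = ct$conf.int[2],
                 n = length(x))
}

#' Two-sample Student t test
#'
#' Pooled-variance Student test by default (`var_equal = FALSE` gives Welch).
#'
#' @param x,y numeric vectors, each n >= 2.
#' @param var_equal pooled-variance Student test if `TRUE` (default).
#' @return a one-row tibble: `t`, `df`, `p_value`, `mean_x`, `mean_y`,
#'   `conf_lo`, `conf_hi`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  if (sum(is.finite(x)) < 2 || sum(is.finite(y)) < 2) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_x = unname(tt$estimate[1]), mean_y = unname(tt$estimate[2]),
                 conf_lo = tt$conf.int[1], conf_hi = tt$conf.int[2])
}

#' Multivariate Cox proportional-hazards model for recurrence-free survival
#'
#' Thin, validated wrapper over [survival::coxph()]. Patients lost to
#' follow-up are excluded (listwise, via `lost_to_followup`), and rows with
#' missing covariates are dropped per analysis. Results are reported on both
#' scales — log-hazard coefficients and hazard ratios — with 95% confidence
#' intervals and the model likelihood-ratio test p-value.
#'
#' @param cohort data frame with columns `rfs_months` (time from surgery to
#'   recurrence or last follow-up), `recurrence` (logical/0-1 event flag),
#'   optionally `lost_to_followup`, plus the covariates.
#' @param covariates character vector of covariate column names.
#' @param conf_level confidence level for the hazard-ratio intervals.
#' @return an object of class `recurrence_fit` wrapping the `coxph` fit;
#'   use [generics::tidy()] for per-covariate rows and [generics::glance()]
#'   for model-level statistics.
#' @export
fit_recurrence_model <- function(cohort, covariates, conf_level = 0.95) {
  cohort <- as.data.frame(cohort)
  need <- c("rfs_months", "recurrence", covariates)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if ("lost_to_followup" %in% names(cohort)) {
    cohort <- cohort[!isTRUE_vec(cohort$lost_to_followup), , drop = FALSE]
  }
  cohort <- cohort[stats::complete.cases(cohort[, need, drop = FALSE]), ,
                   drop = FALSE]
  if (any(cohort$rfs_months < 0)) {
    stop("rfs_months must be non-negative", call. = FALSE)
  }
  ev <- as.integer(as.logical(cohort$recurrence))
  if (sum(ev) == 0) {
    stop("zero recurrence events: survival model cannot be fitted",
         call. = FALSE)
  }
  fm <- stats::as.formula(paste("survival::Surv(rfs_months, recurrence_event) ~",
                                paste(covariates, collapse = " + ")))
  cohort$recurrence_event <- ev
  fit <- survival::coxph(fm, data = cohort)
  if (any(!is.finite(stats::coef(fit))) ||
      any(sqrt(diag(stats::vcov(fit))) > 1e3)) {
    stop("Cox fit is degenerate (likely complete separation of a covariate)",
         call. = FALSE)
  }
  structure(list(fit = fit, n = nrow(cohort), n_events = sum(ev),
                 covariates = covariates, conf_level = conf_level),
            class = "recurrence_fit")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.recurrence_fit <- function(x, ...) {
  cat("<recurrence_fit> Cox proportional hazards: ", x$n, " patients, ",
      x$n_events, " events\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy per-covariate results of a recurrence model
#'
#' @param x a `recurrence_fit`.
#' @param ... unused.
#' @return a tibble with one row per model term: `term`, `log_hr`,
#'   `hazard_ratio`, `hr_ci_lo`, `hr_ci_hi`, `std_error`, `p_value`.
#' @export
tidy.recurrence_fit <- function(x, ...) {
  s <- summary(x$fit, conf.int = x$conf_level)
  co <- s$coefficients
  ci <- s$conf.int
  tibble::tibble(term = rownames(co),
                 log_hr = co[, "coef"],
                 hazard_ratio = co[, "exp(coef)"],
                 hr_ci_lo = ci[, 3], hr_ci_hi = ci[, 4],
                 std_error = co[, "se(coef)"],
                 p_value = co[, "Pr(>|z|)"])
}

#' Model-level summary of a recurrence model
#'
#' @param x a `recurrence_fit`.
#' @param ... unused.
#' @return a one-row tibble: `n`, `n_events`, `lrt_statistic`, `lrt_df`,
#'   `lrt_p_value`, `concordance`.
#' @export
glance.recurrence_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(n = x$n, n_events = x$n_events,
                 lrt_statistic = unname(s$logtest["test"]),
                 lrt_df = unname(s$logtest["df"]),
                 lrt_p_value = unname(s$logtest["pvalue"]),
                 concordance = unname(s$concordance["C"]))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Simulate a synthetic recurrence cohort with a known hazard structure
#'
#' Exponential event times under a proportional-hazards model
#' `h(t) = h0 * exp(sum beta_j x_j)` with uniform censoring, used for
#' parameter-recovery and power checks of [fit_recurrence_model()]. The
#' covariate `bpe20_post` is a continuous post-treatment BPE20% score (scaled
#' to magnitude ~1, as the model covariate); `group` is a balanced binary
#' covariate.
#'
#' @param n patients.
#' @param beta_bpe,beta_group true log-hazard coefficients.
#' @param baseline_hazard events per month at covariate zero.
#' @param censor_max months; censoring times are Uniform(0, censor_max).
#' @return tibble with `id`, `bpe20_post`, `group`, `rfs_months`,
#'   `recurrence`, `lost_to_followup`.
#' @export
simulate_recurrence_cohort <- function(n = 100, beta_bpe = 1, beta_group = 0,
                                       baseline_hazard = 0.004,
                                       censor_max = 60) {
  bpe <- stats::rnorm(n, 0, 0.5)
  grp <- rep(0:1, length.out = n)
  rate <- baseline_hazard * exp(beta_bpe * bpe + beta_group * grp)
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, 0, censor_max)
  tibble::tibble(id = seq_len(n),
                 bpe20_post = bpe, group = grp,
                 rfs_months = pmin(t_event, t_cens),
                 recurrence = t_event <= t_cens,
                 lost_to_followup = FALSE)
}
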