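# Validation statistics: pooled regression metrics, prescription error
# ratios with a tolerance band, improvement hit rates, Bland-Altman limits
# of agreement, and expected-versus-observed regression.

#' Pooled regression metrics
#'
#' RMSE, MAE, R-squared, MSE and the Pearson correlation between prediction
#' and target, with all residuals pooled (matrices are flattened, so
#' multi-output predictions give one number per metric).
#'
#' @param pred,target numeric vectors or matrices of equal size, length
#'   at least 2.
#' @return a `metric_set` list: `rmse`, `mae`, `r2`, `mse`, `pearson_r`, `n`.
#' @export
metric_set <- function(pred, target) {
  pred <- as.numeric(pred)
  target <- as.numeric(target)
  if (length(pred) != length(target)) stop("pred and target lengths differ")
  if (length(pred) < 2) stop("need at least 2 pairs")
  res <- pred - target
  mse <- mean(res^2)
  ss_tot <- sum((target - mean(target))^2)
  if (ss_tot == 0) {
    warning("target has zero variance; R-squared undefined")
    r2 <- NA_real_
    pr <- NA_real_
  } else {
    r2 <- 1 - sum(res^2) / ss_tot
    pr <- if (stats::sd(pred) == 0) NA_real_ else stats::cor(pred, target)
  }
  structure(list(rmse = sqrt(mse), mae = mean(abs(res)), r2 = r2,
                 mse = mse, pearson_r = pr, n = length(pred)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("n=%d  RMSE %.4f  MAE %.4f  MSE %.4f  R2 %.4f  R %.4f\n",
              x$n, x$rmse, x$mae, x$mse, x$r2, x$pearson_r))
  invisible(x)
}

#' Prescription error ratios with a tolerance band
#'
#' Relative deviations, in percent, of predicted from target prescriptions
#' in physical units, per element: `100 * (pred - target) / target` (so a
#' negative mean means under-prescription). Reports mean, SD (n-1
#' denominator) and the fraction within the `+/- tolerance` band
#' (inclusive) for intensity, session time and programme volume. Pairs with
#' a zero target element are excluded with a warning.
#'
#' @param pred,target lists of [prescription()] objects, or n x 3 matrices
#'   with columns intensity (%HRR), time (min), volume (wk).
#' @param tolerance band half-width in percent (default 20).
#' @return an `error_ratio_report`: per-element list of `ratios`, `mean`,
#'   `sd`, `within_band`, plus `tolerance`.
#' @export
error_ratios <- function(pred, target, tolerance = 20) {
  to_mat <- function(z) {
    if (is.list(z) && inherits(z[[1]], "prescription")) {
      t(vapply(z, function(r) c(r$intensity, r$time_min, r$volume_wk),
               numeric(3)))
    } else {
      as.matrix(z)
    }
  }
  p <- to_mat(pred)
  t_ <- to_mat(target)
  stopifnot(ncol(p) == 3, all(dim(p) == dim(t_)))
  elements <- c("intensity", "time", "volume")
  out <- lapply(seq_len(3), function(j) {
    keep <- t_[, j] != 0
    if (any(!keep)) {
      warning("excluding ", sum(!keep), " zero-target ", elements[j],
              " pair(s) from error ratios")
    }
    ratios <- 100 * (p[keep, j] - t_[keep, j]) / t_[keep, j]
    list(ratios = ratios, mean = mean(ratios), sd = stats::sd(ratios),
         within_band = mean(abs(ratios) <= tolerance))
  })
  names(out) <- elements
  structure(c(out, list(tolerance = tolerance)),
            class = "error_ratio_report")
}

#' @export
print.error_ratio_report <- function(x, ...) {
  for (el in c("intensity", "time", "volume")) {
    cat(sprintf("%-9s %+5.1f%% +/- %4.1f%%  (%.0f%% within +/-%g%%)\n", el,
                x[[el]]$mean, x[[el]]$sd,
                round_half_up(100 * x[[el]]$within_band), x$tolerance))
  }
  invisible(x)
}

#' Whole-percent rate from counts
#'
#' `round_half_up(100 * hits / n)`, the convention for all printed rates
#' (e.g. 43 of 61 is 70 percent).
#'
#' @param hits,n counts, `hits <= n`.
#' @return integer percent.
#' @export
rate_from_counts <- function(hits, n) {
  stopifnot(all(hits >= 0), all(hits <= n), all(n >= 1))
  as.integer(round_half_up(100 * hits / n))
}

#' Improvement hit rate within a mean +/- k*SD band
#'
#' Computes the sample mean M and SD (n-1 denominator) of observed
#' improvements and counts values inside `[M - k*sd, M + k*sd]` (inclusive
#' bounds). The rate is reported as a whole percent.
#'
#' @param improvements observed improvements in percent.
#' @param k band multiplier, typically 1 or 1.96.
#' @return a `hit_rate_band`: `m`, `sd`, `k`, `range`, `hits`, `n`, `rate`.
#' @export
hit_rate <- function(improvements, k = 1) {
  improvements <- as.numeric(improvements)
  if (length(improvements) < 2) stop("need at least 2 improvements")
  m <- mean(improvements)
  s <- stats::sd(improvements)
  lo <- m - k * s
  hi <- m + k * s
  hits <- sum(improvements >= lo & improvements <= hi)
  n <- length(improvements)
  structure(list(m = m, sd = s, k = k, range = c(lo, hi),
                 hits = hits, n = n, rate = rate_from_counts(hits, n)),
            class = "hit_rate_band")
}

#' @export
print.hit_rate_band <- function(x, ...) {
  cat(sprintf("M +/- %.2f sd band [%.1f, %.1f]%%: %d/%d hits (%d%%)\n",
              x$k, x$range[1], x$range[2], x$hits, x$n, x$rate))
  invisible(x)
}

#' Study dropout rate
#'
#' Percent of enrolled subjects who did not complete, to one decimal
#' (e.g. 64 enrolled, 61 completed gives 4.7).
#'
#' @param enrolled,completed counts.
#' @return percent to 1 decimal.
#' @export
dropout_rate <- function(enrolled, completed) {
  stopifnot(completed <= enrolled, enrolled >= 1)
  round_half_up(100 * (enrolled - completed) / enrolled, 1)
}

#' Bland-Altman agreement analysis
#'
#' Differences between the paired measurements (default orientation
#' `expected - observed`), the mean difference (bias), the 95 percent
#' limits of agreement `bias +/- 1.96 * sd(differences)` (n-1 SD), and the
#' percent of points inside the limits (inclusive).
#'
#' @param expected,observed paired numeric vectors, length at least 2.
#' @param orientation `"expected_minus_observed"` (default) or
#'   `"observed_minus_expected"`.
#' @return an `agreement_report`: `bias`, `loa_low`, `loa_high`,
#'   `coverage` (percent), `differences`, `means`, `n`.
#' @export
bland_altman <- function(expected, observed,
                         orientation = c("expected_minus_observed",
                                         "observed_minus_expected")) {
  orientation <- match.arg(orientation)
  stopifnot(length(expected) == length(observed))
  if (length(expected) < 2) stop("need at least 2 pairs")
  d <- if (orientation == "expected_minus_observed") expected - observed
       else observed - expected
  bias <- mean(d)
  s <- stats::sd(d)
  lo <- bias - 1.96 * s
  hi <- bias + 1.96 * s
  structure(list(bias = bias, loa_low = lo, loa_high = hi,
                 coverage = 100 * mean(d >= lo & d <= hi),
                 differences = d, means = (expected + observed) / 2,
                 n = length(d), orientation = orientation),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s): bias %.3f, 95%% LoA [%.3f, %.3f], %.1f%% within\n",
              x$orientation, x$bias, x$loa_low, x$loa_high, x$coverage))
  invisible(x)
}

#' Expected-versus-observed ordinary least squares
#'
#' Regresses observed on expected values; reports slope and intercept with
#' the slope's 95 percent confidence interval, R-squared, and the p-value
#' of the non-zero-slope test.
#'
#' @param expected,observed paired numeric vectors, length at least 3.
#' @return list with `slope`, `intercept`, `r2`, `slope_ci`, `p_value`,
#'   and the underlying `stats::lm` fit.
#' @export
expected_vs_observed_regression <- function(expected, observed) {
  stopifnot(length(expected) == length(observed))
  if (length(expected) < 3) stop("need at least 3 pairs")
  if (stats::sd(expected) == 0) stop("expected values have zero variance")
  fit <- stats::lm(observed ~ expected)
  sm <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = sm$r.squared,
    slope_ci = unname(stats::confint(fit)["expected", ]),
    p_value = unname(sm$coefficients["expected", "Pr(>|t|)"]),
    fit = fit
  ), class = "eo_regression")
}

#' @export
print.eo_regression <- function(x, ...) {
  cat(sprintf(
    "observed = %.4f + %.4f * expected  (R2 %.4f, slope 95%% CI [%.4f, %.4f], p %.2g)\n",
    x$intercept, x$slope, x$r2, x$slope_ci[1], x$slope_ci[2], x$p_value))
  invisible(x)
}
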