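#' Total reconstructed counts over a support
#'
#' The calibration factor can be defined from the entire field of view
#' (method 1) or from the liver VOI only (method 2, which avoids counts from
#' image artifacts).
#'
#' @param img \code{voxel_grid} in cps.
#' @param mask a \code{voi_mask}, or NULL for the whole field of view.
#' @return total count rate (cps).
#' @export
total_counts <- function(img, mask = NULL) {
  check_units(img, "cps")
  if (is.null(mask)) return(sum(img$data))
  voi_stats(img, mask)$total
}

#' Fit a calibration curve (counts vs administered activity)
#'
#' Ordinary least squares of reconstructed count rate on administered
#' activity across patients; the calibration factor (CF, cps/MBq) is the
#' slope.  The intercept is reported for diagnostics; a through-origin fit is
#' available via \code{through_origin = TRUE}.
#'
#' @param administered_MBq administered activities (>= 3 values, not all
#'   equal).
#' @param counts_cps total reconstructed count rates, same length.
#' @param method \code{"whole_fov"} or \code{"liver_voi"} provenance tag.
#' @param through_origin force a zero intercept.
#' @return an object of class \code{calibration_model} with \code{slope}
#'   (the CF), \code{intercept}, \code{r_squared}, \code{slope_se},
#'   \code{slope_ci95} (t-based 95\% interval) and \code{degenerate} flag
#'   (slope <= 0).
#' @export
fit_calibration <- function(administered_MBq, counts_cps,
                            method = c("liver_voi", "whole_fov"),
                            through_origin = FALSE) {
  method <- match.arg(method)
  x <- as.numeric(administered_MBq); y <- as.numeric(counts_cps)
  if (length(x) < 3L || length(y) != length(x))
    stop("need >= 3 (activity, counts) pairs")
  if (stats::var(x) == 0) stop("zero variance in administered activities")
  fit <- if (through_origin) stats::lm(y ~ 0 + x) else stats::lm(y ~ x)
  # exact calibration lines are legitimate here; muffle the perfect-fit note
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  co <- sm$coefficients
  srow <- if (through_origin) "x" else "x"
  slope <- co[srow, "Estimate"]
  se <- co[srow, "Std. Error"]
  df <- fit$df.residual
  tq <- stats::qt(0.975, df)
  structure(list(method = method,
                 slope = slope,
                 intercept = if (through_origin) 0
                             else unname(co["(Intercept)", "Estimate"]),
                 r_squared = sm$r.squared,
                 slope_se = se,
                 slope_ci95 = c(slope - tq * se, slope + tq * se),
                 n = length(x), df = df,
                 degenerate = !is.finite(slope) || slope <= 0,
                 fit = fit),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> %s: CF = %.0f cps/MBq (95%% CI %.0f..%.0f), R2 = %.3f\n",
    x$method, x$slope, x$slope_ci95[1], x$slope_ci95[2], x$r_squared))
  if (x$degenerate) cat("  ** degenerate calibration (slope <= 0) **\n")
  invisible(x)
}

#' Convert a count-rate image to activity
#'
#' Voxel values are divided by the calibration factor, converting cps to
#' MBq per voxel.
#'
#' @param img \code{voxel_grid} in cps.
#' @param cf calibration factor, cps/MBq (> 0).
#' @return \code{voxel_grid} in MBq.
#' @export
apply_cf <- function(img, cf) {
  check_units(img, "cps")
  if (!is.finite(cf) || cf <= 0) stop("cf must be positive")
  voxel_grid(img$data / cf, spacing = img$spacing, origin = img$origin,
             units = "MBq")
}

#' Signed percent error of an activity estimate
#'
#' \code{\%Error = (True - Estimated) / True * 100}.  Report tables round to
#' the nearest integer, half away from zero (see \code{rounded}).
#'
#' @param true_MBq true (administered) activity, nonzero.
#' @param estimated_MBq estimated activity.
#' @param rounded round to nearest integer for report tables.
#' @export
percent_error <- function(true_MBq, estimated_MBq, rounded = FALSE) {
  if (any(true_MBq == 0)) stop("true activity must be nonzero")
  e <- (true_MBq - estimated_MBq) / true_MBq * 100
  if (rounded) round_half_away(e) else e
}

#' Mean and sample SD of a set of percent errors
#' @param errors numeric vector, length >= 2.
#' @return list with \code{mean} and \code{sd} (n-1 denominator).
#' @export
error_summary <- function(errors) {
  if (length(errors) < 2L) stop("need >= 2 errors")
  list(mean = mean(errors), sd = stats::sd(errors))
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t transform with
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors, length >= 3, nonzero variance.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
pearson_r <- function(x, y) {
  if (length(x) < 3L || length(y) != length(x)) stop("need n >= 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant sequence: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Paired t statistic from a difference summary
#'
#' \code{t = mean_diff / (sd_diff / sqrt(n))}, df = n - 1.  When only the
#' printed difference summary of a study is available this reproduces the
#' reported statistic; \code{\link{paired_t}} accepts the raw paired samples
#' and reduces to the same computation.
#'
#' @param mean_diff mean of paired differences.
#' @param sd_diff SD of paired differences (> 0; a zero SD with nonzero mean
#'   is reported as an infinite-t condition).
#' @param n number of pairs (>= 2).
#' @return list with \code{t}, \code{df}, \code{p} (two-sided).
#' @export
paired_t_summary <- function(mean_diff, sd_diff, n) {
  if (n < 2L) stop("need n >= 2")
  if (sd_diff < 0) stop("sd_diff must be >= 0")
  if (sd_diff == 0) {
    t <- if (mean_diff == 0) 0 else sign(mean_diff) * Inf
  } else {
    t <- mean_diff / (sd_diff / sqrt(n))
  }
  df <- n - 1
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Paired t test from raw samples
#' @param x,y paired numeric vectors of equal length >= 2.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("need paired samples of equal length >= 2")
  d <- x - y
  paired_t_summary(mean(d), stats::sd(d), length(d))
}

#' Grubbs test for a single outlier
#'
#' \code{G = max |x_i - mean| / sd} (sample SD).  The two-sided p-value uses
#' the standard t-based critical relation
#' \code{G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))}.
#'
#' @param x numeric vector, length >= 3, nonconstant.
#' @return list with \code{G}, \code{index} of the most extreme value, and
#'   two-sided \code{p} (clamped to [0, 1]).
#' @export
grubbs_max_outlier <- function(x) {
  n <- length(x)
  if (n < 3L) stop("need n >= 3")
  s <- stats::sd(x)
  if (s == 0) stop("constant sequence")
  dev <- abs(x - mean(x))
  idx <- which.max(dev)
  g <- dev[idx] / s
  u <- g^2 * n / (n - 1)^2
  if (u >= 1) {
    p <- 0
  } else {
    t <- sqrt(u * (n - 2) / (1 - u))
    p <- min(1, max(0, 2 * n * stats::pt(t, n - 2, lower.tail = FALSE)))
  }
  list(G = g, index = idx, p = p)
}
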