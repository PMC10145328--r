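#' Intraclass correlation ICC(A,1): two-way, absolute agreement, single
#' measure
#'
#' Computes the single-score absolute-agreement intraclass correlation
#' from the two-way ANOVA decomposition of an n-by-k table (here k = 2
#' raters: estimated and reference rates):
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n}(MS_C - MS_E)},}
#' with `MS_R` the between-rows (subjects), `MS_C` the between-columns
#' (raters) and `MS_E` the residual mean squares.  The confidence
#' interval follows the F-distribution construction for this ICC form,
#' with the Satterthwaite degrees of freedom for the column effect.
#' Absolute agreement penalizes any systematic offset between the two
#' series, unlike the consistency form.
#'
#' @param est Numeric vector (estimated values, bpm) — or a two-column
#'   matrix/data frame of both raters, in which case `ref` is ignored.
#' @param ref Numeric vector (reference values), same length as `est`.
#' @param alpha Significance level for the confidence interval
#'   (default 0.05).
#'
#' @return An object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `alpha`, `n`, `k` and the mean squares `msr`, `msc`, `mse`.
#' @examples
#' set.seed(1)
#' ref <- seq(8, 20, length.out = 50)
#' icc_a1(ref + rnorm(50, sd = 0.5), ref)
#' @export
icc_a1 <- function(est, ref = NULL, alpha = 0.05) {
  if (is.matrix(est) || is.data.frame(est)) {
    ratings <- as.matrix(est)
  } else {
    if (is.null(ref)) stop("'ref' is required when 'est' is a vector",
                           call. = FALSE)
    if (length(est) != length(ref))
      stop("'est' and 'ref' must have equal length", call. = FALSE)
    ratings <- cbind(est, ref)
  }
  if (!all(is.finite(ratings))) stop("ratings must be finite", call. = FALSE)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need at least 2 rows and 2 columns",
                             call. = FALSE)

  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  if (ss_total == 0)
    stop("zero total variance: ICC undefined for constant ratings",
         call. = FALSE)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  # CI: F construction with Satterthwaite df for the column effect
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v_num <- ((a * msc + b * mse)^2)
  v_den <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
  v <- v_num / v_den
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  structure(
    list(icc = icc, ci_low = ci_low, ci_high = ci_high, alpha = alpha,
         n = n, k = k, msr = msr, msc = msc, mse = mse),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.4f, %d%% CI [%.4f, %.4f]  (n = %d pairs)\n",
              x$icc, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = est - ref`: bias is their mean, the limits of
#' agreement are `bias +/- 1.96 * sd(d)` (sample SD, N-1 denominator),
#' the interval expected to contain 95% of paired differences.  The
#' Pearson correlation of the two series is attached.
#'
#' @param est Numeric vector (estimated, bpm).
#' @param ref Numeric vector (reference), same length.
#' @return An object of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `pearson_cc`, `n`, plus the `mean` and
#'   `diff` vectors for plotting.
#' @examples
#' set.seed(2)
#' ref <- runif(100, 6, 21)
#' bland_altman(ref + rnorm(100, sd = 0.5), ref)
#' @export
bland_altman <- function(est, ref) {
  if (length(est) != length(ref) || length(est) < 2L)
    stop("'est' and 'ref' must be equal-length vectors (n >= 2)",
         call. = FALSE)
  if (!all(is.finite(est)) || !all(is.finite(ref)))
    stop("inputs must be finite", call. = FALSE)
  d <- est - ref
  bias <- mean(d)
  sd_d <- stats::sd(d)
  # correlation is undefined when either series is constant
  cc <- if (stats::sd(est) == 0 || stats::sd(ref) == 0) NA_real_
        else stats::cor(est, ref)
  structure(
    list(bias = bias, sd_diff = sd_d,
         loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
         pearson_cc = cc, n = length(d),
         mean = (est + ref) / 2, diff = d),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4f +/- %.4f, LoA [%.4f, %.4f], r = %.4f (n = %d)\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$pearson_cc, x$n))
  invisible(x)
}

#' Stratified and combined agreement summary
#'
#' Runs [icc_a1()] and [bland_altman()] per source label and on the
#' pooled data, returning one row per stratum plus a `"combined"` row —
#' the usual per-signal-type agreement table.
#'
#' @param est Numeric vector (estimated, bpm).
#' @param ref Numeric vector (reference), same length.
#' @param labels Character/factor of per-pair source tags (optional; if
#'   omitted only the combined row is produced).
#' @param alpha Significance level for the ICC interval (default 0.05).
#' @return Data frame with columns `label`, `n`, `icc`, `icc_ci_low`,
#'   `icc_ci_high`, `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `pearson_cc`.
#' @export
agreement_summary <- function(est, ref, labels = NULL, alpha = 0.05) {
  one <- function(e, r, lab) {
    ic <- icc_a1(e, r, alpha)
    ba <- bland_altman(e, r)
    data.frame(label = lab, n = length(e), icc = ic$icc,
               icc_ci_low = ic$ci_low, icc_ci_high = ic$ci_high,
               bias = ba$bias, sd_diff = ba$sd_diff,
               loa_low = ba$loa_low, loa_high = ba$loa_high,
               pearson_cc = ba$pearson_cc)
  }
  rows <- list()
  if (!is.null(labels)) {
    if (length(labels) != length(est))
      stop("'labels' must match the pair count", call. = FALSE)
    for (lab in unique(as.character(labels))) {
      sel <- labels == lab
      rows[[lab]] <- one(est[sel], ref[sel], lab)
    }
  }
  rows[["combined"]] <- one(est, ref, "combined")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
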