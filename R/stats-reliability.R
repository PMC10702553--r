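#' Intraclass correlation, two-way mixed model, single rating
#'
#' ICC(3,1) in the Shrout–Fleiss / McGraw–Wong taxonomy: subjects are random
#' rows, raters (here: measurement methods, e.g. automated vs ground truth)
#' are fixed columns, and the coefficient reflects the consistency of single
#' ratings. From the two-way ANOVA decomposition,
#' `ICC = (MS_rows - MS_error) / (MS_rows + (k - 1) * MS_error)`, with the
#' 95% confidence interval from the F-distribution method and the observed
#' `F = MS_rows / MS_error` on `(n - 1, (n - 1)(k - 1))` degrees of freedom.
#'
#' The qualitative band follows the conventional interpretation scale:
#' below 0.50 poor, 0.50 to under 0.75 fair, 0.75 to under 0.90 good, 0.90
#' and above excellent (edges 0.50 -> fair, 0.90 -> excellent).
#'
#' @param ratings numeric matrix or data frame, `n_subjects x k_raters`
#'   (`n >= 5`, `k >= 2`), no missing cells.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return An `icc_result` with elements `icc`, `ci95`, `f_stat`, `df1`,
#'   `df2`, `p_value`, `band`, `n_subjects`, `k_raters`, `degenerate`
#'   (TRUE when subjects have zero variance).
#' @examples
#' x <- c(2.1, 3.4, 4.2, 5.1, 6.0, 7.3)
#' icc_single_rating(cbind(x, x))$icc  # identical columns: 1
#' @export
icc_single_rating <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("ratings has missing cells; ICC requires a complete table")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 5L) stop("need at least 5 subjects")
  if (k < 2L) stop("need at least 2 raters/methods")
  ms <- icc_mean_squares(m)
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  degenerate <- ms$msr < .Machine$double.eps & ms$mse < .Machine$double.eps
  icc <- if (ms$msr + (k - 1) * ms$mse <= 0) NA_real_ else
    (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
  f_obs <- if (ms$mse <= 0) Inf else ms$msr / ms$mse
  p <- if (is.infinite(f_obs)) 0 else stats::pf(f_obs, df1, df2, lower.tail = FALSE)
  alpha <- 1 - conf_level
  if (is.infinite(f_obs)) {
    ci <- c(1, 1)  # perfect agreement: interval collapses
  } else {
    fl <- f_obs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f_obs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  structure(
    list(icc = icc, ci95 = ci, f_stat = f_obs, df1 = df1, df2 = df2,
         p_value = p, band = icc_band(icc), n_subjects = n, k_raters = k,
         ms_rows = ms$msr, ms_cols = ms$msc, ms_error = ms$mse,
         degenerate = isTRUE(degenerate)),
    class = "icc_result"
  )
}

icc_mean_squares <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1), mse = sse / ((n - 1) * (k - 1)))
}

icc_band <- function(icc) {
  if (is.na(icc)) return(NA_character_)
  if (icc < 0.50) "poor"
  else if (icc < 0.75) "fair"
  else if (icc < 0.90) "good"
  else "excellent"
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(3,1) single rating: %.4f [%.4f, %.4f] (%s)\n",
              x$icc, x$ci95[1], x$ci95[2], x$band))
  cat(sprintf("F(%d, %d) = %.4g, p = %.4g; %d subjects x %d raters\n",
              x$df1, x$df2, x$f_stat, x$p_value, x$n_subjects, x$k_raters))
  if (x$degenerate) cat("note: zero variance across subjects (degenerate)\n")
  invisible(x)
}

#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$icc, conf.low = x$ci95[1], conf.high = x$ci95[2],
    statistic = x$f_stat, df1 = x$df1, df2 = x$df2, p.value = x$p_value,
    band = x$band
  )
}

#' @export
glance.icc_result <- function(x, ...) {
  tibble::tibble(icc = x$icc, band = x$band, p.value = x$p_value,
                 n_subjects = x$n_subjects, k_raters = x$k_raters)
}

#' Bland–Altman agreement analysis
#'
#' Bias and 95% limits of agreement of paired differences `d = a - b`:
#' `bias = mean(d)`, `loa = bias +/- 1.96 * sd(d)` (the classical constant is
#' used exactly at `alpha = 0.05`; `qnorm(1 - alpha/2)` otherwise).
#' Proportional bias is assessed by regressing the differences on the pair
#' means `(a + b) / 2`; a slope p-value below `alpha` indicates that the
#' disagreement scales with the magnitude of the measurement.
#'
#' @param method_a,method_b paired measurements, equal length, `n >= 3`.
#' @param alpha significance level (default 0.05).
#' @return A `bland_altman_result` with `bias`, `sd_diff`, `loa`,
#'   `proportional_bias_slope`, `proportional_bias_p`, `n`, and the
#'   per-pair `means` / `diffs` used (for plotting).
#' @export
bland_altman <- function(method_a, method_b, alpha = 0.05) {
  if (length(method_a) != length(method_b)) {
    stop("method_a and method_b must have equal length")
  }
  n <- length(method_a)
  if (n < 3L) stop("need at least 3 pairs")
  d <- method_a - method_b
  means <- (method_a + method_b) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  z <- if (isTRUE(all.equal(alpha, 0.05))) 1.96 else stats::qnorm(1 - alpha / 2)
  loa <- c(lower = bias - z * sd_diff, upper = bias + z * sd_diff)
  if (sd_diff > 0 && stats::sd(means) > 0) {
    fit <- stats::lm(d ~ means)
    ct <- suppressWarnings(summary(fit))$coefficients
    slope <- ct["means", "Estimate"]
    slope_p <- ct["means", "Pr(>|t|)"]
  } else {
    slope <- 0
    slope_p <- NA_real_
  }
  structure(
    list(bias = bias, sd_diff = sd_diff, loa = loa,
         proportional_bias_slope = slope, proportional_bias_p = slope_p,
         alpha = alpha, n = n, means = means, diffs = d),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4g, limits of agreement [%.4g, %.4g] (n = %d)\n",
              x$bias, x$loa[1], x$loa[2], x$n))
  cat(sprintf("proportional bias slope %.4g, p = %.4g\n",
              x$proportional_bias_slope, x$proportional_bias_p))
  invisible(x)
}

#' @export
tidy.bland_altman_result <- function(x, ...) {
  tibble::tibble(
    bias = x$bias, sd_diff = x$sd_diff,
    loa_lower = x$loa[["lower"]], loa_upper = x$loa[["upper"]],
    proportional_bias_slope = x$proportional_bias_slope,
    proportional_bias_p = x$proportional_bias_p, n = x$n
  )
}

#' @export
glance.bland_altman_result <- function(x, ...) tidy(x)

#' Normality-gated paired comparison
#'
#' The paired-testing scheme used to compare automated against ground-truth
#' morphometrics: differences are first tested for normality with
#' Shapiro–Wilk; when normality is rejected at `alpha` the Wilcoxon
#' signed-rank test is used (two-sided, zero differences dropped per
#' Wilcoxon's rule, exact distribution for 25 or fewer nonzero untied pairs,
#' normal approximation with continuity and tie correction otherwise), and a
#' paired t-test otherwise.
#'
#' @param x,y paired measurements, equal length, `n >= 6`.
#' @param alpha normality-gate significance level (default 0.05).
#' @return A `paired_comparison` with `test_used`, `statistic`, `p_value`,
#'   `normality_p`, `n`, `n_nonzero`, `degenerate` (all differences zero).
#' @export
paired_compare <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 6L) stop("need at least 6 pairs")
  d <- x - y
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    return(structure(
      list(test_used = NA_character_, statistic = NA_real_, p_value = NA_real_,
           normality_p = NA_real_, n = n, n_nonzero = 0L, degenerate = TRUE),
      class = "paired_comparison"
    ))
  }
  sw_p <- tryCatch(stats::shapiro.test(d)$p.value, error = function(e) NA_real_)
  use_wilcoxon <- is.na(sw_p) || sw_p < alpha
  if (use_wilcoxon) {
    exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
    wt <- suppressWarnings(
      stats::wilcox.test(nz, mu = 0, exact = exact, correct = TRUE)
    )
    res <- list(test_used = "wilcoxon", statistic = unname(wt$statistic),
                p_value = wt$p.value)
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    res <- list(test_used = "paired_t", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  }
  structure(
    c(res, list(normality_p = sw_p, n = n, n_nonzero = length(nz),
                degenerate = FALSE)),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat("paired comparison: all differences zero (degenerate)\n")
    return(invisible(x))
  }
  cat(sprintf("paired comparison (%s): statistic %.4g, p = %.4g\n",
              x$test_used, x$statistic, x$p_value))
  cat(sprintf("Shapiro-Wilk normality p = %.4g (n = %d, %d nonzero)\n",
              x$normality_p, x$n, x$n_nonzero))
  invisible(x)
}

#' @export
tidy.paired_comparison <- function(x, ...) {
  tibble::tibble(test_used = x$test_used, statistic = x$statistic,
                 p.value = x$p_value, normality_p = x$normality_p,
                 n = x$n, degenerate = x$degenerate)
}

#' One-way ANOVA across parallel sections
#'
#' Fixed-effects one-way ANOVA used to check that morphometrics measured on
#' parallel histological sections of the same nerve do not differ.
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2 values)
#' @return A tibble with `f_stat`, `df_between`, `df_within`, `p_value`.
#' @export
parallel_sections_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("every group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  tibble::tibble(
    f_stat = tab[["F value"]][1],
    df_between = tab[["Df"]][1],
    df_within = tab[["Df"]][2],
    p_value = tab[["Pr(>F)"]][1]
  )
}
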