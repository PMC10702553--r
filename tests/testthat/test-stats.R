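test_that("ICC(3,1) matches the independent ANOVA oracle", {
  # fixed 6x2 hand table
  tab <- cbind(c(9, 2, 5, 8, 6, 7), c(8, 1, 7, 9, 4, 8))
  res <- icc_single_rating(tab)
  expect_equal(res$icc, icc_oracle(tab), tolerance = 1e-10)
  # random 10x2 tables
  set.seed(99)
  for (i in 1:20) {
    m <- matrix(rnorm(20), 10, 2)
    expect_equal(icc_single_rating(m)$icc, icc_oracle(m), tolerance = 1e-10)
  }
})

test_that("identical columns give ICC 1 in the excellent band", {
  x <- c(2.3, 4.1, 5.5, 7.2, 8.8, 10.1)
  res <- icc_single_rating(cbind(x, x))
  expect_equal(res$icc, 1)
  expect_identical(res$band, "excellent")
  expect_equal(res$ci95, c(1, 1))
  expect_lt(res$p_value, 1e-10)
})

test_that("noise at the subject SD halves the ICC", {
  withr::local_seed(7)
  s <- rnorm(200, sd = 1)
  tab <- cbind(s + rnorm(200, sd = 1), s + rnorm(200, sd = 1))
  res <- icc_single_rating(tab)
  expect_lt(abs(res$icc - 0.5), 0.1)  # sigma_s^2/(sigma_s^2+sigma_e^2)
  expect_true(res$ci95[1] < res$icc, res$ci95[2] > res$icc)
})

test_that("interpretation band edges sit exactly at 0.50, 0.75, 0.90", {
  band <- gratior:::icc_band
  expect_identical(band(0.4999), "poor")
  expect_identical(band(0.50), "fair")
  expect_identical(band(0.7499), "fair")
  expect_identical(band(0.75), "good")
  expect_identical(band(0.8999), "good")
  expect_identical(band(0.90), "excellent")
})

test_that("ICC input validation rejects unusable tables", {
  expect_error(icc_single_rating(matrix(rnorm(8), 4, 2)), "at least 5")
  expect_error(icc_single_rating(matrix(rnorm(10), 10, 1)), "at least 2")
  m <- matrix(rnorm(20), 10, 2)
  m[3, 2] <- NA
  expect_error(icc_single_rating(m), "missing")
})

test_that("Bland-Altman handles degenerate and closed-form cases", {
  x <- c(1.2, 3.4, 5.6, 7.8, 9.1)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(unname(ba0$loa), c(0, 0))

  bac <- bland_altman(x + 0.7, x)
  expect_equal(bac$bias, 0.7)
  expect_equal(bac$sd_diff, 0)
  expect_equal(unname(bac$loa), c(0.7, 0.7))

  withr::local_seed(123)
  a <- rnorm(1000, 0.2, 0.1)
  ba <- bland_altman(a, rep(0, 1000))
  se <- 0.1 / sqrt(1000)
  expect_lt(abs(ba$bias - 0.2), 3 * se)
  expect_lt(abs(ba$loa[["lower"]] - 0.004), 3 * sqrt(3) * se)
  expect_lt(abs(ba$loa[["upper"]] - 0.396), 3 * sqrt(3) * se)
  # limits symmetric about bias with the 1.96 constant
  expect_equal(ba$loa[["upper"]] - ba$bias, ba$bias - ba$loa[["lower"]],
               tolerance = 1e-9)
  expect_equal(ba$loa[["upper"]], ba$bias + 1.96 * ba$sd_diff, tolerance = 1e-9)
})

test_that("proportional bias is detected when differences scale with means", {
  withr::local_seed(5)
  truth <- runif(200, 1, 10)
  a <- truth * 1.2 + rnorm(200, 0, 0.1)  # disagreement grows with magnitude
  ba <- bland_altman(a, truth)
  expect_gt(ba$proportional_bias_slope, 0.1)
  expect_lt(ba$proportional_bias_p, 0.001)
})

test_that("paired comparison gates on Shapiro-Wilk and flags degeneracy", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_true(paired_compare(x, x)$degenerate)

  withr::local_seed(31)
  # strongly non-normal differences -> wilcoxon
  y <- rnorm(50)
  res <- paired_compare(y + 5 * rexp(50), y)
  expect_identical(res$test_used, "wilcoxon")
  expect_lt(res$normality_p, 0.05)
  expect_lt(res$p_value, 0.001)  # 5 SD shift: power ~ 1

  # normal differences -> paired t
  res_t <- paired_compare(y + rnorm(50, 0.1, 0.5), y)
  expect_identical(res_t$test_used, "paired_t")
  expect_gte(res_t$normality_p, 0.05)
})

test_that("exact signed-rank p equals full enumeration at n = 8", {
  withr::local_seed(77)
  for (i in 1:10) {
    d <- round(rnorm(8, 0.3, 1), 3)
    while (any(d == 0) || any(duplicated(abs(d)))) d <- round(rnorm(8, 0.3, 1), 3)
    x <- d
    y <- rep(0, 8)
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, exact = TRUE))
    expect_equal(wt$p.value, wilcoxon_enum_p(d), tolerance = 1e-12)
  }
})

test_that("one-way ANOVA behaves at both extremes", {
  g <- list(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  res <- parallel_sections_anova(g)
  expect_equal(res$f_stat, 0)
  expect_equal(res$p_value, 1)

  withr::local_seed(9)
  a <- rnorm(30)
  b <- rnorm(30) + 10   # 10 SD separation
  res2 <- parallel_sections_anova(list(a, b))
  expect_lt(res2$p_value, 1e-6)
  expect_error(parallel_sections_anova(list(a)), "at least 2")
  expect_error(parallel_sections_anova(list(a, 1)), "at least 2 values")
})

test_that("the normality-gated pair test holds its type-I error near 5%", {
  withr::local_seed(2024)
  rejections <- 0
  n_rep <- 300
  for (i in 1:n_rep) {
    x <- rnorm(30)
    y <- x + rnorm(30)
    p <- paired_compare(x, y)$p_value
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_lt(abs(rejections / n_rep - 0.05), 0.02)
})

test_that("tidiers return one-row tibbles with standard names", {
  x <- rnorm(20)
  tab <- cbind(x, x + rnorm(20, 0, 0.3))
  td <- tidy(icc_single_rating(tab))
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("estimate", "conf.low", "conf.high", "p.value") %in% names(td)))
  tb <- tidy(bland_altman(tab[, 1], tab[, 2]))
  expect_true(all(c("bias", "loa_lower", "loa_upper") %in% names(tb)))
  tp <- tidy(paired_compare(tab[, 1], tab[, 2]))
  expect_true(all(c("test_used", "p.value") %in% names(tp)))
})
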