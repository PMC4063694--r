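# Method-comparison statistics: each operation against hand arithmetic
# or an independently computed reference.

test_that("pearson correlation matches hand-computed covariance ratios", {
  expect_equal(pearson(1:5, 1:5)$r, 1)
  expect_equal(pearson(1:5, -(1:5) + 7)$r, -1)

  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- pearson(x, y)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_identical(got$r_squared, got$r^2)  # machine-precision identity
  expect_error(pearson(rep(1, 4), 1:4), "variance")
  expect_error(pearson(1:2, 1:2), "at least")
})

test_that("icc reproduces the ANOVA-by-hand and reference values", {
  # degenerate and ordering properties
  same <- tibble::tibble(a = c(3, 9, 5, 7, 1, 4), b = c(3, 9, 5, 7, 1, 4))
  expect_equal(icc(same, type = "agreement")$icc, 1)
  expect_equal(icc(same, type = "consistency")$icc, 1)

  shifted <- tibble::tibble(a = c(3, 9, 5, 7, 1, 4),
                            b = c(3, 9, 5, 7, 1, 4) + 50)
  expect_lt(icc(shifted, type = "agreement")$icc,
            icc(shifted, type = "consistency")$icc)

  # 6-subject x 3-rater toy: explicit ANOVA sums
  tab <- tibble::tibble(r1 = c(120, 80, 200, 150, 90, 60),
                        r2 = c(118, 85, 190, 155, 92, 63),
                        r3 = c(125, 78, 205, 148, 88, 58))
  mat <- as.matrix(tab)
  n <- 6
  k <- 3
  grand <- mean(mat)
  ss_rows <- k * sum((rowMeans(mat) - grand)^2)
  ss_cols <- n * sum((colMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  icc_a1_hand <- (msr - mse) /
    (msr + (k - 1) * mse + k * (msc - mse) / n)
  icc_c1_hand <- (msr - mse) / (msr + (k - 1) * mse)
  expect_equal(icc(tab, type = "agreement")$icc, icc_a1_hand,
               tolerance = 1e-12)
  expect_equal(icc(tab, type = "consistency")$icc, icc_c1_hand,
               tolerance = 1e-12)

  # frozen reference values (pingouin 0.6.1, intraclass_corr on this table)
  a <- icc(tab, type = "agreement")
  expect_equal(a$icc, 0.9931390166915196, tolerance = 1e-9)
  expect_equal(icc(tab, type = "consistency")$icc, 0.9918075560552391,
               tolerance = 1e-9)
  expect_equal(a$p_value, 5.661804238029624e-11, tolerance = 1e-6)
  expect_equal(a$conf_low, 0.97, tolerance = 0.005)
  expect_equal(a$conf_high, 1.00, tolerance = 0.005)

  expect_error(icc(tab[1:4, ]), "5 subjects")
  expect_error(icc(tab["r1"]), "2 raters")
})

test_that("cronbach's alpha matches the closed form and the ICC(C,k) identity", {
  same <- tibble::tibble(a = c(3, 9, 5, 7, 1), b = c(3, 9, 5, 7, 1))
  expect_equal(cronbach_alpha(same), 1)

  withr::with_seed(301, {
    big <- tibble::tibble(a = rnorm(4000), b = rnorm(4000))
  })
  expect_lt(abs(cronbach_alpha(big)), 0.1)

  tab <- tibble::tibble(r1 = c(12, 8, 20, 15, 9),
                        r2 = c(11, 9, 19, 16, 9),
                        r3 = c(13, 7, 21, 14, 8))
  mat <- as.matrix(tab)
  alpha_hand <- 3 / 2 * (1 - sum(apply(mat, 2, var)) / var(rowSums(mat)))
  expect_equal(cronbach_alpha(tab), alpha_hand, tolerance = 1e-12)

  # identity with the average-measures consistency ICC from ANOVA sums
  grand <- mean(mat)
  msr <- 3 * sum((rowMeans(mat) - grand)^2) / 4
  mse <- (sum((mat - grand)^2) - 3 * sum((rowMeans(mat) - grand)^2) -
            5 * sum((colMeans(mat) - grand)^2)) / 8
  expect_equal(cronbach_alpha(tab), (msr - mse) / msr, tolerance = 1e-12)
})

test_that("bland-altman percent differences match hand computation", {
  ba0 <- bland_altman_percent(c(5, 8, 13), c(5, 8, 13))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_lower, 0)
  expect_equal(ba0$loa_upper, 0)

  y <- c(10, 20, 40, 80)
  ba_ratio <- bland_altman_percent(1.1 * y, y)
  expect_equal(ba_ratio$bias, 100 * 0.1 / 1.05, tolerance = 1e-12)
  expect_equal(ba_ratio$loa_lower, ba_ratio$bias, tolerance = 1e-9)
  expect_equal(ba_ratio$loa_upper, ba_ratio$bias, tolerance = 1e-9)

  x <- c(100, 120, 90, 150)
  yy <- c(104, 117, 95, 149)
  d_hand <- 100 * (x - yy) / ((x + yy) / 2)
  ba <- bland_altman_percent(x, yy)
  expect_equal(ba$pairs$percent_diff, d_hand, tolerance = 1e-12)
  expect_equal(ba$bias, mean(d_hand), tolerance = 1e-12)
  expect_equal(ba$loa_upper, mean(d_hand) + 1.96 * sd(d_hand),
               tolerance = 1e-12)
  expect_equal(ba$loa_lower, mean(d_hand) - 1.96 * sd(d_hand),
               tolerance = 1e-12)

  expect_warning(baz <- bland_altman_percent(c(0, 5, 8, 13),
                                             c(0, 5, 8, 13)),
                 "zero mean")
  expect_identical(baz$n_pairs, 3L)
})

test_that("paired t-tests match hand arithmetic including degenerate cases", {
  t0 <- paired_t(c(4, 7, 9), c(4, 7, 9))
  expect_equal(t0$t, 0)
  expect_equal(t0$p_value, 1)

  sym <- paired_t(c(2, 1, 4, 3), c(1, 2, 3, 4))
  expect_equal(sym$t, 0)

  x <- c(12, 15, 11, 19, 14)
  y <- c(10, 16, 9, 15, 12)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  got <- paired_t(x, y)
  expect_equal(got$t, t_hand, tolerance = 1e-6)
  expect_equal(got$p_value, p_hand, tolerance = 1e-6)
  expect_equal(got$conf_low, mean(d) - qt(0.975, 4) * sd(d) / sqrt(5),
               tolerance = 1e-6)

  inf <- paired_t(c(5, 6, 7), c(4, 5, 6))
  expect_identical(inf$t, Inf)
  expect_equal(inf$p_value, 0)
})

test_that("the full report is exact on perfect agreement and row-order invariant", {
  tab <- tibble::tibble(
    image_id = paste0("im", 1:8),
    operator1 = c(120, 80, 200, 150, 90, 110, 60, 170),
    operator2 = c(118, 85, 190, 155, 92, 108, 63, 165),
    operator3 = c(125, 78, 205, 148, 88, 115, 58, 172))
  tab$automated <- rowMeans(tab[c("operator1", "operator2", "operator3")])

  rep0 <- agreement_report(tab)
  g <- glance(rep0)
  expect_equal(g$pearson_r, 1, tolerance = 1e-12)
  expect_equal(g$ba_bias, 0, tolerance = 1e-12)
  expect_equal(g$t_p, 1)
  expect_equal(g$icc, 1, tolerance = 1e-12)

  perm <- tab[c(5, 1, 8, 2, 7, 3, 6, 4), ]
  g2 <- glance(agreement_report(perm))
  expect_equal(g2, g, tolerance = 1e-12)

  # pairwise r ordering with one discordant rater
  tab2 <- tibble::tibble(
    o1 = c(10, 20, 30, 40, 50, 60),
    o2 = c(11, 19, 31, 41, 49, 61),
    o3 = c(35, 12, 55, 20, 41, 28),
    automated = c(10, 21, 29, 40, 51, 59))
  tw <- tidy(agreement_report(tab2))
  r12 <- tw$pearson_r[tw$method_1 == "o1" & tw$method_2 == "o2"]
  r13 <- tw$pearson_r[tw$method_1 == "o1" & tw$method_2 == "o3"]
  expect_gt(r12, r13)
  expect_true(all(tw$r_squared == tw$pearson_r^2))
  expect_true(all(tw$ba_loa_lower <= tw$ba_bias &
                    tw$ba_bias <= tw$ba_loa_upper))

  path <- withr::local_tempfile(fileext = ".json")
  write_agreement_report(rep0, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(js$gold_standard, "mean_manual")
  expect_identical(nrow(js$pairwise), nrow(rep0$pairwise))

  expect_s3_class(autoplot(rep0), "ggplot")
})
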