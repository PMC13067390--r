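test_that("Cohen's d behaves at the null and under group swap", {
  d0 <- cohens_d(20, 5, 1, 25, 5, 1.2)
  expect_equal(d0$d, 0)
  expect_equal(d0$ci_low, -d0$ci_high)

  d1 <- cohens_d(30, 10, 2, 40, 8, 2.5)
  d2 <- cohens_d(40, 8, 2.5, 30, 10, 2)
  expect_equal(d1$d, -d2$d)
  expect_equal(d1$ci_low, -d2$ci_high)

  expect_error(cohens_d(10, 1, 0, 10, 1, 0), "pooled")
})

test_that("summary t-test matches stats::t.test on raw samples", {
  set.seed(10)
  for (rep in 1:5) {
    x <- rnorm(20, 1, 2)
    y <- rnorm(25, 0.5, 1.3)
    for (variant in c("student", "welch")) {
      for (alt in c("two.sided", "greater", "less")) {
        got <- t_test_summary(length(x), mean(x), sd(x),
                              length(y), mean(y), sd(y),
                              variant = variant, alternative = alt)
        ref <- t.test(x, y, var.equal = variant == "student",
                      alternative = alt)
        expect_equal(got$t, unname(ref$statistic), tolerance = 1e-8)
        expect_equal(got$df, unname(ref$parameter), tolerance = 1e-8)
        expect_equal(got$p, ref$p.value, tolerance = 1e-8)
      }
    }
  }
  # identical groups: t = 0, two-sided p = 1
  same <- t_test_summary(10, 3, 1, 12, 3, 1)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # Welch equals Student when n and s match
  a <- t_test_summary(15, 2, 1.5, 15, 1, 1.5, variant = "student")
  b <- t_test_summary(15, 2, 1.5, 15, 1, 1.5, variant = "welch")
  expect_equal(a$t, b$t)
  expect_equal(a$df, b$df)
})

test_that("auto variant switches to Welch only under variance heterogeneity", {
  set.seed(11)
  x <- rnorm(60, 0, 1)
  y <- rnorm(60, 0, 1)
  expect_equal(t_test_groups(x, y)$variant, "student")
  y_het <- rnorm(60, 0, 6)
  expect_equal(t_test_groups(x, y_het)$variant, "welch")
})

test_that("two-sided t-test holds its nominal type-I error rate", {
  set.seed(12)
  n_rep <- 10000
  n <- 15
  rejections <- 0L
  for (r in seq_len(n_rep)) {
    x <- rnorm(n); y <- rnorm(n)
    p <- t_test_summary(n, mean(x), sd(x), n, mean(y), sd(y))$p
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_equal(rejections / n_rep, 0.05, tolerance = 0.01 / 0.05)
})

test_that("Mann-Whitney U matches exact enumeration on small samples", {
  # complete separation: U = 0, minimal one-sided p
  x <- 1:4; y <- 5:9
  res <- mann_whitney_u(x, y, alternative = "less")
  expect_equal(unname(res$u), 0)
  expect_equal(res$p, 1 / choose(9, 4), tolerance = 1e-12)

  # identical multisets: two-sided p near 1
  expect_gt(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 0.95)

  set.seed(13)
  for (rep in 1:5) {
    x <- round(rnorm(5), 6); y <- round(rnorm(6) + 0.5, 6)
    for (alt in c("two.sided", "greater", "less")) {
      got <- mann_whitney_u(x, y, alternative = alt)
      expect_equal(got$p, oracle_mwu_exact(x, y, alt), tolerance = 1e-10)
    }
  }
})

test_that("chi-square tests follow the Pearson formula", {
  expect_equal(chi_square_gof(c(50, 50))$statistic, 0)
  # proportional rows give zero association
  expect_equal(chi_square_2x2(rbind(c(10, 20), c(30, 60)))$statistic, 0,
               tolerance = 1e-12)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(3, 4))), "margin")

  set.seed(14)
  for (rep in 1:5) {
    tab <- matrix(sample(5:40, 4), 2, 2)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi_square_2x2(tab)$statistic, sum((tab - e)^2 / e),
                 tolerance = 1e-12)
    counts <- sample(10:50, 3)
    ee <- rep(sum(counts) / 3, 3)
    expect_equal(chi_square_gof(counts)$statistic,
                 sum((counts - ee)^2 / ee), tolerance = 1e-12)
  }
})

test_that("reliability of an averaged measure follows the variance ratio", {
  # direct variance-ratio arithmetic: icc 0.2 -> sigma_w/sigma_b = 4,
  # halved within-variance gives 0.2/(0.2 + 0.8/2) = 1/3
  expect_equal(reliability_of_average(0.2, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(reliability_of_average(1, 5), 1)
  icc <- 0.37; m <- 3
  sigma_b <- icc; sigma_w <- 1 - icc
  expect_equal(reliability_of_average(icc, m),
               sigma_b / (sigma_b + sigma_w / m), tolerance = 1e-12)
})

test_that("Bonferroni screen thresholds at alpha/m", {
  expect_true(bonferroni_screen(0.0007, m = 66))
  expect_false(bonferroni_screen(0.01, m = 66))
  set.seed(15)
  p <- runif(100)
  expect_equal(bonferroni_screen(p, m = 66, alpha = 0.05), p < 0.05 / 66)
})

test_that("group comparison rows carry consistent statistics", {
  set.seed(16)
  vals <- c(rnorm(30, 1), rnorm(35, 0))
  sex <- rep(1:2, c(30, 35))
  row <- compare_groups(vals, sex, "demo")
  expect_equal(row$n_male, 30)
  expect_equal(row$mean_male, mean(vals[1:30]))
  expect_true(row$d_ci_low <= row$d & row$d <= row$d_ci_high)
  expect_gte(row$p_t, 0); expect_lte(row$p_t, 1)

  # swapping group labels negates t and d
  row_sw <- compare_groups(vals, 3 - sex, "demo")
  expect_equal(row_sw$t, -row$t, tolerance = 1e-12)
  expect_equal(row_sw$d, -row$d, tolerance = 1e-12)
  expect_equal(row_sw$p_t, row$p_t, tolerance = 1e-12)

  # NA values reduce the per-group n (unvisited-state exclusion pattern)
  vals_na <- vals; vals_na[c(1, 31)] <- NA
  row_na <- compare_groups(vals_na, sex, "demo")
  expect_equal(row_na$n_male, 29)
  expect_equal(row_na$n_female, 34)
})
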