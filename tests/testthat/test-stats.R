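test_that("the Shapiro-Wilk gate routes clean and skewed samples correctly", {
  t_count <- mw_count <- 0
  for (s in 1:200) {
    set.seed(s)
    t_count <- t_count + (normality_gate(rnorm(20), rnorm(20)) == "t")
    set.seed(s)
    mw_count <- mw_count + (normality_gate(rexp(20)^2, rexp(20)^2) == "wilcoxon")
  }
  # both-groups-normal rate is 0.95^2 = 0.9025 by design; allow binomial
  # error of a 200-draw estimate around the >= 90% design rate
  margin <- 2 * sqrt(0.9 * 0.1 / 200)
  expect_gte(t_count / 200, 0.90 - margin)
  expect_gte(mw_count / 200, 0.90 - margin)
  expect_error(normality_gate(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("group differences are controls minus cases with a pooled-t CI", {
  controls <- sample_with_moments(42.09, 5.77, 20)
  cases <- sample_with_moments(37.12, 5.41, 20)
  res <- group_difference(controls, cases)
  expect_equal(res$mean_difference, 42.09 - 37.12)
  expect_gt(res$mean_difference, 0)  # positive when controls exceed cases
  expect_lt(res$ci_low, res$mean_difference)
  expect_gt(res$ci_high, res$mean_difference)
  same <- group_difference(c(1, 2, 3, 4), c(1, 2, 3, 4), test = "t")
  expect_equal(same$mean_difference, 0)
  expect_gt(same$p_value, 0.99)
  expect_error(group_difference(numeric(0), 1:3), "empty")
})

test_that("the t branch matches a hand-computed pooled-t", {
  x <- c(3.1, 4.2, 5.0, 4.4, 3.8)
  y <- c(2.2, 2.9, 3.5, 3.1, 2.4)
  res <- group_difference(x, y, test = "t")
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 8
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 5))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 8))
  expect_equal(res$ci_low, (mean(x) - mean(y)) - qt(0.975, 8) * sqrt(sp2 * 2 / 5))
})

test_that("median/IQR comparison reports quartiles and the exact U statistic", {
  sym <- c(1, 2, 3, 4, 5)
  res <- median_iqr_compare(sym, sym + 1)
  expect_equal(res$control_median, mean(sym))
  res9 <- median_iqr_compare(1:9, 1:9)
  expect_equal(res9$control_median, 5)
  expect_equal(res9$control_q1, 3)
  expect_equal(res9$control_q3, 7)
  set.seed(11)
  x <- round(rnorm(15, 10, 3), 1)
  y <- round(rnorm(12, 9, 3), 1)
  expect_equal(median_iqr_compare(x, y)$u_statistic, oracle_u_stat(x, y))
})

test_that("Pearson tables match the closed form and flag degeneracies", {
  d <- data.frame(x = c(1, 2, 3, 4, 5), y = 2 * c(1, 2, 3, 4, 5) + 1)
  res <- pearson_matrix(d, "x", "y")
  expect_equal(res$r, 1.0)
  set.seed(2)
  d2 <- data.frame(x = rnorm(1000), y = rnorm(1000))
  expect_lt(abs(pearson_matrix(d2, "x", "y")$r), 0.1)
  d3 <- data.frame(x = c(2.1, 3.3, 1.8, 4.0, 2.9), y = c(5.5, 6.1, 5.0, 7.2, 6.0))
  r_hand <- sum((d3$x - mean(d3$x)) * (d3$y - mean(d3$y))) /
    sqrt(sum((d3$x - mean(d3$x))^2) * sum((d3$y - mean(d3$y))^2))
  expect_equal(pearson_matrix(d3, "x", "y")$r, r_hand)
  dz <- data.frame(x = rep(1, 5), y = rnorm(5))
  flagged <- pearson_matrix(dz, "x", "y")
  expect_true(is.na(flagged$r))
  expect_match(flagged$note, "zero variance")
  # stars at the conventional cutpoints
  expect_identical(octaquant:::p_stars(c(0.2, 0.04, 0.009, 0.0009)),
                   c("", "*", "**", "***"))
})

test_that("sample size search matches noncentral-t power and a MC oracle", {
  expect_identical(sample_size_two_means(1000, 1), 2L)
  n <- sample_size_two_means(18, 17, power = 0.80, alpha = 0.05)
  # Monte-Carlo oracle: empirical power at n and at n - 2
  mc_power <- function(n, delta, sd, B = 20000) {
    set.seed(99)
    x <- matrix(rnorm(n * B, delta, sd), n)
    y <- matrix(rnorm(n * B, 0, sd), n)
    mx <- colMeans(x); my <- colMeans(y)
    vx <- colSums((x - rep(mx, each = n))^2)
    vy <- colSums((y - rep(my, each = n))^2)
    sp2 <- (vx + vy) / (2 * n - 2)
    tt <- (mx - my) / sqrt(sp2 * 2 / n)
    mean(abs(tt) > qt(0.975, 2 * n - 2))
  }
  expect_gte(mc_power(n, 18, 17), 0.80 - 0.02)
  expect_lt(mc_power(n - 2L, 18, 17), 0.80)
  # halving the effect roughly quadruples the group size
  n_half <- sample_size_two_means(9, 17, power = 0.80)
  expect_lt(abs(n_half / n - 4), 0.25 * 4)
  expect_error(sample_size_two_means(-1, 17), "> 0")
})

test_that("the age-by-group interaction check has correct size and power", {
  rej <- 0
  B <- 500
  for (b in 1:B) {
    set.seed(b)
    d <- data.frame(group = rep(c("control", "case"), each = 20),
                    age = runif(40, 20, 60))
    d$y <- 5 + 2 * (d$group == "case") + 0.1 * d$age + rnorm(40)
    rej <- rej + (age_interaction_check(d, "y")$p_value < 0.05)
  }
  expect_lt(abs(rej / B - 0.05), 0.03)
  set.seed(1)
  d <- data.frame(group = rep(c("control", "case"), each = 20),
                  age = runif(40, 20, 60))
  d$y <- 5 + 0.1 * d$age + 1.0 * d$age * (d$group == "case") + rnorm(40)
  expect_lt(age_interaction_check(d, "y")$p_value, 0.001)
  d$age <- 50
  expect_error(age_interaction_check(d, "y"), "vary")
})

test_that("t-interval coverage of the simulated cohort difference is nominal", {
  hits <- 0
  B <- 300
  for (b in 1:B) {
    sp <- cohort_spec(n_controls = 10, n_cases = 10, seed = 40000 + b)
    tr <- generate_cohort(sp, render = "metrics")$truth
    x <- tr$vld[tr$plexus == "CC" & tr$region == "tight_central" & tr$group == "control"]
    y <- tr$vld[tr$plexus == "CC" & tr$region == "tight_central" & tr$group == "case"]
    res <- group_difference(x, y)
    true_diff <- cohort_spec()$vld_effect[["CC"]]
    hits <- hits + (res$ci_low <= true_diff && true_diff <= res$ci_high)
  }
  expect_gt(hits / B, 0.90)
  expect_lt(hits / B, 0.99)
})
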