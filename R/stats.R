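#' Normality-gated test choice
#'
#' Shapiro-Wilk is run per group; if both groups are compatible with
#' normality (p >= `alpha`) the pooled Student t-test is used, otherwise the
#' Mann-Whitney U-test.
#'
#' @param controls,cases numeric vectors (n >= 3 each).
#' @param alpha gate level for the Shapiro-Wilk tests.
#' @return `"t"` or `"wilcoxon"`.
#' @export
normality_gate <- function(controls, cases, alpha = 0.05) {
  if (length(controls) < 3 || length(cases) < 3) {
    stop("normality gate needs at least 3 observations per group")
  }
  sw <- function(x) {
    if (stats::sd(x) == 0) return(0)  # degenerate: clearly non-normal
    stats::shapiro.test(x)$p.value
  }
  if (sw(controls) >= alpha && sw(cases) >= alpha) "t" else "wilcoxon"
}

#' Two-group comparison with controls-minus-cases difference
#'
#' Reports group means with SDs, the mean difference oriented as controls
#' minus cases, a pooled-variance t confidence interval for that difference,
#' and a p-value from the gated test (pooled Student t or Mann-Whitney; the
#' gate can be overridden).
#'
#' @param controls,cases numeric vectors, each non-empty.
#' @param variable label carried into the output row.
#' @param test `"auto"` (Shapiro-Wilk gate), `"t"`, `"wilcoxon"`, or
#'   `"welch"` (unpooled t, available behind this flag).
#' @param conf_level confidence level of the t interval.
#' @return a one-row tibble (class `comparison_result`).
#' @export
group_difference <- function(controls, cases, variable = "value",
                             test = c("auto", "t", "wilcoxon", "welch"),
                             conf_level = 0.95) {
  test <- match.arg(test)
  if (length(controls) == 0 || length(cases) == 0) stop("empty group")
  if (test == "auto") test <- normality_gate(controls, cases)
  n1 <- length(controls)
  n2 <- length(cases)
  m1 <- mean(controls)
  m2 <- mean(cases)
  diff <- m1 - m2
  df <- n1 + n2 - 2
  sp2 <- (sum((controls - m1)^2) + sum((cases - m2)^2)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se > 0) {
    tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
    ci <- diff + c(-1, 1) * tcrit * se
  } else {
    ci <- c(diff, diff)
  }
  p <- if (se == 0) {
    if (diff == 0) 1 else 0
  } else if (test == "t") {
    stats::t.test(controls, cases, var.equal = TRUE)$p.value
  } else if (test == "welch") {
    stats::t.test(controls, cases)$p.value
  } else {
    stats::wilcox.test(controls, cases, exact = FALSE)$p.value
  }
  out <- tibble::tibble(
    variable = variable, n_controls = n1, n_cases = n2,
    control_mean = m1, control_sd = stats::sd(controls),
    case_mean = m2, case_sd = stats::sd(cases),
    mean_difference = diff, ci_low = ci[1], ci_high = ci[2],
    p_value = p, test = test
  )
  class(out) <- c("comparison_result", class(out))
  out
}

#' Median/IQR comparison (Mann-Whitney)
#'
#' For variables reported as median and interquartile range: returns group
#' medians with IQR bounds, the Mann-Whitney U statistic and its p-value.
#'
#' @param controls,cases numeric vectors.
#' @param variable label for the output row.
#' @return a one-row tibble.
#' @export
median_iqr_compare <- function(controls, cases, variable = "value") {
  if (length(controls) == 0 || length(cases) == 0) stop("empty group")
  q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  qc <- q(controls)
  qs <- q(cases)
  w <- stats::wilcox.test(controls, cases, exact = FALSE)
  tibble::tibble(
    variable = variable,
    control_median = qc[2], control_q1 = qc[1], control_q3 = qc[3],
    case_median = qs[2], case_q1 = qs[1], case_q3 = qs[3],
    u_statistic = unname(w$statistic), p_value = w$p.value,
    test = "wilcoxon"
  )
}

# significance stars at 0.05 / 0.01 / 0.001
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pearson correlation table
#'
#' Correlates every `x_vars` column with every `y_vars` column, optionally
#' within groups, and stars p-values at 0.05 / 0.01 / 0.001. Zero-variance
#' variables are flagged (`r` is `NA`) rather than dropped.
#'
#' @param data a data frame.
#' @param x_vars,y_vars column names to correlate.
#' @param group optional grouping column name.
#' @return a tibble with `x`, `y` (, `group`), `n`, `r`, `p_value`, `stars`,
#'   `note`.
#' @export
pearson_matrix <- function(data, x_vars, y_vars, group = NULL) {
  groups <- if (is.null(group)) list(all = data) else split(data, data[[group]])
  rows <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    for (xv in x_vars) for (yv in y_vars) {
      x <- d[[xv]]
      y <- d[[yv]]
      ok <- stats::complete.cases(x, y)
      x <- x[ok]
      y <- y[ok]
      n <- length(x)
      if (n < 3) stop(sprintf("pearson_matrix: fewer than 3 complete pairs for %s ~ %s", xv, yv))
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        row <- tibble::tibble(x = xv, y = yv, group = g, n = n, r = NA_real_,
                              p_value = NA_real_, stars = "",
                              note = "zero variance")
      } else {
        ct <- stats::cor.test(x, y, method = "pearson")
        row <- tibble::tibble(x = xv, y = yv, group = g, n = n,
                              r = unname(ct$estimate), p_value = ct$p.value,
                              stars = p_stars(ct$p.value), note = "")
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(group)) out$group <- NULL
  out
}

#' Sample size for a two-sample t-test
#'
#' Smallest integer group size `n` such that the pooled two-sample t-test at
#' level `alpha` reaches the requested power against a mean difference
#' `delta` with common standard deviation `sd`, using the noncentral-t
#' distribution of the test statistic.
#'
#' @param delta true mean difference (> 0).
#' @param sd common (pooled) standard deviation (> 0).
#' @param power target power in (0, 1).
#' @param alpha two-sided significance level.
#' @return n per group (integer >= 2).
#' @export
sample_size_two_means <- function(delta, sd, power = 0.8, alpha = 0.05) {
  if (!is.finite(delta) || delta <= 0) stop("`delta` must be > 0")
  if (!is.finite(sd) || sd <= 0) stop("`sd` must be > 0")
  if (power <= 0 || power >= 1) stop("`power` must be in (0, 1)")
  pow <- function(n) {
    df <- 2 * n - 2
    ncp <- delta / (sd * sqrt(2 / n))
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp = ncp)
  }
  n <- 2L
  while (pow(n) < power) {
    n <- n + 1L
    if (n > 1e6) stop("sample size search did not converge")
  }
  n
}

#' Attained power of the two-sample t-test
#'
#' Noncentral-t power of the pooled two-sided test at group size `n`.
#'
#' @inheritParams sample_size_two_means
#' @param n group size (>= 2).
#' @return power in (0, 1).
#' @export
t_test_power <- function(n, delta, sd, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- delta / (sd * sqrt(2 / n))
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) + stats::pt(-crit, df, ncp = ncp)
}

#' Age-by-group interaction check
#'
#' Fits `outcome ~ group + age + group:age` and returns the p-value of the
#' interaction term, a simple check that the group effect is not an age
#' artifact.
#'
#' @param data a data frame with `group` and `age` columns.
#' @param outcome outcome column name.
#' @param group_col,age_col column names.
#' @return list with `p_value`, `estimate` and the fitted `model`.
#' @export
age_interaction_check <- function(data, outcome, group_col = "group",
                                  age_col = "age") {
  g <- factor(data[[group_col]])
  if (nlevels(g) != 2) stop("exactly two groups required")
  ages <- split(data[[age_col]], g)
  if (any(vapply(ages, function(a) length(unique(a)) < 2, logical(1)))) {
    stop("age must vary within both groups")
  }
  d <- data.frame(y = data[[outcome]], group = g, age = data[[age_col]])
  fit <- stats::lm(y ~ group * age, data = d)
  co <- summary(fit)$coefficients
  term <- grep(":age$", rownames(co), value = TRUE)
  if (length(term) != 1 || anyNA(co[term, ])) stop("collinear design: interaction not estimable")
  list(p_value = co[term, "Pr(>|t|)"], estimate = co[term, "Estimate"], model = fit)
}

#' Tables-style group comparison over many variables
#'
#' Runs [group_difference()] (with the Shapiro-Wilk gate) for each variable
#' of a per-eye table and stacks the rows, mirroring a
#' "Controls / Cases / Mean difference (95% CI) / p" reporting table.
#'
#' @param table data frame with a group column and numeric variables.
#' @param variables character vector of column names to compare.
#' @param group_col grouping column; must contain `control_label` and
#'   `case_label`.
#' @param control_label,case_label group labels.
#' @return a tibble with one row per variable.
#' @export
compare_groups <- function(table, variables, group_col = "group",
                           control_label = "control", case_label = "case") {
  g <- table[[group_col]]
  if (!all(c(control_label, case_label) %in% g)) {
    stop("both group labels must be present")
  }
  rows <- lapply(variables, function(v) {
    group_difference(table[[v]][g == control_label],
                     table[[v]][g == case_label], variable = v)
  })
  do.call(rbind, rows)
}
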