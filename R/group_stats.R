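#' Cohen's d with 95% confidence interval from group summaries
#'
#' Standardized mean difference `d = (m1 - m2) / s_pooled` with the pooled
#' standard deviation
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' Group 1 is conventionally the male group so the sign follows the
#' "males minus females" convention of the result tables. The confidence
#' interval uses the normal-approximation standard error
#' `sqrt((n1+n2)/(n1 n2) + d^2 / (2 (n1+n2)))`; a noncentral-t interval is
#' available via `method = "noncentral"`.
#'
#' @param n1,m1,s1 size, mean and SD of group 1 (males).
#' @param n2,m2,s2 size, mean and SD of group 2 (females).
#' @param conf confidence level (default 0.95).
#' @param method `"normal"` (default) or `"noncentral"` CI.
#' @return list with `d`, `ci_low`, `ci_high`.
#' @export
cohens_d <- function(n1, m1, s1, n2, m2, s2, conf = 0.95,
                     method = c("normal", "noncentral")) {
  method <- match.arg(method)
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  d <- (m1 - m2) / sp
  if (method == "normal") {
    se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
    zc <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- c(d - zc * se, d + zc * se)
  } else {
    ## invert the noncentral-t CDF for the noncentrality parameter
    scale <- sqrt(1 / n1 + 1 / n2)
    tobs <- d / scale
    df <- n1 + n2 - 2
    lo <- stats::uniroot(function(ncp) stats::pt(tobs, df, ncp) - (1 + conf) / 2,
                         interval = tobs + c(-10, 10) * (abs(tobs) + 1))$root
    hi <- stats::uniroot(function(ncp) stats::pt(tobs, df, ncp) - (1 - conf) / 2,
                         interval = tobs + c(-10, 10) * (abs(tobs) + 1))$root
    ci <- c(lo, hi) * scale
  }
  list(d = d, ci_low = ci[1], ci_high = ci[2])
}

#' Two-sample t-test from group summaries
#'
#' Student (pooled variance, `df = n1 + n2 - 2`) or Welch (Satterthwaite df)
#' t-test computed from `(n, mean, sd)` summaries, so printed table rows can
#' be recomputed without raw data. One-sided alternatives halve the matching
#' tail: `"greater"` tests m1 > m2, `"less"` tests m1 < m2.
#'
#' @param n1,m1,s1,n2,m2,s2 group summaries (group 1 minus group 2).
#' @param variant `"student"` or `"welch"`.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return list with `t`, `df`, `p`.
#' @export
t_test_summary <- function(n1, m1, s1, n2, m2, s2,
                           variant = c("student", "welch"),
                           alternative = c("two.sided", "greater", "less")) {
  variant <- match.arg(variant)
  alternative <- match.arg(alternative)
  stopifnot(n1 >= 2, n2 >= 2)
  if (s1 == 0 && s2 == 0) stop("zero variance in both groups")
  if (variant == "student") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tval <- (m1 - m2) / se
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(tval), df),
    greater = stats::pt(tval, df, lower.tail = FALSE),
    less = stats::pt(tval, df)
  )
  list(t = tval, df = df, p = p)
}

#' Two-sample t-test on raw samples
#'
#' Wrapper over [stats::t.test()] returning the same fields as
#' [t_test_summary()]. With `variant = "auto"` the Student test is used
#' unless a Brown-Forsythe test of variance homogeneity
#' ([car::leveneTest()], center = median) rejects at `levene_alpha`, in
#' which case Welch is used.
#'
#' @param x,y numeric samples (x = males, y = females by convention).
#' @param variant `"auto"`, `"student"` or `"welch"`.
#' @param alternative passed to [stats::t.test()].
#' @param levene_alpha switch threshold for `"auto"` (default 0.05).
#' @return list with `t`, `df`, `p`, `variant` actually used.
#' @export
t_test_groups <- function(x, y, variant = c("auto", "student", "welch"),
                          alternative = c("two.sided", "greater", "less"),
                          levene_alpha = 0.05) {
  variant <- match.arg(variant)
  alternative <- match.arg(alternative)
  if (variant == "auto") {
    lev <- car::leveneTest(
      c(x, y), factor(rep(c("x", "y"), c(length(x), length(y)))),
      center = stats::median
    )
    variant <- if (lev[["Pr(>F)"]][1] < levene_alpha) "welch" else "student"
  }
  ht <- stats::t.test(x, y, var.equal = variant == "student",
                      alternative = alternative)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, variant = variant)
}

#' Mann-Whitney U test
#'
#' Rank-sum test via [stats::wilcox.test()]: exact when `n1 * n2 <= 400` and
#' there are no ties, otherwise the tie-corrected normal approximation with
#' continuity correction. The reported U is the number of (x, y) pairs with
#' x > y (R's W statistic).
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return list with `u` and `p`.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1, length(y) >= 1)
  exact <- length(x) * length(y) <= 400 && !any(duplicated(c(x, y)))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  list(u = unname(ht$statistic), p = ht$p.value)
}

#' Chi-square goodness-of-fit against an equal split
#'
#' Pearson `sum((O - E)^2 / E)` with equal expected counts and
#' `df = k - 1`, no continuity correction — the sex-balance test within a
#' dataset (e.g. 34 males vs 29 females -> 0.397).
#'
#' @param counts vector of category counts (length >= 2).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_gof <- function(counts) {
  stopifnot(length(counts) >= 2, all(counts >= 0), sum(counts) > 0)
  ht <- stats::chisq.test(counts)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Pearson chi-square on a 2x2 table
#'
#' No Yates continuity correction — the between-dataset sex-balance test
#' (e.g. rows = datasets, columns = sexes).
#'
#' @param tab 2x2 matrix of nonnegative counts with positive margins.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in 2x2 table")
  }
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Reliability of an m-session average (Spearman-Brown)
#'
#' If a single session has intra-class correlation `icc_single`
#' (`sigma_b / (sigma_b + sigma_w)`), averaging m sessions reduces the
#' within-subject variance by a factor of m, giving
#' `m * icc / (1 + (m - 1) * icc)`; e.g. ICC 0.5 over two sessions rises
#' to 0.67.
#'
#' @param icc_single single-session ICC in (0, 1).
#' @param m number of averaged sessions (default 2).
#' @return ICC of the m-session average.
#' @export
reliability_of_average <- function(icc_single, m = 2) {
  stopifnot(icc_single > 0, icc_single <= 1, m >= 1)
  m * icc_single / (1 + (m - 1) * icc_single)
}

#' Bonferroni screen
#'
#' Passes the p-values that stay below `alpha / m` — the conservative screen
#' applied over the 66 behavioral parameters before mediation.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param m number of tests corrected for (default 66).
#' @param alpha family-wise level (default 0.05).
#' @return logical vector, `TRUE` where `p < alpha / m`.
#' @export
bonferroni_screen <- function(p_values, m = 66, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1), m >= 1)
  p_values < alpha / m
}

#' Full group comparison of one parameter
#'
#' Computes the whole comparison row used in the results tables: per-sex n,
#' mean, SD and median; the t-test (males minus females, Student/Welch by
#' the auto rule unless overridden); the Mann-Whitney U p-value; and
#' Cohen's d with its 95% CI. Missing values are dropped per group (this
#' reproduces the differing Ns across parameters when a state is unvisited).
#'
#' @param values numeric per-subject parameter values (NA allowed).
#' @param sex integer codes (1 = male, 2 = female).
#' @param parameter label for the output row.
#' @param variant t-test variant (`"auto"`, `"student"`, `"welch"`).
#' @param alternative sidedness; `"greater"`/`"less"` refer to males minus
#'   females.
#' @return one-row data.frame mirroring the result-table column structure.
#' @export
compare_groups <- function(values, sex, parameter = "parameter",
                           variant = "auto", alternative = "two.sided") {
  stopifnot(length(values) == length(sex), all(sex %in% 1:2))
  x <- values[sex == 1 & !is.na(values)]
  y <- values[sex == 2 & !is.na(values)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  tt <- t_test_groups(x, y, variant = variant, alternative = alternative)
  mw <- mann_whitney_u(x, y, alternative = alternative)
  dd <- cohens_d(length(x), mean(x), stats::sd(x),
                 length(y), mean(y), stats::sd(y))
  data.frame(
    parameter = parameter,
    n_male = length(x), mean_male = mean(x), sd_male = stats::sd(x),
    median_male = stats::median(x),
    n_female = length(y), mean_female = mean(y), sd_female = stats::sd(y),
    median_female = stats::median(y),
    t = tt$t, df = tt$df, p_t = tt$p, test_variant = tt$variant,
    sidedness = alternative,
    u = mw$u, p_u = mw$p,
    d = dd$d, d_ci_low = dd$ci_low, d_ci_high = dd$ci_high
  )
}

#' Compare a table of parameters between sexes
#'
#' Applies [compare_groups()] to every requested column of a per-subject
#' table, with optional per-parameter sidedness for directional hypotheses
#' (all others two-sided, uncorrected: the comparisons are treated as tests
#' of independent hypotheses).
#'
#' @param data per-subject data.frame including a `sex` column.
#' @param parameters character vector of column names to compare.
#' @param one_sided named character vector mapping a parameter to
#'   `"greater"` or `"less"` (males minus females).
#' @param variant t-test variant passed through.
#' @return data.frame with one row per parameter.
#' @export
compare_table <- function(data, parameters,
                          one_sided = character(), variant = "auto") {
  rows <- lapply(parameters, function(p) {
    alt <- if (p %in% names(one_sided)) unname(one_sided[[p]]) else "two.sided"
    compare_groups(data[[p]], data$sex, parameter = p,
                   variant = variant, alternative = alt)
  })
  do.call(rbind, rows)
}
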