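#' Standardize a variable to unit variance
#'
#' Centers and scales to sample variance 1, as applied to the dependent
#' measures and the integration mediator before the path model (sex keeps
#' its 1 = male / 2 = female coding and is not standardized).
#'
#' @param x numeric vector with positive variance.
#' @return standardized vector.
#' @export
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant variable")
  (x - mean(x)) / s
}

#' Screen behavioral variables for mediation candidacy
#'
#' A dependent variable is a mediation candidate when its Pearson
#' correlation with sex and its correlation with the integration mediator
#' are both significant after Bonferroni correction over `m` parameters
#' (p < alpha/m). For a binary sex code the correlation test is equivalent
#' to the pooled two-sample t-test, so screening on the correlation p-value
#' screens on the t-test p-value as well. Constant variables are skipped
#' with a warning; rows with missing values are dropped per variable
#' (complete-case).
#'
#' @param behavior data.frame of dependent variables (columns).
#' @param sex integer codes (1 = male, 2 = female).
#' @param mediator numeric integration measure per subject.
#' @param m number of parameters corrected for (default 66).
#' @param alpha family-wise level (default 0.05).
#' @return data.frame with one row per variable: correlations, p-values,
#'   and a logical `candidate`.
#' @export
screen_mediation <- function(behavior, sex, mediator, m = 66, alpha = 0.05) {
  stopifnot(nrow(behavior) == length(sex), length(mediator) == length(sex))
  out <- lapply(names(behavior), function(v) {
    y <- behavior[[v]]
    ok <- !is.na(y) & !is.na(sex) & !is.na(mediator)
    if (stats::sd(y[ok]) == 0) {
      warning("skipping constant variable: ", v)
      return(NULL)
    }
    ct_sex <- stats::cor.test(y[ok], sex[ok])
    ct_med <- stats::cor.test(y[ok], mediator[ok])
    data.frame(
      variable = v, n = sum(ok),
      r_sex = unname(ct_sex$estimate), p_sex = ct_sex$p.value,
      r_mediator = unname(ct_med$estimate), p_mediator = ct_med$p.value,
      candidate = bonferroni_screen(ct_sex$p.value, m, alpha) &&
        bonferroni_screen(ct_med$p.value, m, alpha)
    )
  })
  do.call(rbind, out)
}

## Closed-form OLS paths for the single-mediator model:
##   M ~ sex          -> a
##   Y ~ sex + M      -> c', b
##   Y ~ sex          -> c (total)
## Centered cross-products; algebraically identical to lm().
ols_paths <- function(sex, mediator, outcome) {
  x <- sex - mean(sex)
  m <- mediator - mean(mediator)
  y <- outcome - mean(outcome)
  sxx <- sum(x^2)
  smm <- sum(m^2)
  sxm <- sum(x * m)
  sxy <- sum(x * y)
  smy <- sum(m * y)
  det <- sxx * smm - sxm^2
  if (sxx == 0 || det <= 1e-12 * sxx * smm) {
    stop("collinear sex/mediator: path model is not identified")
  }
  a <- sxm / sxx
  c_prime <- (smm * sxy - sxm * smy) / det
  b <- (sxx * smy - sxm * sxy) / det
  c_total <- sxy / sxx
  list(a = a, b = b, c_prime = c_prime, c_total = c_total)
}

#' Fit the mediation path model
#'
#' Ordinary least squares estimates of the three regressions of the
#' single-mediator model: path a from `mediator ~ sex`, paths b and c'
#' (direct effect) from `outcome ~ sex + mediator`, and the total effect c
#' from `outcome ~ sex`. For OLS these satisfy the exact decomposition
#' `c = c' + a * b`.
#'
#' @param sex integer codes (1 = male, 2 = female), not standardized.
#' @param mediator,outcome numeric vectors; standardized to variance 1
#'   unless `standardized = FALSE`.
#' @param standardized standardize mediator and outcome first (default TRUE).
#' @return list with `a`, `b`, `c_prime`, `c_total`, `indirect_ab`.
#' @export
fit_paths <- function(sex, mediator, outcome, standardized = TRUE) {
  stopifnot(length(sex) == length(mediator),
            length(sex) == length(outcome))
  if (standardized) {
    mediator <- standardize(mediator)
    outcome <- standardize(outcome)
  }
  paths <- ols_paths(sex, mediator, outcome)
  paths$indirect_ab <- paths$a * paths$b
  paths
}

#' Bootstrap mediation analysis
#'
#' Point estimates from [fit_paths()] on the full sample; the indirect
#' effect `a * b` gets a 95% percentile confidence interval from
#' `n_boot` bootstrap resamples of subjects (paths refit per resample;
#' variables are standardized once on the analysis sample, not
#' re-standardized within resamples). The effect is reported significant
#' when the CI excludes zero. Resamples with constant sex are redrawn
#' (counted), aborting after `100 * n_boot` attempts.
#'
#' @param sex integer codes (1 = male, 2 = female).
#' @param mediator,outcome numeric vectors (standardized internally).
#' @param n_boot number of bootstrap resamples (default 5000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return object of class `mediation_result`: paths, `indirect_ab`,
#'   `ci_low`, `ci_high`, `n_boot`, `n_redraws`, `significant`.
#' @export
bootstrap_indirect <- function(sex, mediator, outcome, n_boot = 5000,
                               seed = 1L, conf = 0.95) {
  n <- length(sex)
  stopifnot(n >= 30, length(mediator) == n, length(outcome) == n)
  m_std <- standardize(mediator)
  y_std <- standardize(outcome)
  est <- fit_paths(sex, m_std, y_std, standardized = FALSE)

  boot_ab <- with_seed(seed, {
    ab <- numeric(n_boot)
    n_redraws <- 0L
    max_attempts <- 100 * n_boot
    attempts <- 0L
    filled <- 0L
    while (filled < n_boot) {
      ## vectorized block of resamples via closed-form OLS on column sums
      block <- min(n_boot - filled, 1000L)
      idx <- matrix(sample.int(n, n * block, replace = TRUE), n, block)
      xs <- matrix(sex[idx], n, block)
      ms <- matrix(m_std[idx], n, block)
      ys <- matrix(y_std[idx], n, block)
      xs <- sweep(xs, 2, colMeans(xs))
      ms <- sweep(ms, 2, colMeans(ms))
      ys <- sweep(ys, 2, colMeans(ys))
      sxx <- colSums(xs^2)
      smm <- colSums(ms^2)
      sxm <- colSums(xs * ms)
      smy <- colSums(ms * ys)
      sxy <- colSums(xs * ys)
      det <- sxx * smm - sxm^2
      valid <- sxx > 0 & det > 0
      attempts <- attempts + block
      n_redraws <- n_redraws + sum(!valid)
      if (attempts > max_attempts) {
        stop("too many degenerate bootstrap resamples (constant sex)")
      }
      a_b <- sxm[valid] / sxx[valid]
      b_b <- (sxx[valid] * smy[valid] - sxm[valid] * sxy[valid]) / det[valid]
      take <- min(sum(valid), n_boot - filled)
      ab[filled + seq_len(take)] <- (a_b * b_b)[seq_len(take)]
      filled <- filled + take
    }
    attr(ab, "n_redraws") <- n_redraws
    ab
  })

  alpha <- 1 - conf
  ci <- unname(stats::quantile(boot_ab, c(alpha / 2, 1 - alpha / 2),
                               type = 6))
  structure(
    list(a = est$a, b = est$b, c_prime = est$c_prime, c_total = est$c_total,
         indirect_ab = est$indirect_ab,
         ci_low = ci[1], ci_high = ci[2],
         n_boot = n_boot, n_redraws = attr(boot_ab, "n_redraws"),
         significant = ci[1] > 0 || ci[2] < 0),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation (n_boot = %d)\n", x$n_boot))
  cat(sprintf("  a (sex -> mediator)        : % .4f\n", x$a))
  cat(sprintf("  b (mediator -> outcome)    : % .4f\n", x$b))
  cat(sprintf("  c' (direct effect)         : % .4f\n", x$c_prime))
  cat(sprintf("  c (total effect)           : % .4f\n", x$c_total))
  cat(sprintf("  a*b (indirect) [95%% CI]    : % .4f [% .4f, % .4f]%s\n",
              x$indirect_ab, x$ci_low, x$ci_high,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Screen-then-mediate over a behavioral table
#'
#' Runs [screen_mediation()] and then [bootstrap_indirect()] for every
#' candidate variable; no correction is applied across the mediation
#' analyses themselves.
#'
#' @param behavior data.frame of dependent variables.
#' @param sex integer codes (1 = male, 2 = female).
#' @param mediator integration measure per subject (e.g. Prev_I).
#' @param m,alpha screening parameters (defaults 66, 0.05).
#' @param n_boot bootstrap resamples per candidate (default 5000).
#' @param seed integer seed.
#' @return list with `screen` (the screening table) and `results`
#'   (data.frame of path estimates and CIs, one row per candidate).
#' @export
mediate_table <- function(behavior, sex, mediator, m = 66, alpha = 0.05,
                          n_boot = 5000, seed = 1L) {
  scr <- screen_mediation(behavior, sex, mediator, m, alpha)
  cand <- scr$variable[scr$candidate]
  rows <- lapply(seq_along(cand), function(i) {
    v <- cand[i]
    ok <- !is.na(behavior[[v]]) & !is.na(sex) & !is.na(mediator)
    res <- bootstrap_indirect(sex[ok], mediator[ok], behavior[[v]][ok],
                              n_boot = n_boot, seed = seed + i)
    data.frame(variable = v, a = res$a, b = res$b, c_prime = res$c_prime,
               c_total = res$c_total, indirect_ab = res$indirect_ab,
               ci_low = res$ci_low, ci_high = res$ci_high,
               significant = res$significant)
  })
  list(screen = scr,
       results = if (length(rows)) do.call(rbind, rows) else NULL)
}
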