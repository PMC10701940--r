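#' Group summary statistics
#'
#' Container for method-comparison inputs given as printed summary rows
#' (mean recovery, standard deviation, replicate count).
#'
#' @param mean Group mean (typically percent recovery).
#' @param sd Standard deviation.
#' @param n Number of observations (>= 2).
#' @return Object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  if (n < 2) stop("n must be >= 2")
  if (sd < 0) stop("sd must be non-negative")
  structure(list(mean = mean, sd = sd, variance = sd^2, n = n),
            class = "group_summary")
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance (equal-variance) test by default, matching the usual
#' pairing with a preceding variance-ratio F test; Welch's approximation
#' is available with `var_equal = FALSE`.  The statistic is reported as an
#' absolute value with a two-tailed p and the two-tailed critical value.
#'
#' @param a,b [group_summary()] objects.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pool the variances (default `TRUE`).
#' @return List with `t`, `df`, `p`, `t_crit`.
#' @export
#' @examples
#' t_test_from_summary(group_summary(100.93, 0.86, 6),
#'                     group_summary(101.85, 0.48, 6))
t_test_from_summary <- function(a, b, alpha = 0.05, var_equal = TRUE) {
  if (var_equal) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$variance + (b$n - 1) * b$variance) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$variance / a$n; vb <- b$variance / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- abs(a$mean - b$mean) / se
  list(t = t, df = df, p = 2 * pt(-t, df), t_crit = critical_t(alpha, df))
}

#' Variance-ratio F test from summary statistics
#'
#' `F = larger variance / smaller variance` with the corresponding degrees
#' of freedom; p is the upper-tail probability and the critical value the
#' upper `alpha` quantile, the convention used in pharmaceutical method
#' comparison.
#'
#' @inheritParams t_test_from_summary
#' @return List with `f` (>= 1), `df` (numerator, denominator), `p`,
#'   `f_crit`.
#' @export
f_ratio_test <- function(a, b, alpha = 0.05) {
  if (min(a$variance, b$variance) == 0) stop("zero variance in denominator")
  if (a$variance >= b$variance) {
    f <- a$variance / b$variance; df <- c(a$n - 1, b$n - 1)
  } else {
    f <- b$variance / a$variance; df <- c(b$n - 1, a$n - 1)
  }
  list(f = f, df = df, p = pf(f, df[1], df[2], lower.tail = FALSE),
       f_crit = critical_f(alpha, df[1], df[2]))
}

#' One-way ANOVA table from printed sums of squares
#'
#' Rebuilds the mean squares, F statistic, p value and critical value from
#' the between/within sums of squares and degrees of freedom as printed in
#' a summary ANOVA table.
#'
#' @param ss_between,df_between Between-groups sum of squares / df.
#' @param ss_within,df_within Within-groups sum of squares / df.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `anova_table`: `ss_between`, `df_between`,
#'   `ms_between`, `ss_within`, `df_within`, `ms_within`, `f`, `p`,
#'   `f_crit`.
#' @export
#' @examples
#' anova_from_summary(8.83, 4, 22.74, 25)
anova_from_summary <- function(ss_between, df_between, ss_within, df_within,
                               alpha = 0.05) {
  if (ss_between < 0 || ss_within < 0) stop("sums of squares must be non-negative")
  if (df_between < 1 || df_within < 1) stop("degrees of freedom must be positive")
  ms_b <- ss_between / df_between
  ms_w <- ss_within / df_within
  if (ss_between == 0) {
    f <- 0; p <- 1
  } else if (ms_w == 0) {
    f <- Inf; p <- 0
  } else {
    f <- ms_b / ms_w
    p <- pf(f, df_between, df_within, lower.tail = FALSE)
  }
  structure(list(ss_between = ss_between, df_between = df_between,
                 ms_between = ms_b, ss_within = ss_within,
                 df_within = df_within, ms_within = ms_w,
                 f = f, p = p,
                 f_crit = critical_f(alpha, df_between, df_within)),
            class = "anova_table")
}

#' One-way ANOVA from raw group observations
#'
#' Direct sum-of-squares decomposition (computationally cheap, so large
#' simulation studies of the test's size are feasible); the resulting
#' table is identical to [anova_from_summary()] applied to its own sums of
#' squares, and agrees with `stats::aov`.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha Significance level (default 0.05).
#' @return An `anova_table`, see [anova_from_summary()].
#' @export
#' @examples
#' set.seed(1)
#' anova_oneway(replicate(5, rnorm(6, 100, 1), simplify = FALSE))
anova_oneway <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("each group needs at least 2 observations")
  all_obs <- unlist(groups)
  grand <- mean(all_obs)
  means <- vapply(groups, mean, 0)
  ss_b <- sum(sizes * (means - grand)^2)
  ss_w <- sum(vapply(seq_along(groups), function(g)
    sum((groups[[g]] - means[g])^2), 0))
  # guard: identical data in all groups
  if (ss_b == 0 && ss_w == 0) {
    return(structure(list(ss_between = 0, df_between = length(groups) - 1,
                          ms_between = 0, ss_within = 0,
                          df_within = length(all_obs) - length(groups),
                          ms_within = 0, f = 0, p = 1,
                          f_crit = critical_f(alpha, length(groups) - 1,
                                              length(all_obs) - length(groups))),
                     class = "anova_table"))
  }
  anova_from_summary(ss_b, length(groups) - 1, ss_w,
                     length(all_obs) - length(groups), alpha)
}

#' @export
print.anova_table <- function(x, ...) {
  cat("One-way ANOVA\n")
  cat(sprintf("  Between groups: SS %.4g, df %d, MS %.4g\n",
              x$ss_between, x$df_between, x$ms_between))
  cat(sprintf("  Within groups:  SS %.4g, df %d, MS %.4g\n",
              x$ss_within, x$df_within, x$ms_within))
  cat(sprintf("  F = %.4g, p = %.4g, F-crit = %.4g\n", x$f, x$p, x$f_crit))
  invisible(x)
}

#' Critical values of the t and F distributions
#'
#' `critical_t` returns the two-tailed t quantile `qt(1 - alpha/2, df)`;
#' `critical_f` the upper-tail F quantile `qf(1 - alpha, df1, df2)`.
#'
#' @param alpha Significance level.
#' @param df,df1,df2 Degrees of freedom.
#' @return Critical value.
#' @export
#' @examples
#' round(critical_t(0.05, 10), 2)    # 2.23
#' round(critical_f(0.05, 5, 5), 2)  # 5.05
critical_t <- function(alpha, df) qt(1 - alpha / 2, df)

#' @rdname critical_t
#' @export
critical_f <- function(alpha, df1, df2) qf(1 - alpha, df1, df2)
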