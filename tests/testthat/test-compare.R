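test_that("pooled t test from summaries matches hand arithmetic", {
  a <- group_summary(100.93, 0.86, 6)
  b <- group_summary(101.85, 0.48, 6)
  res <- t_test_from_summary(a, b)
  # hand: sp2 = (5*0.86^2 + 5*0.48^2)/10; t = 0.92/sqrt(sp2/3)
  sp2 <- (5 * 0.86^2 + 5 * 0.48^2) / 10
  expect_equal(res$t, 0.92 / sqrt(sp2 * (2 / 6)), tolerance = 1e-12)
  expect_equal(round(res$t, 2), 2.29)
  expect_equal(res$df, 10)
  expect_equal(round(res$t_crit, 2), 2.23)
  ident <- t_test_from_summary(a, a)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(group_summary(100, 1, 1), ">= 2")
})

test_that("variance-ratio F test puts the larger variance on top", {
  a <- group_summary(100.93, sqrt(0.74), 6)
  b <- group_summary(101.85, sqrt(0.23), 6)
  res <- f_ratio_test(a, b)
  expect_equal(round(res$f, 2), 3.22)
  expect_equal(res$df, c(5, 5))
  expect_equal(round(res$f_crit, 2), 5.05)
  expect_gte(res$f, 1)
  swapped <- f_ratio_test(b, a)
  expect_equal(swapped$f, res$f)
  eq <- f_ratio_test(a, a)
  expect_equal(eq$f, 1)
  expect_error(f_ratio_test(a, group_summary(1, 0, 6)), "zero variance")
})

test_that("ANOVA from printed sums of squares rebuilds the printed statistics", {
  par_row <- anova_from_summary(8.83, 4, 22.74, 25)
  expect_equal(par_row$ms_between, 8.83 / 4)
  expect_equal(par_row$ms_within, 22.74 / 25)
  expect_equal(round(par_row$f, 2), 2.43)
  expect_equal(round(par_row$f_crit, 2), 2.76)
  hyo_row <- anova_from_summary(3.29, 4, 13.22, 25)
  expect_equal(round(hyo_row$f, 2), 1.56)
  null_row <- anova_from_summary(0, 4, 22.74, 25)
  expect_equal(null_row$f, 0)
  expect_equal(null_row$p, 1)
  expect_error(anova_from_summary(-1, 4, 1, 25), "non-negative")
})

test_that("one-way ANOVA from raw data agrees with aov and its own summary", {
  set.seed(42)
  groups <- replicate(5, rnorm(6, 100, 1), simplify = FALSE)
  mine <- anova_oneway(groups)
  expect_equal(mine$df_between, 4)
  expect_equal(mine$df_within, 25)
  # oracle: stats::aov on the same layout
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(seq_along(groups), lengths(groups))))
  ref <- summary(stats::aov(y ~ g, data = df))[[1]]
  expect_equal(mine$ss_between, ref["g", "Sum Sq"], tolerance = 1e-10)
  expect_equal(mine$ss_within, ref["Residuals", "Sum Sq"], tolerance = 1e-10)
  expect_equal(mine$f, ref["g", "F value"], tolerance = 1e-10)
  expect_equal(mine$p, ref["g", "Pr(>F)"], tolerance = 1e-10)
  # internal consistency with the summary route
  re <- anova_from_summary(mine$ss_between, mine$df_between,
                           mine$ss_within, mine$df_within)
  expect_equal(re$f, mine$f)
  expect_equal(re$p, mine$p)
})

test_that("degenerate ANOVA inputs follow the stated conventions", {
  allsame <- anova_oneway(replicate(3, rep(2, 4), simplify = FALSE))
  expect_equal(allsame$f, 0)
  expect_equal(allsame$p, 1)
  expect_error(anova_oneway(list(1:3)), "at least 2 groups")
  expect_error(anova_oneway(list(1:3, 5)), "at least 2 observations")
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(9)
  for (rep in 1:20) {
    x <- rnorm(6, 100, 1); y <- rnorm(7, 100.5, 1.3)
    tt <- t_test_from_summary(group_summary(mean(x), sd(x), 6),
                              group_summary(mean(y), sd(y), 7))
    av <- anova_oneway(list(x, y))
    expect_equal(tt$t^2, av$f, tolerance = 1e-10)
    expect_equal(tt$p, av$p, tolerance = 1e-10)
  }
})

test_that("critical values reproduce the standard tabulated entries", {
  expect_equal(round(critical_t(0.05, 10), 2), 2.23)
  expect_equal(round(critical_f(0.05, 4, 25), 2), 2.76)
  expect_equal(round(critical_f(0.05, 5, 5), 2), 5.05)
})

test_that("p-values are proper and monotone in the statistics", {
  a <- group_summary(100, 1, 6)
  deltas <- c(0.2, 0.5, 1, 2)
  ps <- vapply(deltas, function(d)
    t_test_from_summary(a, group_summary(100 + d, 1, 6))$p, 0)
  expect_true(all(ps >= 0 & ps <= 1))
  expect_true(all(diff(ps) < 0))
  fs <- vapply(c(1.5, 2.5, 4), function(v)
    f_ratio_test(a, group_summary(100, sqrt(v), 6))$p, 0)
  expect_true(all(diff(fs) < 0))
})
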