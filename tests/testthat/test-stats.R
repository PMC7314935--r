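gt <- function(values, conditions) data.frame(condition = conditions,
                                              value = values)

test_that("group summaries reproduce hand-computed mean and SE", {
  s <- summarize_groups(gt(c(2, 4), c("a", "a")))
  expect_equal(s$mean, 3)
  expect_equal(s$se, 1)
  s2 <- summarize_groups(gt(c(5, 5, 5), c("a", "a", "a")))
  expect_equal(s2$mean, 5); expect_equal(s2$se, 0)
  set.seed(8)
  for (i in 1:10) {
    v <- rnorm(sample(3:12, 1)); n <- length(v)
    s <- summarize_groups(gt(v, rep("g", n)))
    expect_equal(s$mean, sum(v) / n, tolerance = 1e-12)
    expect_equal(s$se, sqrt(sum((v - mean(v))^2) / (n - 1)) / sqrt(n),
                 tolerance = 1e-12)
  }
  expect_error(summarize_groups(gt(numeric(), character())), "empty")
})

test_that("two-group comparison matches the closed-form pooled t-test", {
  # identical groups: t = 0, p = 1
  cmp <- compare_groups(gt(c(1, 2, 3, 1, 2, 3),
                           rep(c("a", "b"), each = 3)))
  expect_equal(cmp$pairwise$t, 0)
  expect_equal(cmp$pairwise$p, 1)
  expect_false(cmp$pairwise$significant)

  # {1,2,3} vs {4,5,6}: closed-form pooled t
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  t_hand <- (mean(b) - mean(a)) / (sp * sqrt(1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  cmp <- compare_groups(gt(c(a, b), rep(c("a", "b"), each = 3)))
  expect_equal(cmp$pairwise$t, t_hand, tolerance = 1e-12)
  expect_equal(cmp$pairwise$p, p_hand, tolerance = 1e-12)
  expect_true(cmp$pairwise$significant)
  expect_error(compare_groups(gt(c(1, 2, 3), c("a", "a", "b"))), "fewer than 2")
})

test_that("ANOVA F equals the squared pooled t for two balanced groups", {
  set.seed(19)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    tab <- gt(rnorm(2 * n, mean = rep(c(0, runif(1, 0, 2)), each = n)),
              rep(c("a", "b"), each = n))
    cmp <- compare_groups(tab)
    expect_equal(cmp$anova$F, cmp$pairwise$t^2, tolerance = 1e-9)
  }
})

test_that("Tukey-adjusted p-values never fall below unadjusted pairwise p", {
  set.seed(23)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    n <- sample(3:6, 1)
    tab <- gt(rnorm(k * n, mean = rep(runif(k, 0, 1.5), each = n)),
              rep(letters[1:k], each = n))
    cmp <- compare_groups(tab)
    expect_equal(nrow(cmp$pairwise), choose(k, 2))
    expect_true(all(cmp$pairwise$p_adjusted >= cmp$pairwise$p - 1e-12))
  }
})

test_that("statistics are invariant to row order", {
  set.seed(31)
  tab <- gt(rnorm(12), rep(c("a", "b", "c"), each = 4))
  cmp1 <- compare_groups(tab)
  perm <- sample(nrow(tab))
  cmp2 <- compare_groups(tab[perm, ])
  expect_equal(cmp1$anova$F, cmp2$anova$F, tolerance = 1e-12)
  expect_equal(cmp1$pairwise$p_adjusted, cmp2$pairwise$p_adjusted,
               tolerance = 1e-12)
  s1 <- summarize_groups(tab); s2 <- summarize_groups(tab[perm, ])
  expect_equal(s1, s2)
})

test_that("report formatting includes the omnibus test and every pair", {
  set.seed(3)
  tab <- gt(rnorm(9, rep(c(0, 0, 3), each = 3)),
            rep(c("a", "b", "c"), each = 3))
  cmp <- compare_groups(tab)
  rep_lines <- format_stats_report(cmp, summarize_groups(tab))
  expect_true(any(grepl("ANOVA", rep_lines)))
  expect_equal(sum(grepl(" vs ", rep_lines)), 3L)
})
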