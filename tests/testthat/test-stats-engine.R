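test_that("log2(x+1) transform handles the unit points and rejects negatives", {
  expect_equal(log2p1(c(0, 1, 7)), c(0, 1, 3))
  expect_error(log2p1(-1), "non-negative")
})

test_that("regressing out a covariate leaves orthogonal residuals", {
  x <- 1:20
  expect_equal(unname(regress_out(2 * x + 1, x)), rep(0, 20))
  set.seed(4)
  y <- rnorm(50); x <- rnorm(50)
  r <- regress_out(y, x)
  expect_lt(abs(cor(r, x)), 1e-10)
  expect_lt(abs(mean(r)), 1e-12)
  expect_error(regress_out(y, rep(1, 50)), "constant")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  # classic 3-group example computed by hand:
  g <- list(a = c(6, 8, 4, 5, 3, 4), b = c(8, 12, 9, 11, 6, 8),
            c = c(13, 9, 11, 8, 7, 12))
  means <- vapply(g, mean, 0)
  grand <- mean(unlist(g))
  ss_between <- sum(6 * (means - grand)^2)
  ss_within <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0))
  f_hand <- (ss_between / 2) / (ss_within / 15)
  res <- anova_tukey(g)
  expect_equal(res$anova$statistic, f_hand, tolerance = 1e-12)
  expect_equal(res$anova$df, c(2, 15))
  expect_equal(nrow(res$tukey), 3L)
})

test_that("two-group ANOVA reproduces the pooled t-test p-value", {
  set.seed(5)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  res <- anova_tukey(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$anova$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$anova$statistic, unname(tt$statistic)^2,
               tolerance = 1e-12)
})

test_that("identical groups give F near 0 and adjusted p near 1", {
  g <- list(a = c(1, 2, 3, 2), b = c(2, 1, 3, 2), c = c(3, 2, 1, 2))
  res <- anova_tukey(g)
  expect_lt(res$anova$statistic, 1e-10)
  expect_true(all(res$tukey$p_adj > 0.999))
})

test_that("Anderson-Darling separates normal from heavy-tailed samples", {
  set.seed(6)
  x <- rnorm(500)
  res <- anderson_darling(x)
  expect_lt(res$statistic, 0.752)   # 5% critical value, case 3
  expect_gt(res$p, 0.05)
  y <- rt(500, df = 1)
  expect_lt(anderson_darling(y)$p, 0.05)
  # location-scale invariance
  res2 <- anderson_darling(5 + 3 * x)
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-10)
  expect_error(anderson_darling(rep(1, 20)), "constant")
})

test_that("Dunn-Sidak correction reproduces the printed alpha", {
  expect_equal(round(dunn_sidak(0.05, 20), 4), 0.0026)
  expect_equal(dunn_sidak(0.05, 1), 0.05)
  # always above Bonferroni
  for (m in c(2, 5, 20, 100)) {
    expect_gt(dunn_sidak(0.05, m), 0.05 / m)
  }
})

test_that("exact binomial CI at x=0 equals the closed form", {
  for (n in c(10L, 158L, 413L, 1000L)) {
    res <- exact_binomial(0L, n, 0.5)
    expect_equal(res$ci[1], 0)
    expect_equal(res$ci[2], 1 - 0.025^(1 / n), tolerance = 1e-12)
  }
  expect_equal(exact_binomial(5L, 10L, 0.5)$p, 1)
  expect_error(exact_binomial(0L, 0L, 0.5))
})

test_that("two-sided exact binomial p follows the minimum-likelihood rule", {
  # independent oracle: sum P(k) over outcomes no more likely than x
  oracle <- function(x, n, p0) {
    d <- dbinom(0:n, n, p0)
    sum(d[d <= d[x + 1] * (1 + 1e-7)])
  }
  cases <- list(c(60, 100), c(3, 20), c(17, 40))
  for (cs in cases) {
    expect_equal(exact_binomial(cs[1], cs[2], 0.5)$p,
                 oracle(cs[1], cs[2], 0.5), tolerance = 1e-9)
  }
})

test_that("Welch t is antisymmetric and matches the closed form", {
  x <- c(5.1, 4.8, 5.6, 5.2, 4.9)
  y <- c(4.2, 4.0, 4.4, 4.6)
  sx <- var(x) / length(x); sy <- var(y) / length(y)
  t_hand <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df_hand <- (sx + sy)^2 /
    (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
  res <- welch_t(x, y)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(welch_t(y, x)$statistic, -res$statistic)
  expect_equal(welch_t(x, x)$statistic, 0)
})

test_that("pairwise Wilcoxon applies the Bonferroni multiplier", {
  set.seed(7)
  g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  res <- wilcoxon_pairwise(g)
  expect_equal(nrow(res), 3L)
  expect_equal(res$p_adj, pmin(1, res$p_raw * 3))
  # fully separated groups attain the exact minimum two-sided p
  res2 <- wilcoxon_pairwise(list(lo = 1:10, hi = 101:110))
  expect_equal(res2$p_raw, 2 / choose(20, 10), tolerance = 1e-12)
  ident <- wilcoxon_pairwise(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(ident$p_adj, 1)
})

test_that("Poisson regression recovers parameters and closed forms", {
  set.seed(8)
  x <- runif(500, -1, 1)
  y <- rpois(500, exp(1 + 2 * x))
  fit <- poisson_glm(y, data.frame(x = x))
  expect_lt(abs(fit$coefficients[["x"]] - 2), 3 * fit$se[["x"]])
  const <- poisson_glm(rep(4L, 30), data.frame(x = rnorm(30)))
  expect_lt(abs(const$coefficients[[2]]), 1e-6)
  io <- poisson_glm(c(2L, 4L, 6L, 8L))
  expect_equal(unname(io$coefficients[1]), log(5), tolerance = 1e-9)
})

test_that("generation time follows g = a + s/(1-s)", {
  expect_equal(generation_time(2, 0), 2)
  expect_equal(generation_time(2, 0.5), 3)
  expect_equal(generation_time(1, 0.68), 3.125)
  expect_error(generation_time(2, 1), "survival")
})
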