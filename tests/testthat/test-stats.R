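test_that("band normalization is exact for the control and linear overall", {
  tab <- data.frame(sample_id = letters[1:6],
                    group = rep(c("ctl", "kd"), each = 3),
                    target_intensity = c(100, 120, 80, 300, 360, 240),
                    loading_intensity = rep(100, 6))
  out <- normalize_bands(tab, "ctl")
  expect_equal(mean(out$fold_change[out$group == "ctl"]), 1)
  doubled <- tab
  doubled$target_intensity <- 2 * tab$target_intensity
  out2 <- normalize_bands(doubled, "ctl")
  # doubling every target leaves fold changes unchanged (control mean scales
  # too); doubling only the treated group doubles its fold change
  expect_equal(out2$fold_change, out$fold_change)
  half <- tab
  half$target_intensity[half$group == "kd"] <-
    2 * half$target_intensity[half$group == "kd"]
  out3 <- normalize_bands(half, "ctl")
  expect_equal(out3$fold_change[out3$group == "kd"],
               2 * out$fold_change[out$group == "kd"])
  bad <- tab
  bad$loading_intensity[1] <- 0
  expect_error(normalize_bands(bad, "ctl"), "loading")
})

test_that("Welch t matches the direct formula and handles degeneracy", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  got <- welch_t(a, b)
  ref <- oracle_welch(a, b)
  expect_equal(got$statistic, ref$t, tolerance = 1e-12)
  expect_equal(got$df, ref$df, tolerance = 1e-12)
  expect_equal(got$p.value, ref$p, tolerance = 1e-12)

  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(9, 0.5, 2)
    got <- welch_t(x, y)
    ref <- oracle_welch(x, y)
    expect_equal(got$statistic, ref$t, tolerance = 1e-10)
    expect_equal(got$p.value, ref$p, tolerance = 1e-10)
  }

  same <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_identical(same$statistic, 0)
  expect_identical(same$p.value, 1)
  expect_match(same$flags, "degenerate")
})

test_that("reported means and SEM match direct computation", {
  set.seed(13)
  x <- rnorm(11); y <- rnorm(5)
  est <- welch_t(x, y)$estimates
  expect_equal(est$mean, c(mean(x), mean(y)), tolerance = 1e-12)
  expect_equal(est$sem, c(sd(x) / sqrt(11), sd(y) / sqrt(5)),
               tolerance = 1e-12)
})

test_that("tests are invariant under common affine rescaling", {
  set.seed(14)
  x <- rnorm(8); y <- rnorm(8, 1)
  z <- rnorm(8, 2)
  f <- function(v) 3.2 * v - 7
  expect_equal(welch_t(x, y)$p.value, welch_t(f(x), f(y))$p.value,
               tolerance = 1e-10)
  g1 <- anova_dunnett_t3(list(x, y, z))
  g2 <- anova_dunnett_t3(list(f(x), f(y), f(z)))
  expect_equal(g1$comparisons$p.adjusted, g2$comparisons$p.adjusted,
               tolerance = 1e-8)
  # K-S is invariant under any monotone transform
  expect_equal(ks_two_sample(x, y)$statistic,
               ks_two_sample(exp(x), exp(y))$statistic)
})

test_that("K-S statistic equals the brute-force ECDF scan", {
  set.seed(15)
  for (i in 1:10) {
    a <- rnorm(sample(5:30, 1))
    b <- rnorm(sample(5:30, 1), 0.3)
    expect_equal(ks_two_sample(a, b)$statistic, oracle_ks_D(a, b),
                 tolerance = 1e-12)
  }
  x <- rnorm(10)
  expect_identical(ks_two_sample(x, x)$statistic, 0)
})

test_that("Dunnett T3 adjustment is coherent", {
  set.seed(16)
  x <- rnorm(10); y <- rnorm(10, 1); z <- rnorm(12, -0.5, 2)
  rep <- anova_dunnett_t3(list(ctl = x, a = y, b = z))
  # adjusted never below unadjusted
  expect_true(all(rep$comparisons$p.adjusted >=
                  rep$comparisons$p.unadjusted - 1e-12))
  expect_true(all(rep$comparisons$p.adjusted <= 1))
  # SMM with one comparison reduces to the two-sided t probability
  q <- 2.1; df <- 14
  expect_equal(neuroquant:::psmm(q, 1, df), 1 - 2 * pt(-q, df),
               tolerance = 1e-7)
  # identical groups: F near zero, nothing significant
  g <- list(c(5, 5.01, 4.99), c(5, 5.01, 4.99), c(5, 5.01, 4.99))
  r0 <- anova_dunnett_t3(g)
  expect_lt(r0$statistic, 1e-10)
  expect_true(all(r0$comparisons$p.adjusted > 0.99))
  expect_error(anova_dunnett_t3(list(x, y)), "3 groups")
})

test_that("Tukey HSD wrapper reports adjusted pairs", {
  g <- list(a = c(1, 1.1, 0.9), b = c(1, 1.05, 0.95), c = c(1.02, 1, 0.98))
  rep <- anova_tukey(g)
  expect_identical(nrow(rep$comparisons), 3L)
  expect_true(all(rep$comparisons$p.adjusted > 0.5))
  expect_error(anova_tukey(g[1:2]), "3 groups")
})

test_that("percent change propagates uncertainty sensibly", {
  a <- c(1, 1, 1, 1); b <- c(1.16, 1.16, 1.16, 1.16)
  pc <- percent_change(a, b)
  expect_equal(pc$percent, 16, tolerance = 1e-10)
  expect_equal(pc$sem, 0, tolerance = 1e-10)
})
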