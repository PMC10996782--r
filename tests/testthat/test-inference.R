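test_that("pooled t-test matches a long-hand computation", {
  # textbook-style two-sample data, computed by the pooled-variance formula
  a <- c(12.1, 14.3, 11.8, 13.5, 12.9, 15.0)
  b <- c(10.2, 11.1, 12.0, 9.8, 11.5)
  d <- data.frame(v = c(a, b), g = rep(c("a", "b"), c(6, 5)))
  out <- group_ttest(d, "v", "g")
  sp2 <- ((6 - 1) * var(a) + (5 - 1) * var(b)) / (6 + 5 - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 6 + 1 / 5))
  expect_equal(out$statistic, t_hand, tolerance = 1e-12)
  expect_equal(out$df, 9)
  expect_equal(out$p_value, 2 * pt(-abs(t_hand), 9), tolerance = 1e-12)
  expect_equal(out$d, (mean(a) - mean(b)) / sqrt(sp2), tolerance = 1e-12)
})

test_that("identical groups give t = 0 and two-tailed p = 1", {
  d <- data.frame(v = rep(c(1, 2, 3), 2), g = rep(c("x", "y"), each = 3))
  out <- group_ttest(d, "v", "g")
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$d, 0)
})

test_that("one-tailed p halves the two-tailed p in the hypothesized direction", {
  set.seed(71)
  d <- data.frame(v = c(rnorm(20), rnorm(20) + 1),
                  g = rep(c("lo", "hi"), each = 20))
  two <- group_ttest(d, "v", "g")
  # first level ("hi") has the larger mean, so "greater" is the
  # hypothesized direction
  one <- group_ttest(d, "v", "g", alternative = "greater")
  expect_equal(one$p_value, two$p_value / 2, tolerance = 1e-12)
  expect_equal(one$tail, "one")
})

test_that("the one-tailed test holds its nominal type-I error under the null", {
  set.seed(73)
  n_rep <- 1000
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- data.frame(v = rnorm(40), g = rep(c("a", "b"), each = 20))
    rej[i] <- group_ttest(d, "v", "g", alternative = "less")$p_value < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("correlation recovers exact linear relations and rejects degenerate ones", {
  x <- rnorm(30)
  expect_equal(pearson_correlation(data.frame(x = x, y = x), "x", "y")$r, 1)
  expect_equal(pearson_correlation(
    data.frame(x = x, y = -2 * x + 5), "x", "y")$r, -1)
  set.seed(79)
  ind <- data.frame(x = rnorm(500), y = rnorm(500))
  out <- pearson_correlation(ind, "x", "y")
  expect_lt(abs(out$r), 0.15)
  expect_equal(out$df, 498)
  expect_error(pearson_correlation(data.frame(x = rep(1, 10), y = rnorm(10)),
                                   "x", "y"), "zero variance")
})

test_that("the covariate-adjusted F reduces to t-squared without real covariates", {
  set.seed(83)
  n <- 60
  d <- data.frame(v = c(rnorm(n / 2), rnorm(n / 2) + 0.8),
                  g = rep(c("a", "b"), each = n / 2),
                  z = rep(c(-1, 1), n / 2))   # balanced, orthogonal to group
  t_unadj <- group_ttest(d, "v", "g")$statistic
  f_adj <- ancova_group_effect(d, "v", "g", covariates = "z")
  f_noadj <- ancova_group_effect(d, "v", "g")
  expect_equal(f_noadj$statistic, t_unadj^2, tolerance = 1e-10)
  expect_equal(f_noadj$df2, n - 2)
  # orthogonal covariate barely moves the F
  expect_equal(f_adj$statistic, f_noadj$statistic, tolerance = 0.15)
  # same outcome values in both groups: no group effect at all
  flat <- ancova_group_effect(data.frame(v = rep(c(1, 2, 3, 4, 5), 4),
                                         g = rep(c("a", "b"), each = 10)),
                              "v", "g")
  expect_lt(flat$statistic, 1e-20)
})

test_that("type-II sums of squares match the car oracle", {
  set.seed(89)
  d <- data.frame(g = rep(c("a", "b"), each = 25),
                  z = rnorm(50), w = rnorm(50))
  d$v <- (d$g == "b") * 0.7 + 0.4 * d$z + rnorm(50)
  ours <- ancova_group_effect(d, "v", "g", covariates = c("z", "w"))
  ca <- car::Anova(lm(v ~ z + w + g, data = d), type = 2)
  expect_equal(ours$statistic, ca["g", "F value"], tolerance = 1e-10)
  expect_equal(ours$p_value, ca["g", "Pr(>F)"], tolerance = 1e-10)
})

test_that("a confounded covariate shrinks the adjusted group effect", {
  set.seed(97)
  g <- rep(0:1, each = 50)
  z <- g + rnorm(100, 0, 0.5)           # confounder tracks the group
  v <- z + rnorm(100, 0, 0.5)           # outcome driven by the confounder
  d <- data.frame(v = v, g = factor(g), z = z)
  f_unadj <- ancova_group_effect(d, "v", "g")
  f_adj <- ancova_group_effect(d, "v", "g", covariates = "z")
  expect_lt(f_adj$statistic, f_unadj$statistic)
})

test_that("rank deficiency is reported with the collinear column", {
  d <- data.frame(v = rnorm(20), g = rep(c("a", "b"), 10), z = rnorm(20))
  d$z2 <- d$z
  expect_error(ancova_group_effect(d, "v", "g", covariates = c("z", "z2")),
               "z2")
})

test_that("the OLS mediation decomposition is exact", {
  set.seed(101)
  n <- 120
  X <- rbinom(n, 1, 0.4)
  M1 <- 0.5 * X + rnorm(n)
  M2 <- -0.3 * X + rnorm(n)
  cov1 <- rnorm(n)
  Y <- 0.6 * M1 + 0.2 * M2 + 0.3 * X + 0.1 * cov1 + rnorm(n)
  d <- data.frame(X, M1, M2, cov1, Y)
  for (meds in list("M1", c("M1", "M2"))) {
    for (covs in list(character(), "cov1")) {
      md <- mediate(d, "X", "Y", meds, covariates = covs, n_boot = 50,
                    seed = 3)
      g <- glance(md)
      expect_lt(abs(g$c_total - (g$c_prime + g$indirect_total)), 1e-10)
    }
  }
})

test_that("mediation reports partially standardized paths", {
  set.seed(103)
  n <- 400
  X <- rbinom(n, 1, 0.5)
  M <- 0.5 * X + rnorm(n)
  Y <- 0.8 * M + rnorm(n)
  d <- data.frame(X, M, Y)
  md <- mediate(d, "X", "Y", "M", n_boot = 200, seed = 7)
  a <- md$paths$estimate[md$paths$path == "a"]
  b <- md$paths$estimate[md$paths$path == "b"]
  # a is on the mediator scale; b is per mediator unit on the z-scored outcome
  fit_b <- lm(scale(Y) ~ X + M)
  expect_equal(b, unname(coef(fit_b)["M"]), tolerance = 1e-10)
  expect_equal(a, unname(coef(lm(M ~ X))["X"]), tolerance = 1e-10)
  expect_equal(md$indirect$estimate, a * b)
})

test_that("bootstrap mediation is reproducible under a fixed seed", {
  set.seed(107)
  d <- data.frame(X = rbinom(80, 1, 0.5), M = rnorm(80), Y = rnorm(80))
  d$M <- d$M + 0.4 * d$X; d$Y <- d$Y + 0.5 * d$M
  m1 <- mediate(d, "X", "Y", "M", n_boot = 300, seed = 11)
  m2 <- mediate(d, "X", "Y", "M", n_boot = 300, seed = 11)
  expect_identical(tidy(m1), tidy(m2))
  m3 <- mediate(d, "X", "Y", "M", n_boot = 300, seed = 12)
  expect_false(identical(m1$indirect$ci_lo, m3$indirect$ci_lo))
})

test_that("degenerate mediation inputs are rejected", {
  d <- data.frame(X = rbinom(40, 1, 0.5), M = rep(1, 40), Y = rnorm(40))
  expect_error(mediate(d, "X", "Y", "M", n_boot = 100), "constant")
  d$M <- rnorm(40)
  expect_error(mediate(d, "X", "Y", "M", n_boot = 1), "at least 2")
  d$X <- sample(1:3, 40, TRUE)
  expect_error(mediate(d, "X", "Y", "M", n_boot = 100), "binary")
})
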