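test_that("normality and variance screen matches reference values", {
  # Shapiro-Wilk on {1..5}: reference W from an independent implementation
  df <- data.frame(x = c(1, 2, 3, 4, 5, 2.1, 3.3, 1.2, 4.4, 5.5),
                   g = rep(c("a", "b"), each = 5))
  out <- normality_and_variance(df, "x", "g")
  expect_equal(out$shapiro$W[out$shapiro$group == "a"], 0.986762155211559,
               tolerance = 1e-6)
  # Levene (centred on means) against the car implementation
  lev_car <- car::leveneTest(x ~ factor(g), data = df, center = mean)
  expect_equal(out$levene$statistic, lev_car$`F value`[1], tolerance = 1e-9)
  expect_equal(out$levene$p, lev_car$`Pr(>F)`[1], tolerance = 1e-9)
  # degenerate group flagged
  bad <- data.frame(x = c(1, 1, 1, 2, 3, 4), g = rep(c("a", "b"), each = 3))
  expect_error(normality_and_variance(bad, "x", "g"), "degenerate|variance")
  expect_error(normality_and_variance(df[c(1, 2, 6, 7, 8), ], "x", "g"),
               "at least 3")
})

test_that("Levene's test is calibrated under equal variances", {
  set.seed(51)
  hits <- replicate(100, {
    df <- data.frame(x = c(rnorm(50, 0, 2), rnorm(50, 1, 2)),
                     g = rep(c("a", "b"), each = 50))
    normality_and_variance(df, "x", "g")$levene$p > 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("one-way ANOVA matches a hand-computed sums-of-squares oracle", {
  x <- c(2.1, 3.4, 1.9, 4.2, 5.0, 4.8, 7.7, 8.1, 6.9)
  g <- rep(c("a", "b", "c"), each = 3)
  df <- data.frame(x = x, g = g)
  out <- anova_bonferroni(df, "x", "g")
  # brute-force decomposition
  grand <- mean(x)
  ss_between <- sum(tapply(x, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(unlist(tapply(x, g, function(v) (v - mean(v))^2)))
  F_oracle <- (ss_between / 2) / (ss_within / 6)
  expect_equal(out$F, F_oracle, tolerance = 1e-9)
  expect_equal(out$p, pf(F_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # Bonferroni dominance and clamping
  expect_true(all(out$pairwise$p_adj >= out$pairwise$raw_p))
  expect_true(all(out$pairwise$p_adj <= 1))
  expect_equal(out$pairwise$p_adj,
               pmin(1, out$pairwise$raw_p * nrow(out$pairwise)))
})

test_that("ANOVA degenerate and separated cases behave", {
  same <- data.frame(x = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  out <- anova_bonferroni(same, "x", "g")
  expect_equal(out$F, 0, tolerance = 1e-12)
  expect_equal(out$p, 1)
  set.seed(52)
  sep <- data.frame(x = c(rnorm(4, 0, 0.01), rnorm(4, 10, 0.01)),
                    g = rep(c("a", "b"), each = 4))
  expect_lt(anova_bonferroni(sep, "x", "g")$p, 1e-10)
  expect_error(anova_bonferroni(sep[sep$g == "a", ], "x", "g"), "2 factor")
})

test_that("pooled t-test equals the textbook formula", {
  x1 <- c(3.2, 4.1, 5.6, 2.8, 4.4)
  x2 <- c(6.1, 7.3, 5.9, 8.0)
  df <- data.frame(x = c(x1, x2), g = rep(c("A", "B"), c(5, 4)))
  out <- two_sample_t(df, "x", "g")
  sp2 <- ((4 * var(x1) + 3 * var(x2)) / 7)
  t_oracle <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / 5 + 1 / 4))
  expect_equal(out$t, t_oracle, tolerance = 1e-12)
  expect_equal(out$df, 7)
  expect_equal(out$p, 2 * pt(-abs(t_oracle), 7), tolerance = 1e-12)
  expect_equal(out$mean_diff, mean(x1) - mean(x2), tolerance = 1e-12)
  same <- data.frame(x = rep(x1, 2), g = rep(c("A", "B"), each = 5))
  out2 <- two_sample_t(same, "x", "g")
  expect_equal(out2$t, 0, tolerance = 1e-12)
  expect_equal(out2$p, 1)
})

test_that("the t-test holds its nominal type-I error rate", {
  set.seed(53)
  rejections <- replicate(2000, {
    df <- data.frame(x = rnorm(40, 10, 3), g = rep(c("TB", "BB"), each = 20))
    two_sample_t(df, "x", "g")$p < 0.05
  })
  expect_gte(mean(rejections), 0.035)
  expect_lte(mean(rejections), 0.065)
})

test_that("chi-square matches the hand formula and study usage", {
  tab <- matrix(c(10, 20, 5, 10), 2)      # perfectly proportional
  expect_equal(chi_square_gender(tab)$chisq, 0, tolerance = 1e-12)
  gender <- matrix(c(9, 8, 11, 12), 2)    # 9/11 vs 8/12 males/females
  expect_gt(chi_square_gender(gender)$p, 0.05)
  toy <- matrix(c(12, 5, 7, 15), 2)
  E <- outer(rowSums(toy), colSums(toy)) / sum(toy)
  expect_equal(chi_square_gender(toy)$chisq, sum((toy - E)^2 / E),
               tolerance = 1e-12)
  expect_error(chi_square_gender(matrix(c(0, 0, 3, 4), 2)), "marginal")
  expect_error(chi_square_gender(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("OLS regression matches the normal-equations oracle", {
  df <- data.frame(y = c(9.1, 7.9, 12.3, 10.8, 14.2, 13.1),
                   expander = c(0, 0, 0, 1, 1, 1),
                   pwe = c(-1.2, -1.8, -1.5, -2.4, -2.0, -2.8),
                   dae = c(-4.1, -5.0, -4.4, -3.9, -4.6, -4.2))
  fit <- err_regression(df, "y", c("expander", "pwe", "dae"))
  X <- cbind(1, df$expander, df$pwe, df$dae)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% df$y)
  expect_equal(fit$coefficients$B, drop(beta_oracle), tolerance = 1e-10)
  # standardized betas consistent with B rescaled by SDs
  for (p in c("expander", "pwe", "dae")) {
    i <- match(p, fit$coefficients$term)
    expect_equal(fit$coefficients$beta[i],
                 fit$coefficients$B[i] * sd(df[[p]]) / sd(df$y),
                 tolerance = 1e-12)
  }
  # CI identity
  i <- 2
  expect_equal(fit$coefficients$ci_hi[i] - fit$coefficients$B[i],
               qt(0.975, 2) * fit$coefficients$se[i], tolerance = 1e-9)
})

test_that("regression handles exact fits and collinearity", {
  df <- data.frame(y = NA, a = c(1, 2, 3, 4, 5, 6),
                   b = c(0, 1, 0, 1, 0, 1))
  df$y <- 2 + 3 * df$a - 1.5 * df$b
  fit <- err_regression(df, "y", c("a", "b"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$coefficients$B, c(2, 3, -1.5), tolerance = 1e-9)
  df$c <- 2 * df$a
  expect_error(err_regression(df, "y", c("a", "c")), "collinear|aliased")
})

test_that("expander type dominates the regression on simulated effects", {
  set.seed(54)
  dominant <- replicate(40, {
    n <- 20
    expander <- rep(c(0, 1), each = n)
    pwe <- rnorm(2 * n, ifelse(expander == 0, -1.54, -2.22), 1)
    dae <- rnorm(2 * n, ifelse(expander == 0, -5.59, -4.38), 1.6)
    y <- ifelse(expander == 0, rnorm(2 * n, 26.21, 10.03),
                rnorm(2 * n, 4.62, 3.12))
    df <- data.frame(y = y, expander = expander, pwe = pwe, dae = dae)
    co <- err_regression(df, "y", c("expander", "pwe", "dae"))$coefficients
    b <- setNames(co$beta, co$term)
    abs(b["expander"]) > max(abs(b["pwe"]), abs(b["dae"]))
  })
  expect_gte(mean(dominant), 0.95)
})

test_that("ICC(2,1) matches the two-way ANOVA decomposition", {
  M <- cbind(r1 = c(9, 6, 8, 7, 10, 6),
             r2 = c(2, 1, 4, 1, 5, 2))
  out <- icc_agreement(M)
  # oracle via R's anova on the long two-way layout
  long <- data.frame(y = as.vector(M),
                     subj = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  ms <- anova(lm(y ~ subj + rater, long))$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 6)
  expect_equal(out$icc, icc_oracle, tolerance = 1e-9)
  # perfect agreement
  dup <- cbind(c(1, 5, 3, 8, 2), c(1, 5, 3, 8, 2))
  expect_equal(icc_agreement(dup)$icc, 1, tolerance = 1e-12)
  # independent ratings hover near zero (sampling sd of ICC at n subjects
  # is about 1/sqrt(n), so test at n = 200)
  set.seed(55)
  rnd <- matrix(rnorm(400), 200)
  expect_lt(abs(icc_agreement(rnd)$icc), 0.15)
  expect_error(icc_agreement(cbind(c(1, NA, 3, 4, 5), 1:5)), "missing")
  expect_error(icc_agreement(cbind(1:3, 3:1)), "5 subjects")
})

test_that("sample size iteration agrees with the noncentral-t oracle", {
  expect_equal(sample_size_two_means(1, 1, 1), 17)
  # cross-check against power.t.test (continuous-n solver)
  cont <- power.t.test(delta = 1, sd = 1, power = 0.8)$n
  expect_equal(sample_size_two_means(1, 1, 1), ceiling(cont))
  expect_equal(sample_size_two_means(1000, 1, 1), 2)
  n1 <- sample_size_two_means(2, 1.5, 1.5)
  n2 <- sample_size_two_means(2, 3, 3)
  expect_gt(n2 / n1, 3); expect_lt(n2 / n1, 5)
  expect_error(sample_size_two_means(1, -1, 1), "positive")
  expect_error(sample_size_two_means(1, 1, 1, power = 1.2), "power")
})

test_that("side pooling pre-test flags only real side differences", {
  set.seed(56)
  tab <- data.frame(tooth_class = rep(c("P1", "M1"), each = 20),
                    side = rep(c("L", "R"), 20),
                    delta_v = rnorm(40, 10, 2))
  out <- side_pooling_pretest(tab, "delta_v")
  expect_true(all(out$poolable))
  tab$delta_v[tab$tooth_class == "M1" & tab$side == "L"] <-
    tab$delta_v[tab$tooth_class == "M1" & tab$side == "L"] + 50
  out2 <- side_pooling_pretest(tab, "delta_v")
  expect_false(out2$poolable[out2$stratum == "M1"])
  expect_true(out2$poolable[out2$stratum == "P1"])
})
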