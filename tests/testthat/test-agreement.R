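test_that("Spearman rho and banding match the rank-difference oracle", {
  r <- spearman_banded(1:3, c(1, 2, 3))
  expect_equal(r$rho, 1)
  expect_equal(as.character(r$band), "strong")
  expect_equal(spearman_banded(1:3, c(3, 2, 1))$rho, -1)
  r2 <- spearman_banded(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r2$rho, 0.8)
  expect_equal(r2$rho, oracle_spearman(1:5, c(2, 1, 4, 3, 5)))
  set.seed(3)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(spearman_banded(x, y)$rho, oracle_spearman(x, y))
  expect_error(spearman_banded(rep(1, 5), 1:5), "constant")
  expect_error(spearman_banded(1:2, 1:2), "3 complete pairs")
})

test_that("Spearman is invariant under strictly increasing transforms", {
  set.seed(4)
  x <- rlnorm(40); y <- x * rlnorm(40, sdlog = 0.5)
  base <- spearman_banded(x, y)
  expect_equal(spearman_banded(log(x), y)$rho, base$rho)
  expect_equal(spearman_banded(x, exp(y / max(y)))$rho, base$rho)
  expect_equal(spearman_banded(rank(x), y)$p_value, base$p_value)
})

test_that("correlation bands split at 0.20 and 0.50 as specified", {
  expect_equal(as.character(rho_band(c(0.19, 0.199, -0.3))),
               rep("poor", 3))
  expect_equal(as.character(rho_band(c(0.20, 0.49, 0.499))),
               rep("acceptable", 3))
  expect_equal(as.character(rho_band(c(0.50, 0.51, 1))),
               rep("strong", 3))
})

test_that("regression R2 matches the normal-equations oracle", {
  d <- data.frame(x = c(1, 2, 3, 4, 5, 6))
  d$y <- 2 * d$x
  expect_equal(glance(regression_r2(d, "y", "x"))$r_squared, 1)
  d$yc <- 5
  expect_equal(glance(regression_r2(d, "yc", "x"))$r_squared, 0)
  set.seed(9)
  d6 <- data.frame(x1 = rnorm(6), x2 = rnorm(6))
  d6$y <- 1 + 0.5 * d6$x1 - 0.3 * d6$x2 + rnorm(6, sd = 0.2)
  fit <- regression_r2(d6, "y", c("x1", "x2"))
  expect_equal(fit$r_squared, oracle_r2(d6$y, d6[, c("x1", "x2")]),
               tolerance = 1e-10)
  # covariates enter as additional columns
  d6$age <- rnorm(6)
  fit_adj <- regression_r2(d6, "y", "x1", covariates = "age")
  expect_equal(fit_adj$r_squared, oracle_r2(d6$y, d6[, c("x1", "age")]),
               tolerance = 1e-10)
  expect_true(all(c("term", "estimate", "p_value") %in%
                    names(tidy(fit))))
  d6$x1dup <- d6$x1
  expect_error(regression_r2(d6, "y", c("x1", "x1dup")), "Rank-deficient")
  expect_error(regression_r2(d6[1:3, ], "y", c("x1", "x2")), "enough")
})

test_that("Bland-Altman statistics follow the closed-form definitions", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(glance(same)$mean_diff, 0)
  expect_equal(glance(same)$loa_low, 0)
  expect_equal(glance(same)$loa_high, 0)
  # d = {+1, -1}: mean 0, sample SD sqrt(2), LoA +/- 1.96 sqrt(2)
  ba <- bland_altman(c(2, 1), c(1, 2))
  expect_equal(glance(ba)$sd_diff, sqrt(2))
  expect_equal(glance(ba)$loa_high, 1.96 * sqrt(2))
  expect_equal(glance(ba)$loa_low, -1.96 * sqrt(2))
  # constant shift
  a <- c(5, 7, 9, 13)
  shift <- bland_altman(a, a + 4)
  expect_equal(glance(shift)$mean_diff, -4)
  expect_equal(glance(shift)$sd_diff, 0)
  expect_equal(nrow(tidy(shift)), 4)
  expect_error(bland_altman(1, 2), "2 complete pairs")
})

test_that("Bland-Altman limits cover about 95% of Gaussian differences", {
  set.seed(20)
  n <- 10000
  b <- rnorm(n, 100, 5)
  a <- b + rnorm(n, 2, 10)
  ba <- glance(bland_altman(a, b))
  d <- a - b
  cover <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_gte(cover, 0.945)
  expect_lte(cover, 0.955)
})

test_that("Wilcoxon exact p matches full sign enumeration", {
  a <- c(5, 6, 7, 8, 9); b <- c(4, 4, 4, 4, 4) # distinct positive differences
  w <- wilcoxon_signed_rank(a, b)
  expect_equal(w$p_value, 2 / 32)
  expect_equal(w$method, "exact")
  expect_equal(w$p_value, oracle_signrank_p(a, b))
  # equal differences (fully tied ranks) take the enumeration path,
  # and every all-positive configuration still has p = 2/32
  wt <- wilcoxon_signed_rank(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))
  expect_match(wt$method, "enumerated")
  expect_equal(wt$p_value, 2 / 32)
  expect_equal(wt$p_value, oracle_signrank_p(c(5, 6, 7, 8, 9), 1:5))
  # antisymmetry: swapping a and b keeps p, mirrors the statistic
  w2 <- wilcoxon_signed_rank(b, a)
  expect_equal(w2$p_value, w$p_value)
  expect_equal(w2$statistic, sum(1:5) - w$statistic)
  expect_error(wilcoxon_signed_rank(c(1, 1, 1, 1, 2), c(1, 1, 1, 1, 1)),
               "5 informative")
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "zero")
})

test_that("Wilcoxon agrees with base R on tied and large samples", {
  set.seed(6)
  a <- round(rnorm(40, 10, 2), 1)
  b <- round(rnorm(40, 10.5, 2), 1)
  got <- wilcoxon_signed_rank(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             correct = FALSE, exact = FALSE))
  expect_equal(got$p_value, unname(ref$p.value))
  expect_equal(got$statistic, unname(ref$statistic))
})

test_that("Pratt zero handling keeps zeros in the ranking", {
  a <- c(3, 5, 7, 9, 11, 4, 4)
  b <- c(1, 2, 3, 4, 5, 4, 4)
  drop <- wilcoxon_signed_rank(a, b)
  pratt <- wilcoxon_signed_rank(a, b, zero_method = "pratt")
  expect_equal(drop$n_informative, pratt$n_informative)
  expect_gt(pratt$statistic, drop$statistic)
})

test_that("paired t matches the direct formula and base t.test", {
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  set.seed(12)
  a <- rnorm(5, 75, 10); b <- a + rnorm(5, 0.5, 1)
  got <- paired_t(a, b)
  d <- a - b
  expect_equal(got$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  expect_equal(paired_t(b, a)$t, -got$t)
  expect_error(paired_t(c(1, 2), c(2, 3)), "zero variance")
})

test_that("ICC matches the aov-based oracle and orders as expected", {
  r1 <- c(9, 6, 8, 7, 10, 6)
  r2 <- c(2, 1, 4, 1, 5, 2)
  got <- icc_agreement(r1, r2)
  expect_equal(got$icc, oracle_icc_a1(r1, r2), tolerance = 1e-10)
  set.seed(31)
  x <- rnorm(20); y <- x + rnorm(20, sd = 0.3)
  expect_equal(icc_agreement(x, y)$icc, oracle_icc_a1(x, y),
               tolerance = 1e-10)
  expect_equal(icc_agreement(x, x)$icc, 1)
  # a large systematic shift hurts agreement but not consistency
  shifted <- x + 5
  expect_lt(icc_agreement(x, shifted)$icc,
            icc_agreement(x, shifted, type = "consistency")$icc)
  expect_error(icc_agreement(rep(1, 5), rep(1, 5)), "variance")
  expect_error(icc_agreement(1:2, 1:2), "3 complete pairs")
})

test_that("normality gate routes Gaussian and lognormal samples correctly", {
  set.seed(100)
  g <- normality_gate(rnorm(100))
  expect_equal(g$route, "parametric")
  expect_equal(g$scale, "raw")
  set.seed(100)
  ln <- normality_gate(rlnorm(100, sdlog = 1))
  expect_equal(ln$route, "parametric")
  expect_equal(ln$scale, "log")
  set.seed(100)
  mix <- normality_gate(c(rnorm(95), rnorm(5, 40))) # not normal on any scale
  expect_equal(mix$route, "nonparametric")
  neg <- normality_gate(c(rlnorm(99, sdlog = 2), -1))
  expect_match(neg$note, "non-positive")
  expect_error(normality_gate(c(1, 2)), "between 3 and 5000")
})

test_that("percent bias reproduces the worked group-mean examples", {
  expect_equal(percent_bias(86, 82), 100 * 4 / 82)
  expect_equal(percent_bias(3124, 4267, denominator = "reported"),
               100 * (3124 - 4267) / 3124)
  expect_equal(percent_bias(50, 50), 0)
  expect_error(percent_bias(10, 0), "positive")
})
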