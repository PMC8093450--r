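test_that("task accuracies follow their confusion-count formulas", {
  expect_equal(accuracy_nback(confusion_counts(8, 1, 0, 1)), 0.8)
  expect_equal(accuracy_nback(confusion_counts(5, 0, 5, 0)), 1)
  expect_equal(accuracy_nback(confusion_counts(0, 3, 0, 2)), 0)
  expect_equal(accuracy_arithmetic(confusion_counts(3, 1)), 0.75)
  expect_equal(accuracy_arithmetic(confusion_counts(0, 4)), 0)
  expect_equal(accuracy_arithmetic(confusion_counts(7, 0)), 1)
  expect_error(accuracy_nback(confusion_counts()), "denominator")
  expect_error(accuracy_arithmetic(confusion_counts(0, 0, 5, 5)), "denominator")
})

test_that("Anderson-Darling distinguishes normal from uniform samples", {
  set.seed(31)
  expect_gt(anderson_darling_normal(rnorm(1000))$p_value, 0.05)
  expect_lt(anderson_darling_normal(runif(1000))$p_value, 0.01)
  expect_error(anderson_darling_normal(rep(2, 50)), "zero variance")
  expect_error(anderson_darling_normal(rnorm(5)), "n >= 8")
})

test_that("Anderson-Darling matches the reference implementation", {
  set.seed(17)
  for (i in 1:20) {
    x <- switch(i %% 3 + 1, rnorm(60), rexp(40), runif(100))
    a <- anderson_darling_normal(x)
    b <- nortest::ad.test(x)
    expect_equal(unname(a$statistic["A2"]), unname(b$statistic),
                 tolerance = 1e-12)
    expect_equal(a$p_value, b$p.value, tolerance = 1e-12)
  }
})

test_that("Friedman chi-square follows the closed form and the oracle", {
  concordant <- matrix(rep(c(1, 2, 3), each = 4), ncol = 3)
  r <- friedman_test(concordant)
  expect_equal(unname(r$statistic["chisq"]), 8)
  expect_equal(r$df, 2)
  expect_equal(unname(friedman_test(matrix(5, 4, 3))$statistic["chisq"]), 0)
  set.seed(23)
  for (i in 1:50) {
    m <- matrix(rnorm(36), 12, 3)
    expect_lt(abs(friedman_test(m)$statistic -
                    stats::friedman.test(m)$statistic), 1e-9)
  }
  # tie correction agrees with the oracle too
  mt <- matrix(sample(1:3, 36, TRUE), 12, 3)
  mt[1, ] <- c(1, 1, 2)
  expect_lt(abs(friedman_test(mt)$statistic -
                  stats::friedman.test(mt)$statistic), 1e-9)
})

test_that("rank-based tests ignore the scale of the data", {
  set.seed(41)
  m <- matrix(rexp(36), 12, 3)
  # Friedman sees only within-row ranks: any strictly monotone transform
  expect_equal(friedman_test(m)$statistic, friedman_test(exp(m))$statistic)
  expect_equal(friedman_test(m)$statistic, friedman_test(log(m))$statistic)
  # the signed-rank test additionally ranks |differences|, so its
  # invariance is to positive affine maps, not arbitrary monotone ones
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               wilcoxon_signed_rank(3 * a + 7, 3 * b + 7)$p_value)
})

test_that("Friedman holds its nominal type-I error under the null", {
  set.seed(57)
  rej <- mean(replicate(2000, {
    friedman_test(matrix(rnorm(36), 12, 3))$p_value < 0.05
  }))
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
})

test_that("Wilcoxon signed-rank enumerates exact p-values and reports W and Z", {
  r <- wilcoxon_signed_rank(c(2, 4, 7, 11, 16, 22), 1:6)
  expect_equal(unname(r$statistic["W"]), 0)
  expect_equal(r$p_value, 2 / 2^6)
  expect_equal(r$method, "exact")
  # antisymmetry
  set.seed(3)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               wilcoxon_signed_rank(b, a)$p_value)
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "all differences zero")
})

test_that("Wilcoxon matches the reference implementation on random pairs", {
  set.seed(29)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    mine <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    W_ref <- min(ref$statistic, n * (n + 1) / 2 - ref$statistic)
    expect_lt(abs(unname(mine$statistic["W"]) - W_ref), 1e-9)
    expect_lt(abs(mine$p_value - ref$p.value), 1e-9)
  }
})

test_that("Spearman rho follows the printed formula and handles ties", {
  expect_equal(unname(spearman_rho(1:3, 3:1)$statistic["rho"]), -1)
  set.seed(19)
  x <- rnorm(20)
  expect_equal(unname(spearman_rho(x, exp(x))$statistic["rho"]), 1)
  expect_equal(unname(spearman_rho(x, x)$statistic["rho"]), 1)
  for (i in 1:50) {
    a <- sample(1:6, 15, TRUE); b <- sample(1:6, 15, TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_lt(abs(unname(spearman_rho(a, b)$statistic["rho"]) -
                    cor(a, b, method = "spearman")), 1e-12)
    ref <- stats::cor.test(a, b, method = "spearman", exact = FALSE)
    expect_lt(abs(spearman_rho(a, b)$p_value - ref$p.value), 1e-9)
  }
  expect_error(spearman_rho(rep(1, 10), rnorm(10)), "constant")
})

test_that("repeated-measures ANOVA matches aov and flags degeneracy", {
  m0 <- matrix(rep(rnorm(5), 3), 5, 3)  # each subject identical across conditions
  r0 <- rm_anova_oneway(m0)
  expect_equal(unname(r0$statistic["F"]), 0)
  expect_equal(unname(r0$effect_size["eta_sq_p"]), 0)

  shift <- outer(rnorm(6), c(0, 1, 2), "+")  # perfectly additive
  rs <- rm_anova_oneway(shift)
  expect_true(rs$degenerate)
  expect_equal(unname(rs$statistic["F"]), Inf)

  set.seed(37)
  for (i in 1:50) {
    m <- matrix(rnorm(60), 20, 3)
    mine <- rm_anova_oneway(m)
    df <- data.frame(v = as.vector(m), s = factor(rep(1:20, 3)),
                     cond = factor(rep(1:3, each = 20)))
    aa <- summary(stats::aov(v ~ cond + Error(s / cond), df))
    f_ref <- aa[["Error: s:cond"]][[1]]["cond", "F value"]
    expect_lt(abs(unname(mine$statistic["F"]) - f_ref), 1e-9)
  }
  expect_error(rm_anova_oneway(matrix(c(1, NA, 3, 4, 5, 6), 3, 2)), "missing")
})
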