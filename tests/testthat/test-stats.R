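test_that("Welch t-test matches closed forms and handles degeneracy", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  r2 <- welch_t_test(c(0, 0, 1, 1), c(10, 10, 11, 11))
  expect_equal(r2$statistic, -10 / sqrt(1 / 6), tolerance = 1e-9)
  expect_equal(r2$df, 6)
  expect_lt(r2$p, 0.001)

  d <- welch_t_test(c(5, 5), c(5, 5))
  expect_equal(d$p, 1)
  expect_match(d$note, "degenerate")
  d2 <- welch_t_test(c(5, 5), c(7, 7))
  expect_equal(d2$p, 0)
})

test_that("Welch t is invariant to common positive affine transforms", {
  set.seed(10)
  x <- rnorm(15); y <- rnorm(12, 0.5)
  p0 <- welch_t_test(x, y)$p
  for (i in 1:5) {
    a <- runif(1, -5, 5); b <- runif(1, 0.1, 4)
    expect_equal(welch_t_test(a + b * x, a + b * y)$p, p0, tolerance = 1e-12)
  }
})

test_that("Fisher exact equals the hypergeometric enumeration oracle", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p, 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  set.seed(40)
  for (i in 1:200) {
    cells <- as.vector(stats::rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    got <- fisher_exact_2x2(matrix(c(a, c, b, d), 2))$p
    expect_equal(got, fisher_enum_p(a, b, c, d), tolerance = 1e-7)
  }
})

test_that("Pearson correlation: exact line, independence, affine invariance", {
  x <- c(1, 2, 3, 4, 5)
  r <- pearson_correlation(x, 2 * x + 1)
  expect_equal(r$r, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)

  set.seed(3)
  xx <- rnorm(4000); yy <- rnorm(4000)
  expect_lt(abs(pearson_correlation(xx, yy)$r), 0.05)

  x2 <- rnorm(30); y2 <- x2 + rnorm(30)
  r0 <- pearson_correlation(x2, y2)
  r1 <- pearson_correlation(3 + 2 * x2, -1 + 0.5 * y2)
  expect_equal(r1$r, r0$r, tolerance = 1e-12)
  expect_equal(r1$p, r0$p, tolerance = 1e-12)

  u <- pearson_correlation(rep(1, 5), 1:5)
  expect_true(is.na(u$r))
  expect_match(u$note, "undefined")
})

test_that("repeated-measures ANOVA partitions SS and reduces to paired t at k = 2", {
  set.seed(12)
  tab <- matrix(rnorm(8 * 2, sd = 1) + rep(c(0, 0.8), each = 8), 8, 2)
  a <- rm_anova(tab)
  tt <- stats::t.test(tab[, 1], tab[, 2], paired = TRUE)
  expect_equal(a$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p, tt$p.value, tolerance = 1e-9)
  expect_equal(a$ss_total, a$ss_subjects + a$ss_treatment + a$ss_error,
               tolerance = 1e-9 * a$ss_total)

  tab3 <- matrix(rnorm(10 * 3) + rep(c(0, 0.5, 1), each = 10), 10, 3)
  a3 <- rm_anova(tab3)
  expect_equal(a3$df, 2)
  expect_equal(a3$df2, 18)
  expect_equal(a3$ss_total, a3$ss_subjects + a3$ss_treatment + a3$ss_error,
               tolerance = 1e-9 * a3$ss_total)

  # identical treatments per block: zero treatment SS
  same <- matrix(rnorm(6), 6, 3)[, c(1, 1, 1)]
  z <- rm_anova(same)
  expect_equal(z$statistic, 0)
  expect_equal(z$p, 1)
  expect_error(rm_anova(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("Bonferroni adjustment caps at one and preserves order", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 3), 1.0)
  p <- c(0.001, 0.02, 0.2, 0.9)
  expect_false(is.unsorted(bonferroni_adjust(p, 4)))
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
})

test_that("Friedman statistic: closed form, ties, base-R agreement", {
  perfect <- matrix(c(1, 1, 1, 2, 2, 2, 3, 3, 3), 3)
  f <- friedman_test(perfect)
  expect_equal(f$statistic, 6.0)
  expect_equal(f$df, 2)

  allsame <- matrix(5, 4, 3)
  f0 <- friedman_test(allsame)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p, 1)

  set.seed(9)
  for (i in 1:10) {
    tab <- matrix(rnorm(7 * 4), 7, 4)  # continuous, no ties
    ours <- friedman_test(tab)
    base <- stats::friedman.test(tab)
    expect_equal(ours$statistic, unname(base$statistic), tolerance = 1e-12)
    expect_equal(ours$p, base$p.value, tolerance = 1e-12)
  }
})

test_that("Friedman is invariant to within-block monotone transforms", {
  set.seed(5)
  tab <- matrix(rnorm(6 * 3), 6, 3)
  f0 <- friedman_test(tab)$statistic
  expect_equal(friedman_test(exp(tab))$statistic, f0)
  expect_equal(friedman_test(tab^3)$statistic, f0)
  shifted <- tab + rnorm(6)  # per-block shifts are monotone within block
  expect_equal(friedman_test(shifted)$statistic, f0)
})

test_that("Conover post hoc: identical columns give p = 1 and shifted ones rank first", {
  set.seed(21)
  base <- rnorm(20)
  tab <- cbind(t1 = base, t2 = base, t3 = base + 3)
  cp <- conover_posthoc(tab)
  expect_equal(cp$p[cp$treatment_1 == "t1" & cp$treatment_2 == "t2"], 1)
  p12 <- cp$p[cp$treatment_1 == "t1" & cp$treatment_2 == "t2"]
  p13 <- cp$p[cp$treatment_1 == "t1" & cp$treatment_2 == "t3"]
  p23 <- cp$p[cp$treatment_1 == "t2" & cp$treatment_2 == "t3"]
  expect_lt(p13, p12)
  expect_lt(p23, p12)
  expect_true(all(cp$p_bonferroni >= cp$p))
})

test_that("Conover p values agree with the permutation enumeration oracle", {
  set.seed(33)
  for (rep in 1:3) {
    n <- 5
    tab <- matrix(rnorm(n * 3) + rep(c(0, 1.5, 3), each = n), n, 3)
    cp <- conover_posthoc(tab)
    for (q in seq_len(nrow(cp))) {
      i <- as.integer(cp$treatment_1[q]); j <- as.integer(cp$treatment_2[q])
      expect_lt(abs(cp$p[q] - conover_perm_p(tab, i, j)), 0.03)
    }
  }
})

test_that("all battery p values stay within [0, 1]", {
  set.seed(50)
  for (i in 1:20) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1))
    expect_true(welch_t_test(x, y)$p >= 0 && welch_t_test(x, y)$p <= 1)
    tab <- matrix(rnorm(12), 4, 3)
    expect_true(friedman_test(tab)$p >= 0 && friedman_test(tab)$p <= 1)
    expect_true(all(conover_posthoc(tab)$p >= 0 & conover_posthoc(tab)$p <= 1))
  }
})
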