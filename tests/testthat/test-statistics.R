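test_that("omnibus normality statistic matches independently computed values", {
  # frozen cross-check: the same samples run through scipy.stats.normaltest
  # give K2 = 2.31514018 (p 0.31424885) and K2 = 28.04299318 (p 8.138e-07)
  set.seed(7)
  x <- rnorm(60)
  y <- rexp(60)
  rx <- dagostino_pearson(x)
  ry <- dagostino_pearson(y)
  expect_equal(rx$statistic, 2.31514018, tolerance = 1e-7)
  expect_equal(rx$p_value, 0.31424885, tolerance = 1e-6)
  expect_equal(ry$statistic, 28.04299318, tolerance = 1e-7)
  expect_error(dagostino_pearson(rnorm(5)),
               class = "spinemorph_parameter_error")
  expect_error(dagostino_pearson(rep(1, 20)),
               class = "spinemorph_parameter_error")
})

test_that("the normality gate passes normal and rejects skewed samples", {
  set.seed(11)
  gn <- normality_gate(rnorm(500))
  ge <- normality_gate(rexp(500))
  expect_true(gn$applicable && gn$passes)
  expect_true(ge$applicable && !ge$passes)
  gs <- normality_gate(rnorm(5))
  expect_false(gs$applicable)
  expect_false(gs$passes)
})

test_that("the gated comparison picks t for normal and Mann-Whitney otherwise", {
  set.seed(21)
  a <- rnorm(60)
  b <- rnorm(60, 0.2)
  rt <- compare_two_groups(a, b)
  expect_equal(rt$test_name, "students_t")
  expect_true(rt$gate_applied)
  rm <- compare_two_groups(exp(rnorm(60)), exp(rnorm(60, 1)))
  expect_equal(rm$test_name, "mann_whitney")
  # equal-variance Student t by default, Welch on request
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(compare_two_groups(a, b, gate = FALSE, test = "t")$p_value,
               tt$p.value)
  tw <- t.test(a, b, var.equal = FALSE)
  expect_equal(compare_two_groups(a, b, gate = FALSE, test = "t",
                                  welch = TRUE)$p_value, tw$p.value)
})

test_that("small-sample Mann-Whitney equals exhaustive enumeration", {
  set.seed(5)
  for (i in 1:4) {
    a <- round(rnorm(4, 0, 10), 2)
    b <- round(rnorm(4, 3, 10), 2)
    if (any(duplicated(c(a, b)))) next
    res <- compare_two_groups(a, b, gate = FALSE, test = "mw")
    expect_equal(res$p_value, mw_exact_p(a, b), tolerance = 1e-12)
  }
})

test_that("identical samples compare as indistinguishable", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  res <- compare_two_groups(a, a, gate = FALSE, test = "mw")
  expect_gt(res$p_value, 0.99)
  expect_false(res$significant)
})

test_that("a one-sd mean shift at n = 100 is detected", {
  set.seed(31)
  res <- compare_two_groups(rnorm(100), rnorm(100, 1))
  expect_true(res$significant)
})

test_that("KS statistic and p behave at the extremes", {
  x <- c(1, 2, 3, 4)
  same <- ks_two_sample(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disj <- ks_two_sample(1:5, 11:15)
  expect_equal(disj$statistic, 1)
  expect_true(disj$significant)
  expect_error(ks_two_sample(numeric(0), x),
               class = "spinemorph_parameter_error")
})

test_that("asymptotic KS p tracks the exhaustive permutation p at n = 6", {
  set.seed(41)
  for (i in 1:3) {
    a <- rnorm(6)
    b <- rnorm(6, 0.8)
    pa <- ks_two_sample(a, b, method = "asymptotic")$p_value
    pe <- ks_two_sample(a, b, method = "exact")$p_value
    expect_equal(pe, ks_exact_p(a, b), tolerance = 1e-12)
    expect_lt(abs(pa - pe), 0.05)
  }
})

test_that("KS D is invariant under strictly monotone transforms and ordering", {
  set.seed(51)
  a <- rnorm(30)
  b <- rnorm(30, 0.5)
  d0 <- ks_two_sample(a, b)$statistic
  expect_equal(ks_two_sample(exp(a), exp(b))$statistic, d0)
  expect_equal(ks_two_sample(sample(a), sample(b))$statistic, d0)
  expect_equal(compare_two_groups(sample(a), sample(b))$p_value,
               compare_two_groups(a, b)$p_value)
})

test_that("the KS D agrees with the reference implementation", {
  set.seed(61)
  a <- rnorm(40)
  b <- rnorm(35, 0.3)
  ours <- ks_two_sample(a, b)
  ref <- suppressWarnings(stats::ks.test(b, a))
  expect_equal(ours$statistic, unname(ref$statistic))
})

test_that("ecdf_table matches brute-force counting", {
  e <- ecdf_table(c(1, 2, 3))
  expect_equal(e$fraction, c(1, 2, 3) / 3)
  e2 <- ecdf_table(c(2, 1, 2, 3))
  expect_equal(e2$value, c(1, 2, 3))
  expect_equal(e2$fraction, c(0.25, 0.75, 1))
  set.seed(71)
  x <- sample(1:10, 30, replace = TRUE)
  e3 <- ecdf_table(x)
  for (i in seq_len(nrow(e3)))
    expect_equal(e3$fraction[i], sum(x <= e3$value[i]) / length(x))
  expect_true(all(diff(e3$fraction) > 0))
  expect_equal(e3$fraction[nrow(e3)], 1)
})

test_that("matched-pairs signed-rank test matches the reference", {
  set.seed(81)
  x <- rnorm(12)
  y <- x + rnorm(12, 0.4)
  ours <- wilcoxon_matched_pairs(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p_value, ref$p.value)
  expect_error(wilcoxon_matched_pairs(rnorm(3), rnorm(4)),
               class = "spinemorph_parameter_error")
})
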