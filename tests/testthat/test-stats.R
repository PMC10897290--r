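# Statistics policy: normality gate, Mann-Whitney, Welch, group comparisons.

test_that("the normality gate selects the test the data distribution demands", {
  set.seed(11)
  expect_equal(choose_test(rlnorm(30, 0, 2), rlnorm(30, 0, 2)), "mann_whitney")
  set.seed(12)
  expect_equal(choose_test(rnorm(30), rnorm(30, 1)), "welch_t")
  set.seed(13)
  expect_equal(choose_test(rnorm(40), rlnorm(40, 0, 2)), "mann_whitney")
  expect_error(choose_test(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("Gaussian pairs pass the gate at the Shapiro-Wilk joint rate", {
  # both samples pass at alpha = 0.05 with probability 0.95^2
  n_seeds <- 200
  hits <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    if (choose_test(rnorm(30), rnorm(30)) == "welch_t") hits <- hits + 1
  }
  frac <- hits / n_seeds
  expect_lt(abs(frac - 0.95^2), 3 * sqrt(0.9025 * 0.0975 / n_seeds))
})

test_that("the worked Mann-Whitney example and symmetry cases hold", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)           # 2 of the 20 labelings are as extreme
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(mann_whitney(numeric(), 1:3), "nonempty")
})

test_that("exact p-values equal full enumeration for small tie-free samples", {
  set.seed(17)
  for (i in 1:5) {
    a <- rnorm(sample(4:8, 1))
    b <- rnorm(sample(4:8, 1), mean = runif(1, 0, 1.5))
    r <- mann_whitney(a, b)
    expect_true(r$exact)
    expect_equal(r$p_value, enum_mann_whitney_p(a, b), tolerance = 1e-12)
  }
})

test_that("exact and approximate branches agree for n = 8 tie-free samples", {
  set.seed(19)
  for (i in 1:5) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    p_exact <- mann_whitney(a, b)$p_value
    p_approx <- mann_whitney(a, b, exact_threshold = 0)$p_value
    expect_false(mann_whitney(a, b, exact_threshold = 0)$exact)
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("tied samples take the corrected approximate branch", {
  r <- mann_whitney(c(1, 2, 2, 3, 5), c(2, 3, 3, 4, 6))
  expect_false(r$exact)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
})

test_that("Welch's t handles identical, degenerate, and swapped samples", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(welch_t(c(2, 2), c(2, 2))$p_value, 1)   # constant, equal means
  expect_error(welch_t(c(2, 2), c(3, 3)), "degenerate")
  set.seed(23)
  a <- rnorm(12); b <- rnorm(15, 0.8)
  r1 <- welch_t(a, b); r2 <- welch_t(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("Welch df reduces to the Student df for equal-variance equal-n samples", {
  set.seed(29)
  a <- rnorm(20); a <- (a - mean(a)) / sd(a)          # exactly unit variance
  b <- rnorm(20, 2); b <- (b - mean(b)) / sd(b) + 2
  r <- welch_t(a, b)
  expect_equal(r$df, 38, tolerance = 1e-9)
})

test_that("null simulation holds the nominal type-I error", {
  n_rep <- 200
  rej <- 0
  for (s in seq_len(n_rep)) {
    set.seed(s)
    if (mann_whitney(rnorm(20), rnorm(20))$p_value < 0.05) rej <- rej + 1
  }
  expect_gte(rej, qbinom(0.025, n_rep, 0.05))
  expect_lte(rej, qbinom(0.975, n_rep, 0.05))
})

test_that("group summaries and reference comparisons assemble correctly", {
  set.seed(31)
  tbl <- rbind(
    group_table("WT", 1:20, "width_nm", rnorm(20, 14.5, 2)),
    group_table("KO", 1:20, "width_nm", rnorm(20, 20, 4)),
    group_table("OE", 1:20, "width_nm", rlnorm(20, log(15), 0.5)))
  s <- summarize_groups(tbl)
  expect_setequal(s$group, c("WT", "KO", "OE"))
  expect_true(all(s$n == 20))
  cmp <- compare_groups(tbl, reference = "WT")
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$group_a == "WT"))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_true(all(cmp$test_name %in% c("mann_whitney", "welch_t")))
  cmp_h <- compare_groups(tbl, reference = "WT", adjust = "holm")
  expect_true(all(cmp_h$p_adjusted >= cmp_h$p_value))
  expect_error(compare_groups(tbl, reference = "XX"), "not present")
})

test_that("the outlier sensitivity re-run is available but off by default", {
  set.seed(37)
  a <- c(rnorm(19, 10), 60)   # one gross outlier
  tbl <- rbind(group_table("WT", 1:20, "m", a),
               group_table("KO", 1:20, "m", rnorm(20, 12)))
  base <- compare_groups(tbl)
  trimmed <- compare_groups(tbl, drop_outliers = TRUE)
  expect_equal(base$n_a, 20)
  expect_lt(trimmed$n_a, 20)
})
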