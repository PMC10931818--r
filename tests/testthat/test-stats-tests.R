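test_that("spearman rho handles monotone, reversed and tied inputs", {
  expect_equal(spearman_test(1:3, 1:3)$statistic, 1)
  expect_equal(spearman_test(1:3, 3:1)$statistic, -1)
  # mid-rank rho must agree with cor(method = "spearman") under ties
  set.seed(1)
  for (i in 1:10) {
    x <- sample(1:4, 10, replace = TRUE)
    y <- sample(1:4, 10, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_test(x, y)$statistic,
                 cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  expect_error(spearman_test(1:3, 1:4), "equal length")
  expect_error(spearman_test(1:2, 1:2), "at least 3")
})

test_that("exact permutation p is 2/720 for a perfect monotone sextet", {
  st <- spearman_test(1:6, c(0.3, 0.5, 1.1, 1.2, 3.5, 7.2))
  expect_true(st$exact)
  expect_equal(st$p_value, 2 / 720)
})

test_that("exact and approximate spearman p agree closely at n = 8", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(8); y <- 0.5 * x + rnorm(8)
    pe <- spearman_test(x, y, exact_threshold = 8)$p_value
    pa <- spearman_test(x, y, exact_threshold = 0)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("fisher exact matches hand-enumerable cases", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "negative")
  # modulated-proportion contrast at the reported cohort counts is significant
  expect_lt(fisher_exact_2x2(matrix(c(10, 27, 2, 31), 2, byrow = TRUE))$p_value,
            0.05)
})

test_that("t contrasts use pooled variance and handle degenerate input", {
  st <- t_contrast(1:3, 4:6)
  expect_equal(st$statistic, -3 / sqrt(1 * (1/3 + 1/3)), tolerance = 1e-6)
  expect_equal(st$statistic, -3.674, tolerance = 1e-3)
  expect_equal(st$df, 4)
  a <- c(1.2, 3.1, 0.5, 2.2)
  expect_equal(t_contrast(a, a, "paired")$statistic, 0)
  expect_equal(t_contrast(a, a, "paired")$p_value, 1)
  expect_equal(t_contrast(c(2, 2, 2, 2), mode = "one_sample", mu = 2)$statistic, 0)
  expect_match(t_contrast(c(2, 2, 2), c(2, 2, 2), "paired")$note, "zero variance")
})

test_that("fisher z averaging is exact, bounded and monotone", {
  expect_equal(fisher_z_mean(c(0.5, 0.5)), 0.5)
  expect_equal(fisher_z_mean(0), 0)
  expect_equal(fisher_z_mean(c(0.3, 0.7)), 0.5288, tolerance = 1e-4)
  set.seed(3)
  r <- runif(50, -0.99, 0.99)
  z <- fisher_z_mean(r)
  expect_true(z > -1 && z < 1)
  r2 <- r; r2[7] <- r2[7] + 0.005
  expect_gt(fisher_z_mean(r2), z)
  expect_warning(fisher_z_mean(c(1, 0.5)), "clipped")
  expect_error(fisher_z_mean(numeric(0)), "empty")
})

test_that("overlap test reproduces expected counts and edge cases", {
  ot <- overlap_chance_test(39, 37, 13, 101)
  expect_equal(ot$expected, 39 * 37 / 101, tolerance = 1e-12)
  expect_gt(ot$p_value, 0.05)
  expect_equal(overlap_chance_test(0, 37, 0, 101)$p_value, 1)
  expect_equal(overlap_chance_test(0, 37, 0, 101)$expected, 0)
  ext <- overlap_chance_test(20, 20, 20, 40)
  expect_lt(ext$p_value, 0.01)
  expect_equal(ext$effect_direction, "positive")
  expect_error(overlap_chance_test(5, 5, 6, 20), "inconsistent")
  # hypergeometric route agrees with the base fisher.test on the 2x2 layout
  p_ft <- fisher.test(matrix(c(13, 39 - 13, 37 - 13, 101 - 39 - 37 + 13), 2))$p.value
  expect_equal(ot$p_value, p_ft, tolerance = 1e-9)
})

test_that("permutation overlap variant approximates the exact p", {
  pe <- overlap_chance_test(15, 12, 3, 40)$p_value
  pp <- overlap_chance_test(15, 12, 3, 40, method = "permutation",
                            n_perm = 20000, seed = 9)$p_value
  expect_lt(abs(pe - pp), 0.03)
})

test_that("all reported p-values stay within [0, 1]", {
  set.seed(11)
  for (i in 1:25) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(length(x))
    expect_true(spearman_test(x, y)$p_value >= 0,
                label = "spearman p lower bound")
    expect_true(spearman_test(x, y)$p_value <= 1)
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) > 0) {
      p <- fisher_exact_2x2(tab)$p_value
      expect_true(p >= 0 && p <= 1)
    }
  }
})
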