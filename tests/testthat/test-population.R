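test_that("per-mouse proportion contrast behaves at the boundaries", {
  expect_equal(proportion_contrast(c(30, 40, 50), c(30, 40, 50))$p_value, 1)
  expect_error(proportion_contrast(30, 30), "2 mice")
  st <- proportion_contrast(c(50, 60, 55, 58), c(20, 25, 22, 24))
  expect_lt(st$p_value, 0.01)
  expect_equal(st$effect_direction, "positive")
})

test_that("amplitude contrast is the pooled-variance unpaired t", {
  set.seed(40)
  a <- rnorm(37, 0.646, 0.37); b <- rnorm(33, 0.427, 0.36)
  st <- amplitude_contrast(a, b)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(st$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(st$df, 68)
})

test_that("length modulation flags increasing activity, not constants", {
  set.seed(41)
  lens <- rep(c(1, 3, 4, 5, 6, 8), each = 5)
  act_up <- as.integer(assign_length_group(lens)) + rnorm(30, 0, 0.2)
  row <- length_modulation(act_up, lens)
  expect_true(row$positively_modulated)
  expect_gt(row$rho, 0.8)
  row_const <- length_modulation(rep(1, 30), lens)
  expect_false(row_const$positively_modulated)
  expect_equal(row_const$rho, 0)
  # only two distinct groups is unclassifiable
  row2 <- length_modulation(rnorm(20), rep(c(2, 4), 10))
  expect_false(row2$classifiable)
  # per-group means are reported on the ordinal grid
  expect_equal(row$`mean_<=2`, mean(act_up[lens == 1]), tolerance = 1e-12)
})

test_that("negative or null coding stays below the nominal rate", {
  set.seed(42)
  n <- 300
  lens <- rlength(120, 4)
  flags <- vapply(seq_len(n), function(i)
    length_modulation(rnorm(120), lens)$positively_modulated, logical(1))
  expect_lte(mean(flags), 0.05 + 2 * sqrt(0.05 * 0.95 / n))
})

test_that("length proportion contrast matches fisher.test on cohort counts", {
  st <- length_proportion_contrast(10, 37, 2, 33)
  expect_lt(st$p_value, 0.05)
  expect_equal(st$p_value,
               fisher.test(matrix(c(10, 27, 2, 31), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
  expect_equal(length_proportion_contrast(0, 37, 0, 33)$p_value, 1)
  expect_error(length_proportion_contrast(40, 37, 2, 33), "inconsistent")
})

test_that("reward laterality runs both test pairs per class", {
  set.seed(43)
  mk <- function(mouse, cond, n, p_rw, p_mg, rw_amp, mg_amp) {
    tibble::tibble(mouse = mouse, neuron_id = paste0(mouse, cond, seq_len(n)),
                   condition = cond,
                   is_reward = runif(n) < p_rw, is_magazine = runif(n) < p_mg,
                   max_post_lick = rnorm(n, rw_amp, 0.3),
                   max_pre_lick = rnorm(n, mg_amp, 0.3))
  }
  mt <- dplyr::bind_rows(lapply(paste0("m", 1:6), function(m)
    dplyr::bind_rows(mk(m, "contra", 17, 0.25, 0.15, 1.0, 1.49),
                     mk(m, "ipsi", 17, 0.25, 0.15, 1.0, 0.66))))
  out <- reward_laterality(mt)
  expect_setequal(unique(out$class), c("reward", "magazine_approach"))
  expect_equal(nrow(out), 4)
  amp_mag <- out[out$class == "magazine_approach" & out$test == "peak_unpaired_t", ]
  expect_lt(amp_mag$p, 0.05)
  amp_rw <- out[out$class == "reward" & out$test == "peak_unpaired_t", ]
  expect_gt(amp_rw$p, 0.01)
})

test_that("overlap analysis agrees with the underlying counts", {
  set.seed(44)
  mv <- runif(101) < 0.39
  rw <- runif(101) < 0.37
  ot <- overlap_analysis(mv, rw)
  expect_equal(ot$statistic, sum(mv & rw))
  expect_equal(ot$expected, sum(mv) * sum(rw) / 101)
  expect_error(overlap_analysis(mv, rw[-1]), "align")
})

test_that("contra/ipsi label flip exactly exchanges the laterality result", {
  set.seed(45)
  a <- rnorm(20, 0.6, 0.3); b <- rnorm(18, 0.4, 0.3)
  s1 <- amplitude_contrast(a, b)
  s2 <- amplitude_contrast(b, a)
  expect_equal(s1$statistic, -s2$statistic, tolerance = 1e-12)
  expect_equal(s1$p_value, s2$p_value, tolerance = 1e-12)
})
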