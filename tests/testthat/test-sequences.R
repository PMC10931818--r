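test_that("length groups pool 1-2 and 7+ as ordered categories", {
  g <- assign_length_group(c(1, 2, 3, 4, 5, 6, 7, 11))
  expect_equal(as.character(g), c("<=2", "<=2", "3", "4", "5", "6", "7+", "7+"))
  expect_true(is.ordered(g))
  expect_error(assign_length_group(0), ">= 1")
})

test_that("target IPI follows window/(n-1)", {
  expect_equal(round(target_ipi(4, 1), 3), 0.333)
  expect_equal(target_ipi(2, 1), 1)
  expect_equal(target_ipi(4, 2), 2 / 3)
  expect_error(target_ipi(1, 1), "at least 2")
})

test_that("reward eligibility requires n consecutive presses within window", {
  expect_true(reward_eligible(c(0, 0.3, 0.6, 0.9)))
  expect_false(reward_eligible(c(0, 0.5, 1.0, 1.5)))
  expect_true(reward_eligible(c(0, 0.1, 0.2, 0.3, 5.0)))
  expect_false(reward_eligible(c(0, 0.3, 0.6)))
  # all IPIs strictly below the target IPI guarantees eligibility
  set.seed(4)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    ipis <- runif(n - 1, 0.05, target_ipi(4, 1) - 1e-6)
    expect_true(reward_eligible(cumsum(c(0, ipis))))
  }
})

test_that("occupancy segmentation reproduces the defining examples", {
  b <- segment_sequences(simple_log(c(1, 1.3, 1.6, 1.9), rbind(c(0.5, 2.5))))
  expect_equal(nrow(b), 1)
  expect_equal(b$n_presses, 4)
  expect_equal(b$limb, "contra")
  b2 <- segment_sequences(simple_log(c(1, 5), rbind(c(0.5, 1.5), c(4.5, 5.5))))
  expect_equal(b2$n_presses, c(1, 1))
  expect_equal(nrow(segment_sequences(simple_log(numeric(0),
                                                 matrix(numeric(), ncol = 2)))), 0)
})

test_that("press conservation: bouts plus orphans account for every press", {
  set.seed(10)
  for (i in 1:10) {
    occ <- cbind(seq(5, 95, by = 10), seq(5, 95, by = 10) + runif(10, 2, 6))
    presses <- sort(runif(40, 0, 100))
    presses <- presses[c(TRUE, diff(presses) > 1e-3)]
    log <- simple_log(presses, occ, duration = 110)
    b <- segment_sequences(log)
    expect_equal(sum(b$n_presses) + attr(b, "n_orphans"), length(presses))
    # every non-orphan press belongs to exactly one bout
    expect_equal(anyDuplicated(unlist(b$press_times)), 0)
  }
})

test_that("segmentation is invariant to a global time shift", {
  presses <- c(3, 3.4, 3.7, 12, 12.5)
  occ <- rbind(c(2.5, 4.5), c(11.5, 13))
  b1 <- segment_sequences(simple_log(presses, occ, duration = 50))
  b2 <- segment_sequences(simple_log(presses + 7, occ + 7, duration = 57))
  expect_equal(b1$n_presses, b2$n_presses)
  expect_equal(b2$start - b1$start, rep(7, nrow(b1)))
})

test_that("gap rule splits bouts for logs without occupancy data", {
  log <- event_log("s1", lever_side = "left", hemisphere = "right",
                   press_times = c(1, 1.3, 1.6, 6, 6.2), session_duration = 30)
  b <- segment_sequences(log, gap_threshold = 2)
  expect_equal(b$n_presses, c(3, 2))
})

test_that("behavior metrics match hand-computed values", {
  log <- simple_log(c(1, 1.2, 1.6), rbind(c(0.5, 2)), duration = 120)
  b <- segment_sequences(log)
  m <- behavior_metrics(log, b)
  expect_equal(m$presses_per_min, 3 / 2)
  expect_equal(m$pct_presses_in_sequence, 100)
  # IPIs 0.2, 0.4: sample var 0.02, mean 0.3 -> fano 1/15
  expect_equal(m$ipi_fano, 0.02 / 0.3, tolerance = 1e-12)
  expect_equal(m$ipi_mean, 0.3)
  # constant IPIs give zero fano
  log2 <- simple_log(c(1, 1.3, 1.6, 1.9), rbind(c(0.5, 2.5)))
  m2 <- behavior_metrics(log2, segment_sequences(log2))
  expect_equal(m2$ipi_fano, 0)
  # single-press session has no IPI
  log3 <- simple_log(2, rbind(c(1.5, 2.5)))
  m3 <- behavior_metrics(log3, segment_sequences(log3))
  expect_true(is.na(m3$ipi_fano))
  expect_equal(m3$pct_presses_in_sequence, 0)
})
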