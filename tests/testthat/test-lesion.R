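test_that("long-sequence threshold is the baseline mean, strictly exceeded", {
  expect_equal(long_sequence_threshold(c(4, 4, 4)), 4)
  expect_equal(long_sequence_threshold(c(2, 6)), 4)
  expect_error(long_sequence_threshold(numeric(0)), "empty")
  # post-treatment [5, 3] against threshold 4 -> 50% long
  expect_equal(sncvigor:::pct_long(c(5, 3), 4), 50)
  # values equal to the threshold are not long (strict inequality)
  expect_equal(sncvigor:::pct_long(c(4, 4, 4), 4), 0)
})

make_lesion_bouts <- function(means, n_mice = 6, n_bouts = 60, noise = 0,
                              group = "6OHDA") {
  rows <- list()
  for (m in seq_len(n_mice)) {
    off <- rnorm(1, 0, noise)
    for (limb in c("contra", "ipsi")) for (epoch in c("before", "after")) {
      mu <- means[[limb]][[epoch]] + off
      rows[[length(rows) + 1]] <- tibble::tibble(
        mouse = paste0("m", m), group = group, epoch = epoch, limb = limb,
        n_presses = pmax(1, round(rnorm(n_bouts, mu, 1))))
    }
  }
  dplyr::bind_rows(rows)
}

test_that("identical before/after distributions give null effects", {
  set.seed(50)
  rows <- list()
  for (m in 1:6) for (limb in c("contra", "ipsi")) {
    lens <- pmax(1, rpois(80, 4))
    for (epoch in c("before", "after"))
      rows[[length(rows) + 1]] <- tibble::tibble(
        mouse = paste0("m", m), group = "saline", epoch = epoch, limb = limb,
        n_presses = lens)  # exactly the same bouts in both epochs
  }
  res <- lesion_stats(dplyr::bind_rows(rows))$saline
  expect_equal(res$anova_length$anova$F, c(0, res$anova_length$anova$F[2], 0),
               tolerance = 1e-9)
  expect_equal(res$ratios$len_ratio, rep(1, 12))
  one_samp <- res$tests[res$tests$test == "contra_ratio_vs_1" &
                          res$tests$measure == "presses_per_sequence", ]
  expect_equal(one_samp$p, 1)
})

test_that("swapping epochs inverts the per-mouse ratios exactly", {
  set.seed(51)
  b <- make_lesion_bouts(list(contra = list(before = 4.1, after = 2.2),
                              ipsi = list(before = 4.1, after = 3.5)))
  res <- lesion_stats(b)[["6OHDA"]]
  b_swap <- b
  b_swap$epoch <- ifelse(b$epoch == "before", "after", "before")
  res_swap <- lesion_stats(b_swap)[["6OHDA"]]
  o1 <- res$ratios[order(res$ratios$mouse, res$ratios$limb), ]
  o2 <- res_swap$ratios[order(res_swap$ratios$mouse, res_swap$ratios$limb), ]
  expect_equal(o2$len_ratio, 1 / o1$len_ratio, tolerance = 1e-12)
})

test_that("a planted contralateral collapse yields the expected contrasts", {
  set.seed(52)
  b <- simulate_lesion_bouts(sim_config(seed = 52), "6OHDA")
  res <- lesion_stats(b)[["6OHDA"]]
  an <- res$anova_length$anova
  expect_lt(an$p[an$factor == "epoch"], 0.01)
  expect_lt(an$p[an$factor == "epoch_x_limb"], 0.05)
  ratio <- res$tests[res$tests$measure == "presses_per_sequence", ]
  expect_lt(ratio$p[ratio$test == "contra_ratio_vs_1"], 0.01)
  expect_lt(ratio$mean_contra_ratio[1], ratio$mean_ipsi_ratio[1])
  # the long-sequence fraction collapses contralaterally
  sm <- res$summary
  cb <- mean(sm$pct_long[sm$limb == "contra" & sm$epoch == "before"])
  ca <- mean(sm$pct_long[sm$limb == "contra" & sm$epoch == "after"])
  expect_lt(ca, cb)
})

test_that("mice with incomplete designs are excluded and reported", {
  set.seed(53)
  b <- make_lesion_bouts(list(contra = list(before = 4, after = 3),
                              ipsi = list(before = 4, after = 4)))
  b <- b[!(b$mouse == "m1" & b$epoch == "after" & b$limb == "ipsi"), ]
  res <- lesion_stats(b)[["6OHDA"]]
  expect_equal(res$excluded_mice, "m1")
  expect_equal(length(unique(res$summary$mouse)), 5)
})
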