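test_that("cross-day correlation takes the maximum over shared events", {
  x <- sin(seq(0, 6, length.out = 160))
  a <- list(press_contra = x, press_ipsi = rnorm(160))
  expect_equal(crossday_peth_correlation(a, a), 1)
  b <- list(press_contra = -x, press_ipsi = rev(a$press_ipsi))
  # monotone-decreasing transform of one event dominates at rho near -1;
  # the max rule still picks the larger of the two correlations
  r <- crossday_peth_correlation(a, b)
  expect_equal(r, max(cor(x, -x, method = "spearman"),
                      cor(a$press_ipsi, b$press_ipsi, method = "spearman")))
  one_event_hit <- crossday_peth_correlation(
    list(e1 = x, e2 = rnorm(160)), list(e1 = x, e2 = rnorm(160)))
  expect_equal(one_event_hit, 1)
  expect_error(crossday_peth_correlation(list(a = x), list(b = x)), "no shared")
})

test_that("matched correlations are z-averaged over session pairs", {
  x <- cumsum(rnorm(160))
  sess <- list(list(e = x), list(e = x + rnorm(160, 0, 0.1)),
               list(e = x + rnorm(160, 0, 0.1)))
  r <- matched_correlation(sess)
  prs <- combn(3, 2)
  manual <- fisher_z_mean(apply(prs, 2, function(ij)
    crossday_peth_correlation(sess[[ij[1]]], sess[[ij[2]]])))
  expect_equal(r, manual)
  expect_error(matched_correlation(sess[1]), "2 sessions")
})

test_that("time-shuffled control centers near zero for white-noise tuning", {
  set.seed(30)
  vals <- replicate(200, {
    sess <- lapply(1:2, function(s) list(e = rnorm(160)))
    control_correlations(sess, mode = "shuffled")
  })
  expect_lt(abs(mean(vals)), 2 * sd(vals) / sqrt(length(vals)) + 0.02)
})

test_that("different-ROI control finds an identical alternative", {
  x <- cumsum(rnorm(160))
  ref <- list(list(e = x), list(e = x))
  twin <- list(list(e = x), list(e = x))
  expect_equal(suppressWarnings(
    control_correlations(ref, list(twin), mode = "different")), 1,
    tolerance = 1e-4)
  expect_error(control_correlations(ref, list(), mode = "different"),
               "at least one other")
})

test_that("stability summary recovers matched > different > shuffled ordering", {
  cfg <- sim_config(seed = 2)
  peths <- simulate_stable_peths(cfg, n_roi = 14, seed = 31)
  records <- dplyr::bind_rows(lapply(seq_along(peths), function(i) {
    others <- peths[-i]
    tibble::tibble(
      roi = paste0("r", i),
      group = c("matched", "shuffled", "different"),
      value = c(matched_correlation(peths[[i]]),
                control_correlations(peths[[i]], mode = "shuffled", seed = i),
                control_correlations(peths[[i]], others, mode = "different")))
  }))
  s <- stability_summary(records)
  expect_gt(s$group_means["matched"], s$group_means["different"])
  expect_gt(s$group_means["different"], s$group_means["shuffled"])
  expect_lt(s$anova$p, 0.001)
  expect_equal(s$n_roi, 14)
  expect_gt(s$pct_matched_strong, 50)
  # Tukey contrasts involving the matched group are significant
  tk <- s$tukey
  expect_lt(tk$p[tk$contrast == "matched vs shuffled"], 0.01)
})

test_that("incomplete ROIs are dropped and counted", {
  rec <- tibble::tibble(roi = c("a", "a", "a", "b", "b", "b", "c"),
                        group = c("matched", "shuffled", "different",
                                  "matched", "shuffled", "different",
                                  "matched"),
                        value = c(0.8, 0.1, 0.3, 0.7, 0.0, 0.2, 0.9))
  s <- stability_summary(rec)
  expect_equal(s$n_roi, 2)
  expect_equal(s$n_dropped, 1)
})
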