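test_that("config validates fields and rejects unknown ones", {
  expect_error(sim_config(bogus = 1), "unknown config")
  expect_error(sim_config(kernel_rise = 1, kernel_decay = 0.5))
  cfg <- sim_config(seed = 5, n_mice = 3)
  expect_equal(cfg$n_mice, 3)
  expect_s3_class(cfg, "sim_config")
})

test_that("truncated length distribution hits its mean and support", {
  set.seed(60)
  for (target in c(2.2, 4, 6.5)) {
    draws <- rlength(10000, target)
    expect_true(all(draws >= 1 & draws <= 12))
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - target), 2 * se + 0.02)
  }
})

test_that("behavior simulation is deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 8)
  s1 <- simulate_behavior(cfg)
  s2 <- simulate_behavior(cfg)
  expect_identical(s1$bouts, s2$bouts)
  expect_identical(s1$logs[[3]]$press_times, s2$logs[[3]]$press_times)
  s3 <- simulate_behavior(small_cfg(seed = 9))
  expect_false(identical(s1$bouts$first_press, s3$bouts$first_press))
})

test_that("simulated sessions respect the task rules", {
  cfg <- small_cfg(seed = 10)
  sim <- simulate_behavior(cfg)
  for (sid in names(sim$logs)[1:4]) {
    log <- sim$logs[[sid]]
    b <- sim$bouts[sim$bouts$session_id == sid, ]
    # every emitted reward belongs to a reward-eligible bout
    expect_equal(length(log$reward_times), sum(b$rewarded))
    segs <- segment_sequences(log)
    expect_equal(sum(segs$n_presses), length(log$press_times))  # no orphans
    expect_equal(segs$n_presses, b$n_presses)
    expect_true(all(segs$rewarded == b$rewarded))
    expect_lte(length(log$reward_times), cfg$max_rewards)
    # first lick follows its reward
    expect_true(all(log$lick_times > log$reward_times))
  }
})

test_that("sampled bout statistics track the configured scales", {
  sim <- simulate_behavior(sim_config(seed = 11, n_mice = 2, n_days = 1))
  lens <- sim$bouts$n_presses
  expect_lt(abs(mean(lens) - 4), 3 * sd(lens) / sqrt(length(lens)) + 0.05)
  ipis <- unlist(lapply(sim$logs, function(l)
    unlist(lapply(segment_sequences(l)$press_times,
                  function(p) if (length(p) > 1) diff(p)))))
  expect_gt(mean(ipis), 0.25)
  expect_lt(mean(ipis), 0.40)
})

test_that("kernel is unit-peak and jitter attenuation is sub-unity", {
  k <- gcamp_kernel()
  expect_equal(max(k), 1)
  expect_equal(k[1], 0)
  att <- sncvigor:::movement_attenuation(sim_config())
  expect_gt(att, 0.2)
  expect_lt(att, 1)
})

test_that("noiseless traces reproduce the planted mean-PETH amplitude", {
  cfg <- sim_config(seed = 12, n_mice = 1, n_days = 3,
                    n_neurons_per_mouse = 2, noise_sd = 1e-6,
                    p_movement = 1, p_reward = 0, p_magazine = 0,
                    p_length_coder = 0)
  sim <- simulate_behavior(cfg)
  tr <- simulate_traces(cfg, sim)
  for (limb_target in list(c("contra", cfg$amp_move_contra),
                           c("ipsi", cfg$amp_move_ipsi))) {
    sids <- names(sim$logs)[vapply(sim$logs, function(l)
      sncvigor:::limb_from_sides(l$lever_side, l$hemisphere) == limb_target[1],
      logical(1))]
    ps <- lapply(sids, function(s) {
      b <- sim$bouts[sim$bouts$session_id == s, ]
      build_peth(tr$traces[[s]]$values[1, ], b$first_press)
    })
    peak <- max_activity(combine_peths(ps), c(-2, 0))
    target <- as.numeric(limb_target[2])
    expect_equal(peak, target, tolerance = 0.15 * target)
  }
})

test_that("length coders produce monotone group means when noiseless", {
  cfg <- sim_config(seed = 13, trial_noise_sd = 1e-9)
  la <- simulate_length_activity(cfg, n_neurons = 3, n_bouts = 300,
                                 condition = "contra", seed = 14)
  grp <- assign_length_group(la$n_presses)
  gm <- tapply(la$activity[1, ], grp, mean)
  gm <- gm[!is.na(gm)]
  expect_true(all(diff(gm) > 0))
  # ipsilateral generator plants no gain
  li <- simulate_length_activity(cfg, n_neurons = 2, n_bouts = 300,
                                 condition = "ipsi", seed = 14)
  expect_equal(li$gain, 0)
})

test_that("lesion generator reproduces the planted cell means", {
  cfg <- sim_config(seed = 15, lesion_mouse_sd = 1e-6, bouts_per_cell = 400L)
  b <- simulate_lesion_bouts(cfg, "6OHDA")
  cells <- dplyr::summarise(dplyr::group_by(b, epoch, limb),
                            m = mean(n_presses), se = sd(n_presses) / sqrt(dplyr::n()),
                            .groups = "drop")
  planted <- c(cfg$lesion_contra_means["after"], cfg$lesion_contra_means["before"],
               cfg$lesion_ipsi_means["after"], cfg$lesion_ipsi_means["before"])
  cells <- cells[order(cells$limb, cells$epoch), ]
  for (i in 1:4)
    expect_lt(abs(cells$m[i] - planted[i]), 3 * cells$se[i] + 0.05)
})

test_that("trace simulation is reproducible and emits jittered centroids", {
  cfg <- small_cfg(seed = 16)
  sim <- simulate_behavior(cfg)
  t1 <- simulate_traces(cfg, sim)
  t2 <- simulate_traces(cfg, sim)
  expect_identical(t1$traces[[1]]$values, t2$traces[[1]]$values)
  r1 <- t1$rois[[1]]; r2 <- t1$rois[[2]]
  expect_equal(r1$roi, r2$roi)
  expect_false(all(r1$x == r2$x))
  d <- sqrt((r1$x - r2$x)^2 + (r1$y - r2$y)^2)
  expect_lt(max(d), 10)
})
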