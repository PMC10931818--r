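simulate_one_session <- function(cfg, session_id, mouse_id, day_index,
                                 lever_side, hemisphere, epoch = "none",
                                 treatment = "none", length_mean = NULL) {
  length_mean <- length_mean %||% cfg$length_mean
  rate <- cfg$bout_rate_per_min / 60
  pad <- cfg$occupancy_pad
  margin <- 10  # keep full PETH windows inside the recording
  t <- margin
  presses <- list(); occ <- list(); rewards <- numeric(); licks <- numeric()
  truth <- list()
  b <- 0L
  repeat {
    t <- t + stats::rexp(1, rate)
    len <- rlength(1L, length_mean, cfg$length_support)
    ipis <- stats::rlnorm(max(len - 1L, 0L), log(cfg$ipi_median), cfg$ipi_sigma)
    p <- t + cumsum(c(0, ipis))
    bout_end <- p[len]
    if (bout_end + margin > cfg$session_duration) break
    b <- b + 1L
    presses[[b]] <- p
    occ_start <- t - pad
    if (b > 1L) occ_start <- max(occ_start, occ[[b - 1L]][2] + 0.05)
    occ[[b]] <- c(occ_start, bout_end + pad)
    rewarded <- FALSE
    lick_time <- NA_real_
    if (len >= cfg$n_required) {
      idx <- seq_len(len - cfg$n_required + 1L)
      hit <- which(p[idx + cfg$n_required - 1L] - p[idx] < cfg$reward_window)
      if (length(hit)) {
        rewarded <- TRUE
        rt <- p[hit[1] + cfg$n_required - 1L]
        rewards <- c(rewards, rt)
        # variable magazine-approach time before the first rewarded lick
        delay <- 0.2 + min(stats::rlnorm(1, log(cfg$lick_delay),
                                         cfg$lick_delay_sigma), 5)
        lick_time <- rt + delay
        licks <- c(licks, lick_time)
      }
    }
    truth[[b]] <- tibble::tibble(
      session_id = session_id, mouse_id = mouse_id, day_index = day_index,
      bout_id = b, first_press = p[1], n_presses = len,
      rewarded = rewarded, lick_time = lick_time)
    t <- bout_end + pad
    if (length(rewards) >= cfg$max_rewards) break
  }
  end_time <- if (b > 0L) occ[[b]][2] + margin else 2 * margin
  duration <- min(cfg$session_duration, end_time)
  log <- event_log(session_id = session_id, mouse_id = mouse_id,
                   day_index = day_index, lever_side = lever_side,
                   hemisphere = hemisphere, epoch = epoch,
                   treatment = treatment,
                   press_times = unlist(presses), lick_times = licks,
                   reward_times = rewards,
                   occupancy = if (b > 0L) do.call(rbind, occ) else matrix(numeric(), ncol = 2),
                   session_duration = duration)
  list(log = log, truth = if (b > 0L) dplyr::bind_rows(truth) else tibble::tibble())
}

#' Simulate the behavioral arm of the task
#'
#' Generates event logs for every mouse x day x forelimb session of the
#' imaging design: bout onsets follow a Poisson process at the configured
#' rate, bout lengths are drawn from a truncated Poisson matched to the
#' configured mean, inter-press intervals are i.i.d. log-normal, each bout
#' is wrapped in a snout-occupancy interval, and reward plus first-lick
#' events are emitted whenever four consecutive presses fall within the
#' 1 s completion window. Sessions stop at the configured reward cap or
#' session duration. All randomness is governed by `cfg$seed`; re-running
#' with the same seed reproduces the logs exactly.
#'
#' @param cfg a [sim_config()].
#' @return List with `logs` (named list of [event_log]) and `bouts` (ground
#'   truth tibble with session, limb, first-press and lick times, lengths
#'   and reward flags).
#' @export
simulate_behavior <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  logs <- list(); truths <- list()
  for (m in seq_len(cfg$n_mice)) {
    hemi <- if (m %% 2L == 0L) "left" else "right"
    for (d in seq_len(cfg$n_days)) {
      for (side in c("left", "right")) {
        sid <- sprintf("m%02d_d%d_%s", m, d, side)
        s <- simulate_one_session(cfg, sid, sprintf("m%02d", m), d, side, hemi)
        logs[[sid]] <- s$log
        if (nrow(s$truth)) {
          s$truth$limb <- limb_from_sides(side, hemi)
          truths[[sid]] <- s$truth
        }
      }
    }
  }
  list(logs = logs, bouts = dplyr::bind_rows(truths))
}

#' Simulate bout lengths for the unilateral-lesion design
#'
#' Bout-length-only generator for the before/after x forelimb lesion
#' contrast. Each mouse receives its own mean bout length per design cell:
#' the planted cell mean plus a mouse-level Gaussian deviation (SD
#' calibrated to the dispersion of the printed group means), with bout
#' lengths then drawn from the truncated Poisson family used by the full
#' behavioral generator.
#'
#' @param cfg a [sim_config()].
#' @param group `"6OHDA"` or `"saline"`.
#' @param seed optional seed override (defaults to `cfg$seed`).
#' @return Tibble with columns `mouse`, `group`, `epoch`, `limb`,
#'   `n_presses`, ready for [lesion_stats()].
#' @export
simulate_lesion_bouts <- function(cfg, group = c("6OHDA", "saline"),
                                  seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  group <- match.arg(group)
  set.seed(seed %||% cfg$seed)
  n <- if (group == "6OHDA") cfg$n_lesion else cfg$n_saline
  sdm <- if (group == "6OHDA") cfg$lesion_mouse_sd else cfg$saline_mouse_sd
  means <- if (group == "6OHDA") {
    list(contra = cfg$lesion_contra_means, ipsi = cfg$lesion_ipsi_means)
  } else {
    list(contra = cfg$saline_contra_means, ipsi = cfg$saline_ipsi_means)
  }
  sup <- cfg$length_support
  lo <- min(sup) + 0.1; hi <- max(sup) - 0.1
  rows <- list()
  for (m in seq_len(n)) {
    for (limb in c("contra", "ipsi")) {
      for (epoch in c("before", "after")) {
        mu <- min(max(means[[limb]][[epoch]] + stats::rnorm(1, 0, sdm), lo), hi)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          mouse = sprintf("%s_m%02d", group, m), group = group,
          epoch = epoch, limb = limb,
          n_presses = rlength(cfg$bouts_per_cell, mu, sup))
      }
    }
  }
  dplyr::bind_rows(rows)
}
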