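#' Simulation configuration
#'
#' Builds the configuration for the synthetic-data generator. The defaults
#' ARE the study conditions the analyses target: 6 imaged mice, 3
#' performance days with one session per forelimb per day, the FR4/1-s
#' reward rule with sessions capped at 30 rewards or 30 min, bout lengths
#' peaking at 4 presses, log-normal inter-press intervals with median near
#' 0.35 s, ~17 neurons per mouse (~100 total), planted class probabilities
#' 0.39 (movement) / 0.37 (reward) / 0.15 (magazine approach), pre-press
#' amplitudes of 0.646 (contra) vs 0.427 (ipsi) z, non-lateralized reward
#' responses near 1 z, lateralized magazine-approach responses (1.49 vs
#' 0.66 z), and a contralateral-only sequence-length gain. Lesion-arm
#' parameters plant the observed contralateral collapse of mean sequence
#' length (4.12 to 2.17 presses) against a mild ipsilateral decline (4.13
#' to 3.52), with a small non-lateralized decline in the saline arm.
#'
#' Amplitudes are specified on the scale of the measured quantity (the peak
#' of the trial-averaged PETH in z-units); the trace generator internally
#' compensates for the temporal jitter of movement transients (see
#' [simulate_traces()]).
#'
#' @param seed integer seed controlling every random draw.
#' @param ... named overrides of any default listed above.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # cohort / schedule
    n_mice = 6L,
    n_days = 3L,
    session_duration = 1800,
    max_rewards = 30L,
    # behavior
    bout_rate_per_min = 4,
    length_mean = 4,
    length_support = 1:12,
    ipi_median = 0.28,
    ipi_sigma = 0.5,
    occupancy_pad = 0.5,
    lick_delay = 1.6,
    lick_delay_sigma = 0.5,
    n_required = 4L,
    reward_window = 1,
    # imaging
    sampling_rate = 10,
    n_neurons_per_mouse = 17L,
    p_movement = 0.39,
    p_reward = 0.37,
    p_magazine = 0.15,
    p_length_coder = 0.7,
    kernel_rise = 0.08,
    kernel_decay = 0.4,
    amp_move_contra = 0.646,
    amp_move_ipsi = 0.427,
    amp_reward = 1.0,
    amp_magazine_contra = 1.49,
    amp_magazine_ipsi = 0.66,
    length_gain = 0.1,
    trial_noise_sd = 0.7,
    noise_sd = 1,
    move_jitter = c(-1.5, -0.3),
    magazine_ramp_s = 1.0,
    # field of view / matching
    fov_px = 200,
    centroid_spacing = 15,
    centroid_jitter = 1,
    # lesion arm
    n_lesion = 8L,
    n_saline = 6L,
    lesion_contra_means = c(before = 4.12, after = 2.17),
    lesion_ipsi_means = c(before = 4.13, after = 3.52),
    saline_contra_means = c(before = 3.40, after = 2.73),
    saline_ipsi_means = c(before = 3.06, after = 2.46),
    lesion_mouse_sd = 0.57,
    saline_mouse_sd = 0.80,
    bouts_per_cell = 400L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$p_movement + 0 <= 1, cfg$p_reward + cfg$p_magazine <= 1,
            cfg$kernel_rise > 0, cfg$kernel_decay > cfg$kernel_rise,
            cfg$bout_rate_per_min > 0, cfg$length_mean > min(cfg$length_support),
            cfg$length_mean < max(cfg$length_support))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d mice x %d days, %g z contra / %g z ipsi movement amplitude, seed %d\n",
              x$n_mice, x$n_days, x$amp_move_contra, x$amp_move_ipsi, x$seed))
  invisible(x)
}

# Poisson rate whose truncation to `support` has the requested mean.
lambda_for_mean <- function(target, support = 1:12) {
  stopifnot(target > min(support), target < max(support))
  f <- function(loglam) {
    p <- stats::dpois(support, exp(loglam))
    sum(support * p) / sum(p) - target
  }
  exp(stats::uniroot(f, c(-4, 4), tol = 1e-10)$root)
}

# Draw bout lengths from the truncated Poisson with the given mean.
rlength <- function(n, mean, support = 1:12) {
  lam <- lambda_for_mean(mean, support)
  p <- stats::dpois(support, lam)
  sample(support, n, replace = TRUE, prob = p)
}
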