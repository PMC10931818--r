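#' GCaMP6f-like transient kernel
#'
#' Double-exponential calcium-transient kernel (difference of a decay and a
#' rise exponential), normalized to unit peak, sampled at the imaging rate.
#'
#' @param sampling_rate Hz.
#' @param rise,decay time constants in seconds.
#' @param dur kernel duration in seconds (default 3).
#' @return Numeric kernel vector starting at the event sample.
#' @export
gcamp_kernel <- function(sampling_rate = 10, rise = 0.08, decay = 0.4,
                         dur = 3) {
  t <- seq(0, dur, by = 1 / sampling_rate)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

# Peak attenuation of the trial-averaged PETH caused by uniform temporal
# jitter of the movement transient. Computed on the imaging sample grid
# (events land on samples), so configured amplitudes can be specified on
# the mean-PETH scale.
movement_attenuation <- function(cfg) {
  dt <- 1 / cfg$sampling_rate
  kern <- gcamp_kernel(cfg$sampling_rate, cfg$kernel_rise, cfg$kernel_decay)
  offs <- seq(round(cfg$move_jitter[1] / dt), round(cfg$move_jitter[2] / dt))
  nt <- length(kern) + length(offs)
  avg <- numeric(nt)
  for (o in offs - min(offs)) {
    idx <- seq_along(kern) + o
    avg[idx] <- avg[idx] + kern
  }
  max(avg) / length(offs)
}

#' Draw the neuron roster and ground-truth tuning
#'
#' One row per neuron: movement membership is Bernoulli(`p_movement`);
#' reward and magazine-approach membership come from a single uniform draw
#' (mutually exclusive with each other, independent of movement, so the
#' movement x reward overlap is calibrated to chance); a configurable
#' fraction of movement neurons are contralateral length coders.
#'
#' @param cfg a [sim_config()].
#' @return Tibble: `mouse_id`, `neuron_id`, class flags, `coder`, and base
#'   field-of-view centroid coordinates (`x0`, `y0`).
#' @keywords internal
simulate_neuron_roster <- function(cfg) {
  rows <- list()
  ncol_grid <- ceiling(sqrt(cfg$n_neurons_per_mouse))
  for (m in seq_len(cfg$n_mice)) {
    nn <- cfg$n_neurons_per_mouse
    gx <- ((seq_len(nn) - 1L) %% ncol_grid) * cfg$centroid_spacing + 20
    gy <- ((seq_len(nn) - 1L) %/% ncol_grid) * cfg$centroid_spacing + 20
    is_mv <- stats::runif(nn) < cfg$p_movement
    u <- stats::runif(nn)
    is_mg <- u < cfg$p_magazine
    is_rw <- !is_mg & u < cfg$p_magazine + cfg$p_reward
    coder <- is_mv & stats::runif(nn) < cfg$p_length_coder
    rows[[m]] <- tibble::tibble(
      mouse_id = sprintf("m%02d", m),
      neuron_id = sprintf("m%02d_n%02d", m, seq_len(nn)),
      is_movement = is_mv, is_reward = is_rw, is_magazine = is_mg,
      coder = coder,
      x0 = gx + stats::runif(nn, -2, 2),
      y0 = gy + stats::runif(nn, -2, 2))
  }
  dplyr::bind_rows(rows)
}

#' Simulate calcium traces and ROI maps for simulated sessions
#'
#' Builds each neuron's fluorescence trace as a sum of class-appropriate,
#' event-locked responses convolved with a GCaMP6f-like kernel, plus white
#' Gaussian noise: movement neurons fire once per bout at a uniformly
#' jittered time in the pre-press window, with amplitude set by the session
#' forelimb (and, for contralateral length coders, scaled by the bout's
#' length group around the modal 4-press group); reward neurons respond at
#' the first rewarded lick; magazine-approach neurons ramp up linearly over
#' the final approach second and decay after the lick. Because the printed
#' amplitudes refer to the trial-averaged PETH peak, the per-trial
#' movement amplitude is divided by the numerically computed jitter
#' attenuation of the kernel. Centroids are re-jittered per session to
#' exercise cross-day matching.
#'
#' @param cfg a [sim_config()].
#' @param sim output of [simulate_behavior()].
#' @return List: `traces` (named list of [trace_matrix]), `rois` (named
#'   list of centroid tibbles), `truth` (neuron roster with planted
#'   classes), `attenuation` (the jitter-attenuation factor used).
#' @export
simulate_traces <- function(cfg, sim) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1000L)
  roster <- simulate_neuron_roster(cfg)
  att <- movement_attenuation(cfg)
  fs <- cfg$sampling_rate
  kern <- gcamp_kernel(fs, cfg$kernel_rise, cfg$kernel_decay)
  traces <- list(); rois <- list()
  for (sid in names(sim$logs)) {
    log <- sim$logs[[sid]]
    nr <- roster[roster$mouse_id == log$mouse_id, ]
    limb <- limb_from_sides(log$lever_side, log$hemisphere)
    bouts <- sim$bouts[sim$bouts$session_id == sid, ]
    n <- as.integer(round(log$session_duration * fs)) + 1L
    vals <- matrix(0, nrow(nr), n)
    amp_side <- if (identical(limb, "contra")) cfg$amp_move_contra else cfg$amp_move_ipsi
    amp_mag <- if (identical(limb, "contra")) cfg$amp_magazine_contra else cfg$amp_magazine_ipsi
    licks <- log$lick_times
    for (i in seq_len(nrow(nr))) {
      imp <- numeric(n)
      if (nr$is_movement[i] && nrow(bouts)) {
        ranks <- as.integer(assign_length_group(bouts$n_presses))
        for (b in seq_len(nrow(bouts))) {
          ev <- bouts$first_press[b] +
            stats::runif(1, cfg$move_jitter[1], cfg$move_jitter[2])
          amp <- amp_side
          if (nr$coder[i] && identical(limb, "contra"))
            amp <- amp + cfg$length_gain * (ranks[b] - 3L)
          amp <- max(amp, 0.05)
          j <- as.integer(round(ev * fs)) + 1L
          if (j >= 1L && j <= n) imp[j] <- imp[j] + amp / att
        }
      }
      if (nr$is_reward[i] && length(licks)) {
        j <- as.integer(round(licks * fs)) + 1L
        j <- j[j >= 1L & j <= n]
        imp[j] <- imp[j] + cfg$amp_reward
      }
      sig <- if (any(imp != 0)) {
        conv <- stats::convolve(imp, rev(kern), type = "open")
        conv[seq_len(n)]
      } else numeric(n)
      if (nr$is_magazine[i] && length(licks)) {
        ramp_n <- as.integer(round(cfg$magazine_ramp_s * fs))
        decay_n <- as.integer(round(2 * fs))
        for (lk in licks) {
          j0 <- as.integer(round((lk - cfg$magazine_ramp_s) * fs)) + 1L
          jl <- as.integer(round(lk * fs)) + 1L
          up <- seq.int(j0, jl)
          ok <- up >= 1L & up <= n
          sig[up[ok]] <- sig[up[ok]] + amp_mag * (seq_along(up)[ok] - 1L) / ramp_n
          if (jl < n) {
            dn <- seq.int(jl + 1L, min(jl + decay_n, n))
            sig[dn] <- sig[dn] + amp_mag * exp(-(dn - jl) / (cfg$kernel_decay * fs))
          }
        }
      }
      vals[i, ] <- sig + stats::rnorm(n, 0, cfg$noise_sd)
    }
    traces[[sid]] <- trace_matrix(vals, nr$neuron_id, session_id = sid,
                                  sampling_rate = fs)
    rois[[sid]] <- tibble::tibble(
      roi = nr$neuron_id,
      x = nr$x0 + stats::rnorm(nrow(nr), 0, cfg$centroid_jitter),
      y = nr$y0 + stats::rnorm(nrow(nr), 0, cfg$centroid_jitter))
  }
  list(traces = traces, rois = rois, truth = roster, attenuation = att)
}

#' Simulate per-bout peak activities for length-coding analyses
#'
#' Activity-level generator used for the length-coding power and
#' specificity analyses: each neuron's per-bout peak pre-press activity is
#' its side amplitude plus, in the contralateral condition only, the
#' planted per-group length gain (centered on the modal 4-press group),
#' plus Gaussian trial noise.
#'
#' @param cfg a [sim_config()].
#' @param n_neurons number of neurons.
#' @param n_bouts bouts (trials) per neuron.
#' @param condition `"contra"` (planted gain) or `"ipsi"` (no gain).
#' @param null_gain if TRUE the gain is forced to zero (null generator).
#' @param seed optional seed override.
#' @return List: `activity` (neurons x bouts matrix), `n_presses` (bout
#'   lengths), `gain` (planted gain actually used).
#' @export
simulate_length_activity <- function(cfg, n_neurons = 37L, n_bouts = 150L,
                                     condition = c("contra", "ipsi"),
                                     null_gain = FALSE, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)
  lens <- rlength(n_bouts, cfg$length_mean, cfg$length_support)
  ranks <- as.integer(assign_length_group(lens))
  gain <- if (condition == "contra" && !null_gain) cfg$length_gain else 0
  base <- if (condition == "contra") cfg$amp_move_contra else cfg$amp_move_ipsi
  act <- matrix(stats::rnorm(n_neurons * n_bouts, 0, cfg$trial_noise_sd),
                n_neurons, n_bouts, byrow = TRUE)
  act <- act + base + matrix(gain * (ranks - 3L), n_neurons, n_bouts, byrow = TRUE)
  list(activity = act, n_presses = lens, gain = gain)
}

#' Simulate stable event-aligned tuning across sessions
#'
#' Generator for the cross-session stability analysis: each ROI owns a
#' smooth per-event tuning template (white noise convolved with the
#' transient kernel); each session observes the template plus independent
#' smooth noise. Matched correlations are therefore high, time-shuffled
#' ones near zero, and the best non-matched ROI intermediate.
#'
#' @param cfg a [sim_config()] (kernel parameters are reused).
#' @param n_roi ROIs per animal.
#' @param n_sessions sessions (default 3).
#' @param n_bins PETH length in bins (default 160, the (-10, 6) s window).
#' @param session_noise SD of the session-specific smooth noise relative to
#'   the unit-SD template (default 0.5).
#' @param seed optional seed override.
#' @return List over ROIs; each element is a list over sessions of named
#'   4-event mean-PETH lists.
#' @export
simulate_stable_peths <- function(cfg, n_roi = 20L, n_sessions = 3L,
                                  n_bins = 160L, session_noise = 0.5,
                                  seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  kern <- gcamp_kernel(cfg$sampling_rate, cfg$kernel_rise, cfg$kernel_decay)
  smooth_noise <- function() {
    x <- stats::rnorm(n_bins + length(kern))
    y <- stats::convolve(x, rev(kern), type = "open")[seq_len(n_bins) + length(kern)]
    as.numeric(scale(y))
  }
  events <- c("press_contra", "press_ipsi", "lick_contra", "lick_ipsi")
  lapply(seq_len(n_roi), function(r) {
    tmpl <- stats::setNames(lapply(events, function(e) smooth_noise()), events)
    lapply(seq_len(n_sessions), function(s) {
      stats::setNames(lapply(events, function(e)
        tmpl[[e]] + session_noise * smooth_noise()), events)
    })
  })
}
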