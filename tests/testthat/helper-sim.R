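# Small fixtures shared across test files.

small_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_mice = 2L, n_days = 2L, session_duration = 420,
             max_rewards = 10L, n_neurons_per_mouse = 6L, ...)
}

# a synthetic PETH object with a chosen mean and bin grid
make_peth <- function(mean_peth, window = c(-8, 6), bin = 0.1,
                      neuron_id = "n1", condition = "contra") {
  nb <- length(mean_peth)
  structure(list(neuron_id = neuron_id, event_type = "first_press",
                 condition = condition,
                 trial_matrix = matrix(mean_peth, 1, nb, byrow = TRUE),
                 mean_peth = mean_peth,
                 bin_left = window[1] + (seq_len(nb) - 1L) * bin,
                 bin = bin, window = window, n_dropped = 0L, empty = FALSE),
            class = "peth")
}

# 140-bin null PETH with optional planted bump in a window
null_peth <- function(bump_at = NULL, bump = 0, sd = 1) {
  x <- rnorm(140, 0, sd)
  bl <- seq(-8, 5.9, by = 0.1)
  if (!is.null(bump_at)) {
    sel <- bl >= bump_at[1] & bl < bump_at[2]
    x[sel] <- x[sel] + bump
  }
  make_peth(x)
}

simple_log <- function(press_times, occupancy, duration = 60, ...) {
  event_log("s1", lever_side = "left", hemisphere = "right",
            press_times = press_times, occupancy = occupancy,
            session_duration = duration, ...)
}
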