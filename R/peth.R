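#' Build a peri-event time histogram for one neuron
#'
#' Aligns a single neuron's trace on a set of event times and bins it into
#' left-closed, half-open bins `[t0, t0 + bin)` with the event falling on a
#' bin edge. Sample `i` of the trace is taken at time `(i - 1) / fs`.
#' Events whose full window exceeds the recording bounds are dropped and
#' counted in `n_dropped`.
#'
#' @param x numeric trace for one neuron (z-units).
#' @param events event times (s).
#' @param sampling_rate sampling rate (Hz).
#' @param window alignment window in seconds, default `c(-8, 6)`.
#' @param bin bin width in seconds, default 0.1.
#' @param neuron_id,event_type,condition metadata carried on the object.
#' @return Object of class `peth`: `trial_matrix` (trials x bins),
#'   `mean_peth`, `bin_left` (left bin edges relative to the event),
#'   `n_dropped`, plus metadata. With no valid events the trial matrix has
#'   zero rows and `mean_peth` is NA (flagged via `empty = TRUE`).
#' @export
build_peth <- function(x, events, sampling_rate = 10, window = c(-8, 6),
                       bin = 0.1, neuron_id = NA_character_,
                       event_type = NA_character_, condition = NA_character_) {
  stopifnot(length(window) == 2, window[2] > window[1], bin > 0)
  nb <- as.integer(round((window[2] - window[1]) / bin))
  t_last <- (length(x) - 1) / sampling_rate
  ok <- events + window[1] >= -1e-9 & events + window[2] <= t_last + 1e-9
  kept <- events[ok]
  tm <- matrix(NA_real_, length(kept), nb)
  if (length(kept)) {
    for (i in seq_along(kept)) {
      t0 <- kept[i] + window[1]
      i0 <- max(1L, as.integer(ceiling(t0 * sampling_rate + 1 - 1e-6)))
      i1 <- min(length(x),
                as.integer(ceiling((t0 + nb * bin) * sampling_rate - 1e-6)))
      if (i1 < i0) { tm[i, ] <- NA_real_; next }
      idx <- i0:i1
      ts <- (idx - 1) / sampling_rate
      k <- pmin(floor((ts - t0) / bin + 1e-9) + 1L, nb)
      sums <- rowsum(x[idx], k)
      cnt <- tabulate(k, nbins = nb)
      row <- rep(NA_real_, nb)
      row[as.integer(rownames(sums))] <- sums[, 1] / cnt[as.integer(rownames(sums))]
      tm[i, ] <- row
    }
  }
  mean_peth <- if (nrow(tm)) colMeans(tm) else rep(NA_real_, nb)
  structure(list(neuron_id = neuron_id, event_type = event_type,
                 condition = condition,
                 trial_matrix = tm, mean_peth = mean_peth,
                 bin_left = window[1] + (seq_len(nb) - 1L) * bin,
                 bin = bin, window = window,
                 n_dropped = sum(!ok), empty = nrow(tm) == 0L),
            class = "peth")
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("peth %s/%s/%s: %d trials x %d bins [%g, %g] s, %d dropped\n",
              x$neuron_id, x$event_type, x$condition, nrow(x$trial_matrix),
              length(x$mean_peth), x$window[1], x$window[2], x$n_dropped))
  invisible(x)
}

peth_bins_in <- function(p, window) {
  p$bin_left >= window[1] - 1e-9 & p$bin_left < window[2] - 1e-9
}

moving_average3 <- function(x, k = 3L) {
  n <- length(x)
  half <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}

#' Peak activity in a window of a PETH
#'
#' The maximum of a centered 3-bin moving average of the mean PETH,
#' restricted to the bins of `window`. At the ends of the PETH the moving
#' average is truncated to the available bins rather than discarded.
#'
#' @param p a [build_peth()] object, or a numeric mean-PETH vector (then
#'   `bin_left` must be supplied).
#' @param window seconds pair, e.g. `c(-2, 0)` before the aligned event.
#' @param smooth_bins moving-average width (default 3).
#' @param bin_left left bin edges when `p` is a bare vector.
#' @param trial optional trial index: compute on a single trial row of the
#'   trial matrix instead of the trial-averaged PETH.
#' @return Peak activity in z-units.
#' @export
max_activity <- function(p, window, smooth_bins = 3L, bin_left = NULL,
                         trial = NULL) {
  if (inherits(p, "peth")) {
    x <- if (is.null(trial)) p$mean_peth else p$trial_matrix[trial, ]
    bl <- p$bin_left
  } else {
    x <- as.numeric(p)
    bl <- bin_left
    if (is.null(bl)) stop("bin_left required for vector input")
  }
  sel <- bl >= window[1] - 1e-9 & bl < window[2] - 1e-9
  if (sum(sel) < smooth_bins) stop("window spans fewer bins than smooth_bins")
  ma <- moving_average3(x, smooth_bins)
  max(ma[sel])
}
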