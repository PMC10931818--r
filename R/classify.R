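#' Consecutive-bin percentile modulation test
#'
#' Tests whether a PETH is modulated in a window: the threshold is the 99th
#' percentile of the baseline-period bins of the mean PETH (baseline -8 to
#' -3 s by default), and the neuron counts as positively modulated when at
#' least `min_consecutive` consecutive bins of the test window exceed it.
#' Negative modulation is defined symmetrically with the 1st percentile.
#'
#' @param p a [build_peth()] object.
#' @param test_window seconds pair inside the PETH span.
#' @param baseline_window seconds pair, default `c(-8, -3)`.
#' @param min_consecutive minimum run length of supra-threshold bins
#'   (default 2).
#' @param percentile baseline percentile defining the threshold
#'   (default 0.99).
#' @return List: `is_modulated`, `direction` (`"positive"`, `"negative"`,
#'   `"none"`; positive takes precedence), `onset_time` (left edge of the
#'   first qualifying run, NA if none), `threshold_hi`, `threshold_lo`, and
#'   `note` for degenerate baselines.
#' @export
classify_modulation <- function(p, test_window, baseline_window = c(-8, -3),
                                min_consecutive = 2L, percentile = 0.99) {
  stopifnot(inherits(p, "peth"))
  if (p$empty || anyNA(p$mean_peth)) {
    return(list(is_modulated = FALSE, direction = "none", onset_time = NA_real_,
                threshold_hi = NA_real_, threshold_lo = NA_real_,
                note = "empty PETH"))
  }
  x <- p$mean_peth
  bl <- x[peth_bins_in(p, baseline_window)]
  if (!length(bl)) stop("baseline window outside PETH span")
  sel <- which(peth_bins_in(p, test_window))
  if (!length(sel)) stop("test window outside PETH span")
  thr_hi <- stats::quantile(bl, percentile, names = FALSE, type = 7)
  thr_lo <- stats::quantile(bl, 1 - percentile, names = FALSE, type = 7)
  note <- if (stats::sd(bl) < .Machine$double.eps) "degenerate constant baseline" else NULL
  run_start <- function(hits) {
    r <- rle(hits)
    ends <- cumsum(r$lengths)
    i <- which(r$values & r$lengths >= min_consecutive)
    if (!length(i)) return(NA_integer_)
    ends[i[1]] - r$lengths[i[1]] + 1L
  }
  s_pos <- run_start(x[sel] > thr_hi)
  s_neg <- run_start(x[sel] < thr_lo)
  direction <- if (!is.na(s_pos)) "positive" else if (!is.na(s_neg)) "negative" else "none"
  onset <- if (direction == "positive") p$bin_left[sel[s_pos]]
           else if (direction == "negative") p$bin_left[sel[s_neg]]
           else NA_real_
  list(is_modulated = direction != "none", direction = direction,
       onset_time = onset, threshold_hi = thr_hi, threshold_lo = thr_lo,
       note = note)
}

#' Classify one neuron from its press- and lick-aligned PETHs
#'
#' Applies the consecutive-bin percentile rule in the canonical windows:
#' movement-initiation neurons are positively modulated in the 2 s before
#' the first press; execution neurons only after the first press (0 to 1 s
#' by default); reward neurons in the 1 s after the first rewarded lick but
#' not before it; magazine-approach neurons already before the rewarded
#' lick. Flags are reported separately (a neuron can be movement- and
#' magazine-flagged); the single `class` label resolves them with priority
#' movement > execution > reward > magazine.
#'
#' @param p_press press-aligned [build_peth()] object.
#' @param p_lick rewarded-lick-aligned PETH (may be NULL or empty; the
#'   lick-derived flags are then FALSE and noted).
#' @param pre_press_window window before first press, default `c(-2, 0)`.
#' @param execution_window window after first press, default `c(0, 1)`.
#' @param reward_window window after the rewarded lick, default `c(0, 1)`.
#' @param pre_lick_window window before the rewarded lick, default
#'   `c(-2, 0)`.
#' @param ... passed to [classify_modulation()].
#' @return One-row tibble with the flags, resolved `class`, press-response
#'   direction, and peak activities (`max_pre_press`, `max_post_lick`,
#'   `max_pre_lick`).
#' @export
classify_neuron <- function(p_press, p_lick = NULL,
                            pre_press_window = c(-2, 0),
                            execution_window = c(0, 1),
                            reward_window = c(0, 1),
                            pre_lick_window = c(-2, 0), ...) {
  mv <- classify_modulation(p_press, pre_press_window, ...)
  ex <- classify_modulation(p_press, execution_window, ...)
  have_lick <- !is.null(p_lick) && inherits(p_lick, "peth") && !p_lick$empty
  if (have_lick) {
    rw <- classify_modulation(p_lick, reward_window, ...)
    mg <- classify_modulation(p_lick, pre_lick_window, ...)
  } else {
    rw <- mg <- list(direction = "none")
  }
  is_movement <- mv$direction == "positive"
  is_execution <- ex$direction == "positive" && !is_movement
  is_magazine <- mg$direction == "positive"
  is_reward <- rw$direction == "positive" && !is_magazine
  class <- if (is_movement) "movement_initiation"
           else if (is_execution) "execution"
           else if (is_reward) "reward"
           else if (is_magazine) "magazine_approach"
           else "none"
  tibble::tibble(
    neuron_id = p_press$neuron_id,
    condition = p_press$condition,
    is_movement = is_movement, is_execution = is_execution,
    is_reward = is_reward, is_magazine = is_magazine,
    class = class,
    direction_press = mv$direction,
    max_pre_press = if (!p_press$empty) max_activity(p_press, pre_press_window) else NA_real_,
    max_post_lick = if (have_lick) max_activity(p_lick, reward_window) else NA_real_,
    max_pre_lick = if (have_lick) max_activity(p_lick, pre_lick_window) else NA_real_,
    note = if (have_lick) NA_character_ else "no lick PETH")
}
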