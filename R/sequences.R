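#' Group sequence lengths into the standard ordinal bins
#'
#' Sequences of 1 or 2 presses are pooled, lengths 3-6 keep their own group,
#' and 7 or more presses form the top group, yielding six ordered levels.
#'
#' @param n_presses positive integer vector of bout lengths.
#' @return Ordered factor with levels `"<=2", "3", "4", "5", "6", "7+"`.
#' @export
assign_length_group <- function(n_presses) {
  n <- as.integer(n_presses)
  if (any(is.na(n)) || any(n < 1L)) stop("bout lengths must be >= 1")
  lab <- ifelse(n <= 2L, "<=2", ifelse(n >= 7L, "7+", as.character(n)))
  factor(lab, levels = c("<=2", "3", "4", "5", "6", "7+"), ordered = TRUE)
}

#' Target inter-press interval implied by the reward rule
#'
#' An FR-n schedule with a completion window of `window` seconds implies a
#' target mean inter-press interval of `window / (n - 1)`; for the FR4/1-s
#' rule this is 1/3 s.
#'
#' @param n_presses presses required for reward (>= 2).
#' @param window completion window (s).
#' @return Target IPI in seconds.
#' @export
target_ipi <- function(n_presses, window) {
  if (n_presses < 2L) stop("need at least 2 presses")
  if (window <= 0) stop("window must be positive")
  window / (n_presses - 1)
}

#' Does a bout satisfy the fixed-ratio reward rule?
#'
#' TRUE iff some `n_required` consecutive presses within the bout span less
#' than `window` seconds.
#'
#' @param press_times numeric vector of press times within one bout.
#' @param n_required presses required (default 4).
#' @param window completion window in seconds (default 1).
#' @return Logical scalar.
#' @export
reward_eligible <- function(press_times, n_required = 4L, window = 1) {
  if (n_required < 2L) stop("n_required must be >= 2")
  if (window <= 0) stop("window must be positive")
  k <- length(press_times)
  if (k < n_required) return(FALSE)
  idx <- seq_len(k - n_required + 1L)
  any(press_times[idx + n_required - 1L] - press_times[idx] < window)
}

limb_from_sides <- function(lever_side, hemisphere) {
  if (hemisphere == "none") return(NA_character_)
  if (lever_side == hemisphere) "ipsi" else "contra"
}

#' Segment lever presses into sequence bouts
#'
#' A sequence bout is a maximal run of presses performed while the snout
#' occupies the same lever-adjacent ROI interval; an isolated press forms a
#' bout of one. Presses falling in no occupancy interval are excluded as
#' orphans and counted. For logs without occupancy data an inter-press-gap
#' rule is used instead: a gap larger than `gap_threshold` seconds splits
#' bouts.
#'
#' @param log an [event_log].
#' @param gap_threshold fallback bout-splitting gap (s) when the log has no
#'   occupancy intervals (default 2 s); set explicitly to force the gap rule.
#' @param n_required,window reward rule used to flag bouts when the log
#'   carries no reward events.
#' @return A tibble with one row per bout: `session_id`, `mouse_id`,
#'   `day_index`, `limb`, `bout_id`, `n_presses`, `start`, `end`,
#'   `rewarded`, `length_group`, `press_times` (list column) and, when
#'   available, `mean_velocity`. Attributes `n_orphans` and `orphan_times`
#'   record excluded presses.
#' @export
segment_sequences <- function(log, gap_threshold = NULL,
                              n_required = 4L, window = 1) {
  stopifnot(inherits(log, "event_log"))
  pt <- log$press_times
  empty <- tibble::tibble(session_id = character(), mouse_id = character(),
                          day_index = integer(), limb = character(),
                          bout_id = integer(), n_presses = integer(),
                          start = numeric(), end = numeric(),
                          rewarded = logical(),
                          length_group = assign_length_group(integer(0) + 1L)[0],
                          press_times = list())
  if (length(pt) == 0L) {
    attr(empty, "n_orphans") <- 0L
    return(empty)
  }
  use_occ <- nrow(log$occupancy) > 0 && is.null(gap_threshold)
  if (use_occ) {
    starts <- log$occupancy[, 1]
    ends <- log$occupancy[, 2]
    iv <- findInterval(pt, starts)
    inside <- iv >= 1L & pt <= ends[pmax(iv, 1L)]
    grp <- ifelse(inside, iv, NA_integer_)
  } else {
    thr <- if (is.null(gap_threshold)) 2 else gap_threshold
    grp <- cumsum(c(1, as.integer(diff(pt) > thr)))
    inside <- rep(TRUE, length(pt))
  }
  orphans <- pt[!inside]
  keep <- which(inside)
  if (length(keep) == 0L) {
    attr(empty, "n_orphans") <- length(orphans)
    attr(empty, "orphan_times") <- orphans
    return(empty)
  }
  runs <- split(keep, grp[keep])
  runs <- runs[order(vapply(runs, function(i) pt[i[1]], numeric(1)))]
  limb <- limb_from_sides(log$lever_side, log$hemisphere)
  have_rewards <- length(log$reward_times) > 0
  bouts <- lapply(seq_along(runs), function(b) {
    p <- pt[runs[[b]]]
    rewarded <- if (have_rewards) {
      any(log$reward_times >= p[1] & log$reward_times <= p[length(p)] + window)
    } else {
      reward_eligible(p, n_required, window)
    }
    tibble::tibble(session_id = log$session_id, mouse_id = log$mouse_id,
                   day_index = log$day_index, limb = limb,
                   bout_id = b, n_presses = length(p),
                   start = p[1], end = p[length(p)], rewarded = rewarded,
                   length_group = assign_length_group(length(p)),
                   press_times = list(p))
  })
  out <- dplyr::bind_rows(bouts)
  if (!is.null(log$press_velocity)) {
    out$mean_velocity <- vapply(runs, function(i) mean(log$press_velocity[i]),
                                numeric(1))
  }
  attr(out, "n_orphans") <- length(orphans)
  attr(out, "orphan_times") <- orphans
  out
}

#' Session-level behavioral metrics
#'
#' Computes the standard descriptors of sequence performance: press counts
#' and rates, the percentage of presses occurring within multi-press
#' sequences, mean presses per sequence, and the mean and Fano factor
#' (sample variance / mean) of within-bout inter-press intervals. IPIs are
#' computed within bouts only; presses in different bouts contribute none.
#'
#' @param log an [event_log].
#' @param bouts bout table from [segment_sequences()].
#' @return One-row tibble of metrics; `ipi_mean`/`ipi_fano` are NA when no
#'   (or fewer than two) within-bout IPIs exist.
#' @export
behavior_metrics <- function(log, bouts) {
  total <- length(log$press_times)
  dur_min <- log$session_duration / 60
  in_seq <- if (nrow(bouts)) sum(bouts$n_presses[bouts$n_presses >= 2L]) else 0L
  multi <- if (nrow(bouts)) mean(bouts$n_presses >= 2L) * 100 else NA_real_
  ipis <- if (nrow(bouts)) {
    unlist(lapply(bouts$press_times, function(p) if (length(p) > 1) diff(p) else numeric(0)))
  } else numeric(0)
  tibble::tibble(
    session_id = log$session_id,
    total_presses = total,
    presses_per_min = total / dur_min,
    pct_presses_in_sequence = if (total > 0) 100 * in_seq / total else NA_real_,
    pct_bouts_multi_press = multi,
    mean_presses_per_sequence = if (nrow(bouts)) mean(bouts$n_presses) else NA_real_,
    pct_rewarded = if (nrow(bouts)) 100 * mean(bouts$rewarded) else NA_real_,
    ipi_mean = if (length(ipis)) mean(ipis) else NA_real_,
    ipi_fano = if (length(ipis) >= 2) stats::var(ipis) / mean(ipis) else NA_real_,
    mean_press_velocity = if (!is.null(log$press_velocity))
      mean(log$press_velocity) else NA_real_,
    n_orphans = attr(bouts, "n_orphans") %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
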