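#' Long-sequence threshold from baseline bouts
#'
#' A sequence counts as "long" when its press count strictly exceeds the
#' mean baseline (pre-treatment) bout length of the same mouse and
#' forelimb.
#'
#' @param baseline_lengths press counts of the baseline bouts.
#' @return The per-mouse, per-forelimb threshold (baseline mean).
#' @export
long_sequence_threshold <- function(baseline_lengths) {
  if (length(baseline_lengths) == 0) stop("empty baseline")
  mean(baseline_lengths)
}

pct_long <- function(lengths, threshold) 100 * mean(lengths > threshold)

#' Before/after x forelimb lesion statistics
#'
#' Full analysis of the unilateral-depletion design, run separately per
#' treatment group: per-mouse mean presses/sequence and percentage of long
#' sequences in each (epoch x forelimb) cell, a 2x2 repeated-measures ANOVA
#' on each measure with Sidak post hoc per-forelimb contrasts, per-mouse
#' after/before ratios (ratio of that mouse's cell means), a paired t of
#' contralateral vs ipsilateral ratios, and one-sample t tests of each
#' ratio against 1.
#'
#' @param bouts tibble with columns `mouse`, `group` (e.g. `"6OHDA"`,
#'   `"saline"`), `epoch` (`"before"`/`"after"`), `limb`
#'   (`"contra"`/`"ipsi"`) and `n_presses`. Mice missing any of the four
#'   design cells are excluded and recorded.
#' @return Named list (one element per group), each containing `summary`
#'   (per mouse x cell tibble), `ratios`, `anova_length`, `anova_long`
#'   ([rm_anova_2x2] objects), and `tests` (tibble of the ratio tests).
#' @export
lesion_stats <- function(bouts) {
  need <- c("mouse", "group", "epoch", "limb", "n_presses")
  stopifnot(all(need %in% names(bouts)))
  lapply(split(bouts, bouts$group), function(gb) {
    cells <- gb |>
      dplyr::group_by(mouse, epoch, limb) |>
      dplyr::summarise(mean_len = mean(n_presses), n_bouts = dplyr::n(),
                       .groups = "drop")
    full <- names(which(table(cells$mouse) == 4L))
    excluded <- setdiff(unique(gb$mouse), full)
    gb <- gb[gb$mouse %in% full, ]
    cells <- cells[cells$mouse %in% full, ]
    if (length(full) < 2) stop("need at least 2 mice with complete designs")
    thr <- gb |>
      dplyr::filter(epoch == "before") |>
      dplyr::group_by(mouse, limb) |>
      dplyr::summarise(threshold = long_sequence_threshold(n_presses),
                       .groups = "drop")
    gb2 <- dplyr::left_join(gb, thr, by = c("mouse", "limb"))
    longs <- gb2 |>
      dplyr::group_by(mouse, epoch, limb) |>
      dplyr::summarise(pct_long = pct_long(n_presses, threshold[1]),
                       .groups = "drop")
    summary <- dplyr::left_join(cells, longs, by = c("mouse", "epoch", "limb"))
    summary$epoch <- factor(summary$epoch, levels = c("before", "after"))
    an_len <- rm_anova_2x2(summary, value = "mean_len", subject = "mouse",
                           factor_a = "epoch", factor_b = "limb")
    an_long <- rm_anova_2x2(summary, value = "pct_long", subject = "mouse",
                            factor_a = "epoch", factor_b = "limb")
    wide <- summary |>
      dplyr::group_by(mouse, limb) |>
      dplyr::summarise(
        len_ratio = mean_len[epoch == "after"] / mean_len[epoch == "before"],
        long_ratio = {
          b <- pct_long[epoch == "before"]
          if (b > 0) pct_long[epoch == "after"] / b else NA_real_
        },
        .groups = "drop")
    ratio_tests <- function(col, label) {
      rc <- wide[[col]][wide$limb == "contra"]
      ri <- wide[[col]][wide$limb == "ipsi"]
      keep <- stats::complete.cases(rc, ri)
      rc <- rc[keep]; ri <- ri[keep]
      tt_pair <- t_contrast(rc, ri, "paired")
      tt_c <- t_contrast(rc, mode = "one_sample", mu = 1)
      tt_i <- t_contrast(ri, mode = "one_sample", mu = 1)
      tibble::tibble(
        measure = label,
        test = c("contra_vs_ipsi_ratio_paired_t", "contra_ratio_vs_1",
                 "ipsi_ratio_vs_1"),
        statistic = c(tt_pair$statistic, tt_c$statistic, tt_i$statistic),
        df = c(tt_pair$df, tt_c$df, tt_i$df),
        p = c(tt_pair$p_value, tt_c$p_value, tt_i$p_value),
        mean_contra_ratio = mean(rc), mean_ipsi_ratio = mean(ri))
    }
    tests <- dplyr::bind_rows(ratio_tests("len_ratio", "presses_per_sequence"),
                              ratio_tests("long_ratio", "pct_long_sequences"))
    list(summary = summary, ratios = wide, anova_length = an_len,
         anova_long = an_long, tests = tests, excluded_mice = excluded)
  })
}
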