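#' Paired contrast of per-mouse classification percentages
#'
#' Tests whether the percentage of neurons of a class differs between the
#' contralateral and ipsilateral condition, pairing within mouse.
#'
#' @param pct_contra,pct_ipsi per-mouse percentages (equal length >= 2).
#' @return An [snc_test] (paired t).
#' @export
proportion_contrast <- function(pct_contra, pct_ipsi) {
  if (length(pct_contra) != length(pct_ipsi)) stop("per-mouse vectors must align")
  if (length(pct_contra) < 2) stop("need at least 2 mice")
  t_contrast(pct_contra, pct_ipsi, "paired")
}

#' Neuron-level laterality contrast of peak pre-press activity
#'
#' Unpaired pooled-variance t test comparing the peak pre-press activity of
#' movement-initiation neurons recorded in the contralateral vs ipsilateral
#' condition, neurons pooled across mice.
#'
#' @param max_contra,max_ipsi neuron-level peak activities (z-units).
#' @return An [snc_test].
#' @export
amplitude_contrast <- function(max_contra, max_ipsi) {
  if (length(max_contra) < 2 || length(max_ipsi) < 2)
    stop("need at least 2 neurons per condition")
  t_contrast(max_contra, max_ipsi, "unpaired")
}

#' Sequence-length modulation of one neuron
#'
#' Correlates a neuron's per-bout peak pre-press activity with bout length,
#' using the grouped ordinal lengths (<=2, 3, 4, 5, 6, 7+ mapped to ranks
#' 1..6). The neuron is called positively length-modulated when the
#' Spearman correlation is positive and significant (two-sided p < alpha).
#'
#' @param activity per-bout peak activity (z-units).
#' @param n_presses per-bout press counts (same length).
#' @param alpha significance level (default 0.05).
#' @param exact_threshold passed to [spearman_test()].
#' @return One-row tibble: `rho`, `p`, `positively_modulated`,
#'   `classifiable`, `n_bouts`, `n_groups`, plus per-group mean activities
#'   in columns `mean_<=2` ... `mean_7+`.
#' @export
length_modulation <- function(activity, n_presses, alpha = 0.05,
                              exact_threshold = 8L) {
  if (length(activity) != length(n_presses)) stop("inputs must align per bout")
  grp <- assign_length_group(n_presses)
  rk <- as.integer(grp)
  gm <- tapply(activity, grp, mean)
  gm[setdiff(levels(grp), names(gm))] <- NA_real_
  gm <- gm[levels(grp)]
  names(gm) <- paste0("mean_", levels(grp))
  if (length(unique(rk)) < 3L) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_,
                          positively_modulated = FALSE, classifiable = FALSE,
                          n_bouts = length(activity),
                          n_groups = length(unique(rk)), !!!as.list(gm)))
  }
  st <- spearman_test(activity, rk, exact_threshold)
  tibble::tibble(rho = st$statistic, p = st$p_value,
                 positively_modulated = st$statistic > 0 & st$p_value < alpha,
                 classifiable = TRUE, n_bouts = length(activity),
                 n_groups = length(unique(rk)), !!!as.list(gm))
}

#' Linear trend of peak activity across length groups
#'
#' Applies the post hoc linear-trend contrast to the neurons x length-group
#' matrix of mean peak activities.
#'
#' @param group_means matrix, neurons x ordered length groups (NAs allowed
#'   for unvisited groups).
#' @return An [snc_test] (F on 1 numerator df).
#' @export
length_trend <- function(group_means) linear_trend_contrast(group_means)

#' Contra vs ipsi contrast of length-modulated proportions
#'
#' Fisher's exact test on the 2x2 table of length-modulated / not by
#' condition.
#'
#' @param n_mod_contra,n_contra modulated and total neuron counts,
#'   contralateral condition.
#' @param n_mod_ipsi,n_ipsi same for the ipsilateral condition.
#' @return An [snc_test].
#' @export
length_proportion_contrast <- function(n_mod_contra, n_contra,
                                       n_mod_ipsi, n_ipsi) {
  if (n_mod_contra > n_contra || n_mod_ipsi > n_ipsi) stop("inconsistent counts")
  fisher_exact_2x2(matrix(c(n_mod_contra, n_contra - n_mod_contra,
                            n_mod_ipsi, n_ipsi - n_mod_ipsi),
                          nrow = 2, byrow = TRUE))
}

#' Laterality tests for reward- and magazine-approach neurons
#'
#' For each of the two reward-aligned classes runs the pair of tests used
#' for the movement population: a paired t on per-mouse percentages of
#' classified neurons (contra vs ipsi condition) and an unpaired t on
#' neuron-level peak activity (post-reward peak for reward neurons,
#' pre-lick peak for magazine-approach neurons).
#'
#' @param modtable classification table with columns `mouse`, `neuron_id`,
#'   `condition` (`"contra"`/`"ipsi"`), `is_reward`, `is_magazine`,
#'   `max_post_lick`, `max_pre_lick`.
#' @return Tibble with one row per test (`class`, `test`, statistic, df, p,
#'   n_contra, n_ipsi); classes with empty cells are skipped with a note
#'   attribute.
#' @export
reward_laterality <- function(modtable) {
  need <- c("mouse", "neuron_id", "condition", "is_reward", "is_magazine",
            "max_post_lick", "max_pre_lick")
  stopifnot(all(need %in% names(modtable)))
  run_class <- function(flag_col, peak_col, label) {
    mt <- modtable
    mt$flag <- mt[[flag_col]]
    mt$peak <- mt[[peak_col]]
    pm <- mt |>
      dplyr::group_by(mouse, condition) |>
      dplyr::summarise(pct = 100 * mean(flag), .groups = "drop") |>
      tidyr_pivot(names_from = "condition", values_from = "pct")
    rows <- list()
    if (all(c("contra", "ipsi") %in% names(pm)) && nrow(pm) >= 2 &&
        !anyNA(pm$contra) && !anyNA(pm$ipsi)) {
      tt <- proportion_contrast(pm$contra, pm$ipsi)
      rows$prop <- tibble::tibble(class = label, test = "pct_per_mouse_paired_t",
                                  statistic = tt$statistic, df = tt$df,
                                  p = tt$p_value,
                                  mean_contra = mean(pm$contra),
                                  mean_ipsi = mean(pm$ipsi))
    }
    pc <- mt$peak[mt$flag & mt$condition == "contra"]
    pi <- mt$peak[mt$flag & mt$condition == "ipsi"]
    if (length(pc) >= 2 && length(pi) >= 2) {
      tt <- amplitude_contrast(pc, pi)
      rows$amp <- tibble::tibble(class = label, test = "peak_unpaired_t",
                                 statistic = tt$statistic, df = tt$df,
                                 p = tt$p_value,
                                 mean_contra = mean(pc), mean_ipsi = mean(pi))
    }
    dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(run_class("is_reward", "max_post_lick", "reward"),
                          run_class("is_magazine", "max_pre_lick", "magazine_approach"))
  if (nrow(out) < 4) attr(out, "note") <- "some classes skipped (empty cells)"
  out
}

# minimal long->wide pivot to avoid a tidyr dependency
tidyr_pivot <- function(df, names_from, values_from) {
  wide <- stats::reshape(as.data.frame(df), idvar = setdiff(names(df), c(names_from, values_from)),
                         timevar = names_from, direction = "wide")
  names(wide) <- sub(paste0("^", values_from, "\\."), "", names(wide))
  tibble::as_tibble(wide)
}

#' Overlap of movement- and reward-modulated populations
#'
#' Given per-neuron movement and reward flags (same neurons), reports the
#' observed overlap, the overlap expected under independent allocation, and
#' the hypergeometric two-sided p from [overlap_chance_test()].
#'
#' @param is_movement,is_reward logical vectors over the same neurons.
#' @param ... passed to [overlap_chance_test()].
#' @return An [snc_test] with fields `expected` and `n`.
#' @export
overlap_analysis <- function(is_movement, is_reward, ...) {
  if (length(is_movement) != length(is_reward)) stop("flag vectors must align")
  overlap_chance_test(sum(is_movement), sum(is_reward),
                      sum(is_movement & is_reward), length(is_movement), ...)
}
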