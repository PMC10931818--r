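#' Cross-day functional correlation of two ROIs
#'
#' Each ROI contributes up to four event-aligned mean PETHs (first press and
#' rewarded lick, each in the contralateral and ipsilateral condition),
#' built on the wider (-10, +6) s correlation window. The Spearman
#' correlation is computed per shared event and the maximum over events is
#' returned.
#'
#' @param peths_a,peths_b named lists of numeric mean-PETH vectors (names
#'   identify the event-condition, e.g. `"press_contra"`).
#' @return The maximum Spearman correlation across shared events.
#' @export
crossday_peth_correlation <- function(peths_a, peths_b) {
  shared <- intersect(names(peths_a), names(peths_b))
  if (!length(shared)) stop("no shared event PETHs")
  rs <- vapply(shared, function(e) {
    x <- peths_a[[e]]; y <- peths_b[[e]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }, numeric(1))
  rs <- rs[!is.na(rs)]
  if (!length(rs)) stop("all shared PETHs degenerate")
  max(rs)
}

#' Matched-ROI correlation averaged across session pairs
#'
#' For a track matched across `k` sessions, computes the maximum-event
#' cross-day correlation for every session pair and averages the pairwise
#' values through the Fisher Z transform.
#'
#' @param peths_by_session list (one element per session) of named
#'   mean-PETH lists as in [crossday_peth_correlation()].
#' @return Z-averaged correlation.
#' @export
matched_correlation <- function(peths_by_session) {
  k <- length(peths_by_session)
  if (k < 2) stop("need at least 2 sessions")
  prs <- utils::combn(k, 2)
  vals <- apply(prs, 2, function(ij)
    crossday_peth_correlation(peths_by_session[[ij[1]]], peths_by_session[[ij[2]]]))
  fisher_z_mean(vals)
}

circular_shift <- function(x, offset) {
  n <- length(x)
  offset <- ((offset - 1L) %% n) + 1L
  x[c((offset + 1L):n, 1L:offset)]
}

#' Control correlations for cross-session stability
#'
#' Two controls accompany the matched-ROI correlation. `"shuffled"`
#' correlates the reference ROI with a time-shuffled version of its own
#' matched PETHs (random circular rotation of bins, offset at least
#' `min_shift_s`, preserving autocorrelation). `"different"` takes, for
#' each session pair, the maximum cross-day correlation over all
#' non-matched ROIs of the same animal. Both are Fisher-Z averaged across
#' session pairs.
#'
#' @param ref_by_session reference ROI: list per session of named mean-PETH
#'   lists.
#' @param others_by_session for `"different"`: list over other ROIs, each a
#'   list per session of named mean-PETH lists.
#' @param mode `"shuffled"` or `"different"`.
#' @param seed RNG seed for the shuffle offsets.
#' @param min_shift_s minimum rotation in seconds (default 1).
#' @param bin bin width in seconds (default 0.1).
#' @return Z-averaged control correlation.
#' @export
control_correlations <- function(ref_by_session, others_by_session = NULL,
                                 mode = c("shuffled", "different"),
                                 seed = NULL, min_shift_s = 1, bin = 0.1) {
  mode <- match.arg(mode)
  k <- length(ref_by_session)
  if (k < 2) stop("need at least 2 sessions")
  prs <- utils::combn(k, 2)
  if (mode == "shuffled") {
    if (!is.null(seed)) set.seed(seed)
    min_bins <- max(1L, as.integer(ceiling(min_shift_s / bin)))
    vals <- apply(prs, 2, function(ij) {
      b <- ref_by_session[[ij[2]]]
      nb <- length(b[[1]])
      off <- sample(seq.int(min_bins, nb - min_bins), 1L)
      b_sh <- lapply(b, circular_shift, offset = off)
      crossday_peth_correlation(ref_by_session[[ij[1]]], b_sh)
    })
  } else {
    if (is.null(others_by_session) || length(others_by_session) < 1)
      stop("different-mode requires at least one other ROI")
    vals <- apply(prs, 2, function(ij) {
      max(vapply(others_by_session, function(o)
        crossday_peth_correlation(ref_by_session[[ij[1]]], o[[ij[2]]]),
        numeric(1)))
    })
  }
  fisher_z_mean(vals)
}

#' Summarize functional stability across sessions
#'
#' Takes one correlation per ROI and control group (`matched`, `shuffled`,
#' `different`), Fisher-Z transforms the values, and runs a repeated
#' measures one-way ANOVA across groups with Tukey post hoc comparisons on
#' the within-ROI error term. Also reports the Z-averaged group means and
#' the fraction of matched ROIs with correlation above 0.5.
#'
#' @param records tibble with columns `roi`, `group`, `value`.
#' @param strong_cut threshold for a "strong" matched correlation
#'   (default 0.5).
#' @return List: `group_means` (named, Fisher-Z averaged), `anova` tibble,
#'   `tukey` tibble, `pct_matched_strong`, `n_roi`, `n_dropped`.
#' @export
stability_summary <- function(records, strong_cut = 0.5) {
  stopifnot(all(c("roi", "group", "value") %in% names(records)))
  groups <- c("matched", "shuffled", "different")
  records <- records[records$group %in% groups, ]
  complete <- names(which(tapply(records$group, records$roi,
                                 function(g) length(unique(g)) == 3L)))
  n_dropped <- length(unique(records$roi)) - length(complete)
  records <- records[records$roi %in% complete, ]
  if (length(complete) < 2) stop("need at least 2 ROIs with all three groups")
  z <- atanh(pmin(pmax(records$value, -1 + 1e-6), 1 - 1e-6))
  g <- factor(records$group, levels = groups)
  roi <- factor(records$roi)
  fit <- stats::aov(z ~ g + Error(roi))
  s <- summary(fit)
  within <- s[["Error: Within"]][[1]]
  Fv <- within["g", "F value"]
  p <- within["g", "Pr(>F)"]
  df1 <- within["g", "Df"]
  df2 <- within["Residuals", "Df"]
  mse <- within["Residuals", "Mean Sq"]
  n <- length(complete)
  mz <- tapply(z, g, mean)
  pairs <- utils::combn(groups, 2)
  tukey <- apply(pairs, 2, function(pr) {
    q <- abs(mz[pr[1]] - mz[pr[2]]) / sqrt(mse / n)
    tibble::tibble(contrast = paste(pr, collapse = " vs "),
                   diff_z = unname(mz[pr[1]] - mz[pr[2]]),
                   p = stats::ptukey(q, nmeans = 3, df = df2, lower.tail = FALSE))
  })
  gm <- vapply(groups, function(gr)
    fisher_z_mean(records$value[records$group == gr]), numeric(1))
  matched_vals <- records$value[records$group == "matched"]
  list(group_means = gm,
       anova = tibble::tibble(factor = "group", F = Fv, df_num = df1,
                              df_den = df2, p = p),
       tukey = dplyr::bind_rows(tukey),
       pct_matched_strong = 100 * mean(matched_vals > strong_cut),
       n_roi = n, n_dropped = n_dropped)
}
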