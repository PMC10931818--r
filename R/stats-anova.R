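#' Two-way (2 x 2) repeated-measures ANOVA
#'
#' Fully within-subject two-factor ANOVA for the before/after x
#' contralateral/ipsilateral design. For a 2 x 2 within design each F test
#' equals the squared paired t of the corresponding subject-level contrast,
#' which is how the decomposition is computed here (the sums-of-squares
#' route is used as an independent oracle in the test suite). Companion
#' post hoc paired contrasts across the first factor are run within each
#' level of the second factor with a Sidak correction.
#'
#' @param data data frame with columns `subject`, and the two factor columns
#'   plus a `value` column (names configurable).
#' @param value,subject,factor_a,factor_b column names; `factor_a` is the
#'   "time" (before/after) factor, `factor_b` the forelimb factor.
#' @return A list of class `snc_anova` with elements `anova` (tibble of
#'   factor, F, df_num, df_den, p), `posthoc` (tibble of per-level paired
#'   contrasts with raw and Sidak-adjusted p) and `n_subjects`.
#' @export
rm_anova_2x2 <- function(data, value = "value", subject = "subject",
                         factor_a = "time", factor_b = "limb") {
  need <- c(value, subject, factor_a, factor_b)
  if (!all(need %in% names(data))) stop("missing columns: ",
                                        paste(setdiff(need, names(data)), collapse = ", "))
  a_lev <- if (is.factor(data[[factor_a]])) levels(droplevels(data[[factor_a]]))
           else unique(as.character(data[[factor_a]]))
  b_lev <- if (is.factor(data[[factor_b]])) levels(droplevels(data[[factor_b]]))
           else unique(as.character(data[[factor_b]]))
  if (length(a_lev) != 2L || length(b_lev) != 2L)
    stop("both factors must have exactly 2 levels")
  subj <- unique(as.character(data[[subject]]))
  n <- length(subj)
  if (n < 2L) stop("need at least 2 subjects")
  # cell matrix: rows subjects, columns (a1b1, a1b2, a2b1, a2b2)
  cell <- function(a, b) {
    v <- vapply(subj, function(s) {
      sel <- data[[subject]] == s & data[[factor_a]] == a & data[[factor_b]] == b
      if (!any(sel)) return(NA_real_)
      mean(data[[value]][sel])
    }, numeric(1))
    v
  }
  y11 <- cell(a_lev[1], b_lev[1]); y12 <- cell(a_lev[1], b_lev[2])
  y21 <- cell(a_lev[2], b_lev[1]); y22 <- cell(a_lev[2], b_lev[2])
  if (anyNA(c(y11, y12, y21, y22))) stop("missing design cell for some subject")
  contrast_F <- function(d) {
    v <- stats::var(d)
    if (v < .Machine$double.eps) {
      if (abs(mean(d)) > .Machine$double.eps^0.5)
        return(list(F = 1e12, p = 0))
      return(list(F = 0, p = 1))
    }
    tt <- mean(d) / sqrt(v / n)
    list(F = tt^2, p = 2 * stats::pt(-abs(tt), df = n - 1))
  }
  fa <- contrast_F((y21 + y22 - y11 - y12) / 2)
  fb <- contrast_F((y12 + y22 - y11 - y21) / 2)
  fi <- contrast_F((y21 - y11) - (y22 - y12))
  anova <- tibble::tibble(
    factor = c(factor_a, factor_b, paste0(factor_a, "_x_", factor_b)),
    F = c(fa$F, fb$F, fi$F),
    df_num = 1,
    df_den = n - 1,
    p = c(fa$p, fb$p, fi$p))
  # post hoc: paired contrast across factor_a within each forelimb, Sidak m = 2
  ph <- lapply(b_lev, function(b) {
    pre <- get(paste0("y", 1, match(b, b_lev)))
    post <- get(paste0("y", 2, match(b, b_lev)))
    tt <- t_contrast(post, pre, "paired")
    tibble::tibble(level = b,
                   mean_1 = mean(pre), mean_2 = mean(post),
                   t = tt$statistic, df = tt$df, p = tt$p_value,
                   p_sidak = sidak_adjust(tt$p_value, 2L))
  })
  out <- list(anova = anova, posthoc = dplyr::bind_rows(ph), n_subjects = n,
              levels_a = a_lev, levels_b = b_lev)
  class(out) <- "snc_anova"
  out
}

#' @export
print.snc_anova <- function(x, ...) {
  cat(sprintf("2x2 repeated-measures ANOVA (n = %d subjects)\n", x$n_subjects))
  print(as.data.frame(x$anova))
  cat("post hoc (Sidak-adjusted paired contrasts):\n")
  print(as.data.frame(x$posthoc))
  invisible(x)
}

#' Sidak correction for m independent comparisons
#'
#' @param p raw p-value(s).
#' @param m number of comparisons in the family.
#' @return Adjusted p-value(s) `1 - (1 - p)^m`, capped at 1.
#' @export
sidak_adjust <- function(p, m) pmin(1, 1 - (1 - p)^m)

#' Post hoc test for linear trend across ordered groups
#'
#' After a one-way ANOVA across ordered groups (columns), tests the linear
#' contrast with equally spaced coefficients:
#' `F = (sum(c_g * m_g))^2 / (MSE * sum(c_g^2 / n_g))` on (1, N - k) df,
#' where `m_g`, `n_g` are per-group means and counts and MSE is the pooled
#' within-group mean square. Missing cells are allowed (unbalanced groups).
#'
#' @param m numeric matrix, units x ordered groups (NAs allowed).
#' @return An [snc_test] with `statistic` = F, `df = c(1, N - k)` and a
#'   `slope` field giving the sign of the fitted trend.
#' @export
linear_trend_contrast <- function(m) {
  m <- as.matrix(m)
  k <- ncol(m)
  if (k < 3L) stop("need at least 3 ordered groups")
  ng <- colSums(!is.na(m))
  if (any(ng == 0)) stop("every group needs at least one observation")
  mg <- colMeans(m, na.rm = TRUE)
  N <- sum(ng)
  if (N - k < 1L) stop("no residual degrees of freedom")
  sse <- sum(vapply(seq_len(k), function(g) {
    x <- m[!is.na(m[, g]), g]
    sum((x - mg[g])^2)
  }, numeric(1)))
  mse <- sse / (N - k)
  cc <- seq_len(k) - (k + 1) / 2
  est <- sum(cc * mg)
  if (mse < .Machine$double.eps) {
    Fv <- if (abs(est) < 1e-12) 0 else Inf
    p <- if (Fv == 0) 1 else 0
    Fv <- min(Fv, 1e12)
  } else {
    Fv <- est^2 / (mse * sum(cc^2 / ng))
    p <- stats::pf(Fv, 1, N - k, lower.tail = FALSE)
  }
  dir <- if (est > 0) "positive" else if (est < 0) "negative" else "none"
  snc_test(Fv, p, df = c(1, N - k), effect_direction = dir,
           method = "linear_trend", slope = sign(est))
}
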