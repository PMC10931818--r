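#' Test result container
#'
#' Lightweight container for a single hypothesis-test outcome, used by every
#' statistical routine in the package. Results serialize cleanly to a
#' one-row data frame via [as.data.frame()].
#'
#' @param statistic test statistic (finite).
#' @param p_value two-sided p-value in \[0, 1\].
#' @param df degrees of freedom; a single number or a length-2 vector
#'   (numerator, denominator).
#' @param effect_direction one of `"positive"`, `"negative"`, `"none"`.
#' @param method short label of the test performed.
#' @param note optional character flag (e.g. `"zero variance"`).
#' @param ... extra named fields stored alongside (e.g. `n`, `expected`).
#' @return An object of class `snc_test`.
#' @export
snc_test <- function(statistic, p_value, df = NA_real_,
                     effect_direction = c("none", "positive", "negative"),
                     method = "", note = NULL, ...) {
  effect_direction <- match.arg(effect_direction)
  stopifnot(is.finite(statistic), p_value >= 0, p_value <= 1 + 1e-12)
  out <- list(statistic = unname(statistic),
              p_value = min(unname(p_value), 1),
              df = unname(df),
              effect_direction = effect_direction,
              method = method, note = note, ...)
  class(out) <- "snc_test"
  out
}

#' @export
print.snc_test <- function(x, ...) {
  df <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g (%s)\n",
              x$method, x$statistic, df, x$p_value, x$effect_direction))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
as.data.frame.snc_test <- function(x, ...) {
  data.frame(test = x$method, statistic = x$statistic,
             df = paste(signif(x$df, 6), collapse = "/"),
             p = x$p_value, direction = x$effect_direction,
             stringsAsFactors = FALSE)
}

# All permutations of 1:n as an (n! x n) integer matrix.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, n * m, n)
  for (i in seq_len(n)) {
    blk <- sub
    blk[blk >= i] <- blk[blk >= i] + 1L
    out[(i - 1L) * m + seq_len(m), 1L] <- i
    out[(i - 1L) * m + seq_len(m), -1L] <- blk
  }
  out
}

#' Spearman rank correlation with exact permutation p-value
#'
#' Rank correlation with mid-ranks for ties. For small samples
#' (`n <= exact_threshold`) the two-sided p-value is obtained by full
#' enumeration of all `n!` permutations of one rank vector; above the
#' threshold, the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' `n - 2` df is used (tie-corrected through the mid-rank rho itself).
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param exact_threshold largest n for which the permutation null is fully
#'   enumerated (default 8; 8! = 40320 permutations).
#' @return An [snc_test] with `statistic` = rho and fields `n`, `exact`.
#' @export
spearman_test <- function(x, y, exact_threshold = 8L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(snc_test(0, 1, df = n - 2, method = "spearman",
                    note = "degenerate (all tied)", n = n, exact = FALSE))
  }
  rho <- stats::cor(rx, ry)
  exact <- n <= exact_threshold
  if (exact) {
    a <- rx - mean(rx)
    b <- ry - mean(ry)
    denom <- sqrt(sum(a^2) * sum(b^2))
    P <- all_permutations(n)
    # rho under each permutation of the y ranks
    rho_perm <- as.vector(matrix(b[P], nrow = nrow(P)) %*% a) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    r2 <- min(rho^2, 1 - 1e-12)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  dir <- if (rho > 0) "positive" else if (rho < 0) "negative" else "none"
  snc_test(rho, p, df = n - 2, effect_direction = dir,
           method = "spearman", n = n, exact = exact)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value obtained by summing hypergeometric probabilities of all
#' tables (with the observed margins) as or less probable than the observed
#' one, i.e. the classical Fisher rule as implemented by
#' [stats::fisher.test()].
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return An [snc_test]; `statistic` is the observed top-left cell count
#'   (the hypergeometric statistic).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2")
  if (any(tab < 0)) stop("negative cell count")
  if (sum(tab) == 0) stop("empty table")
  ft <- stats::fisher.test(tab)
  orhat <- (tab[1, 1] * tab[2, 2]) / max(tab[1, 2] * tab[2, 1], .Machine$double.eps)
  dir <- if (any(tab == 0) && (tab[1, 2] + tab[2, 1] == 0 || tab[1, 1] + tab[2, 2] == 0)) {
    if (tab[1, 1] + tab[2, 2] > 0) "positive" else "negative"
  } else if (orhat > 1) "positive" else if (orhat < 1) "negative" else "none"
  snc_test(tab[1, 1], ft$p.value, df = NA_real_, effect_direction = dir,
           method = "fisher_exact")
}

#' Student t tests (pooled-variance, paired, one-sample)
#'
#' Classical t tests with pooled variance for the unpaired mode (no Welch
#' correction) and sample (n-1) variance throughout. Degenerate inputs with
#' zero variance and no mean difference return statistic 0 and p = 1,
#' flagged in `note`.
#'
#' @param a numeric vector.
#' @param b numeric vector (ignored for `one_sample`).
#' @param mode `"unpaired"`, `"paired"` or `"one_sample"`.
#' @param mu null value for the one-sample mode.
#' @return An [snc_test] with the t statistic and two-sided p.
#' @export
t_contrast <- function(a, b = NULL, mode = c("unpaired", "paired", "one_sample"),
                       mu = 0) {
  mode <- match.arg(mode)
  a <- as.numeric(a)
  if (mode != "one_sample") {
    b <- as.numeric(b)
    if (mode == "paired" && length(a) != length(b))
      stop("paired mode requires equal lengths")
  }
  n_ok <- switch(mode,
                 unpaired = length(a) >= 2 && length(b) >= 2,
                 paired = length(a) >= 2,
                 one_sample = length(a) >= 2)
  if (!n_ok) stop("need at least 2 observations per group")
  res <- tryCatch(
    switch(mode,
           unpaired = stats::t.test(a, b, var.equal = TRUE),
           paired = stats::t.test(a, b, paired = TRUE),
           one_sample = stats::t.test(a, mu = mu)),
    error = function(e) NULL)
  if (!is.null(res) && !is.finite(unname(res$statistic))) res <- NULL
  if (is.null(res)) {
    # zero-variance input: t.test refuses essentially-constant data
    eff <- switch(mode,
                  unpaired = mean(a) - mean(b),
                  paired = mean(a - b),
                  one_sample = mean(a) - mu)
    if (abs(eff) < .Machine$double.eps^0.5) {
      return(snc_test(0, 1, df = NA_real_, method = paste0("t_", mode),
                      note = "zero variance, identical means"))
    }
    return(snc_test(sign(eff) * 1e12, 0, df = NA_real_,
                    effect_direction = if (eff > 0) "positive" else "negative",
                    method = paste0("t_", mode), note = "zero variance"))
  }
  stat <- unname(res$statistic)
  dir <- if (stat > 0) "positive" else if (stat < 0) "negative" else "none"
  snc_test(stat, res$p.value, df = unname(res$parameter),
           effect_direction = dir, method = paste0("t_", mode))
}

#' Average correlations through Fisher's Z transform
#'
#' Maps correlations through `atanh`, averages, and back-transforms with
#' `tanh`. Inputs at exactly +/-1 are clipped to +/-(1 - 1e-6) with a warning.
#'
#' @param r numeric vector of correlation coefficients in \[-1, 1\].
#' @return The back-transformed mean correlation, in (-1, 1).
#' @export
fisher_z_mean <- function(r) {
  if (length(r) == 0) stop("empty correlation vector")
  r <- r[!is.na(r)]
  if (length(r) == 0) stop("all correlations missing")
  if (any(abs(r) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  clip <- abs(r) >= 1 - 1e-12
  if (any(clip)) {
    warning("correlations at +/-1 clipped before z-averaging")
    r[clip] <- sign(r[clip]) * (1 - 1e-6)
  }
  tanh(mean(atanh(r)))
}

#' Population-overlap test against independent allocation
#'
#' Given two classified subsets of the same neuron population, tests whether
#' the observed overlap is compatible with independent label assignment.
#' Under independence the overlap count follows a hypergeometric
#' distribution; the two-sided p sums all overlap counts whose probability
#' does not exceed that of the observed count. A label-permutation Monte
#' Carlo variant is available as a cross-check.
#'
#' @param n_a,n_b sizes of the two subsets.
#' @param n_both observed overlap.
#' @param n_total population size.
#' @param method `"hypergeometric"` (exact) or `"permutation"`.
#' @param n_perm,seed Monte Carlo settings for the permutation method.
#' @return An [snc_test] with `statistic` = observed overlap and field
#'   `expected` = `n_a * n_b / n_total`.
#' @export
overlap_chance_test <- function(n_a, n_b, n_both, n_total,
                                method = c("hypergeometric", "permutation"),
                                n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  if (n_both > min(n_a, n_b) || max(n_a, n_b) > n_total ||
      n_both < max(0L, n_a + n_b - n_total) || any(c(n_a, n_b, n_both, n_total) < 0))
    stop("inconsistent overlap counts")
  expected <- n_a * n_b / max(n_total, 1L)
  lo <- max(0L, n_a + n_b - n_total)
  hi <- min(n_a, n_b)
  if (method == "hypergeometric") {
    supp <- lo:hi
    d <- stats::dhyper(supp, n_a, n_total - n_a, n_b)
    p <- sum(d[d <= stats::dhyper(n_both, n_a, n_total - n_a, n_b) * (1 + 1e-7)])
  } else {
    if (!is.null(seed)) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
    }
    sim <- vapply(seq_len(n_perm), function(i) {
      length(intersect(sample.int(n_total, n_a), sample.int(n_total, n_b)))
    }, integer(1))
    # probability-ordering two-sided p, estimated from the empirical null
    freq <- tabulate(sim + 1L, nbins = hi + 1L)
    p <- sum(freq[freq <= freq[n_both + 1L]]) / n_perm
  }
  dir <- if (n_both > expected) "positive" else if (n_both < expected) "negative" else "none"
  snc_test(n_both, min(p, 1), df = NA_real_, effect_direction = dir,
           method = "overlap_chance", expected = expected, n = n_total)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
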