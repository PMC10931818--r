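# Independent brute-force oracles used to cross-check the package's
# statistical primitives. These deliberately take different code paths
# from the implementations.

# all distinct permutations of 1:n via filtered grid expansion (n <= 5/6)
oracle_perms <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  g[apply(g, 1, function(z) length(unique(z)) == n), , drop = FALSE]
}

oracle_spearman_p <- function(x, y) {
  P <- oracle_perms(length(x))
  rho <- stats::cor(rank(x), rank(y))
  rp <- apply(P, 1, function(pm) stats::cor(rank(x), rank(y[pm])))
  mean(abs(rp) >= abs(rho) - 1e-12)
}

# Fisher two-sided p by explicit table enumeration with binomial coefficients
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  sum(pr[pr <= pr[ks == tab[1, 1]] * (1 + 1e-7)])
}

# RM-ANOVA F statistics through base aov() with an Error() stratum
oracle_rm_anova_F <- function(df) {
  fit <- stats::aov(value ~ time * limb + Error(subject / (time * limb)),
                    data = df)
  s <- summary(fit)
  c(time = s[["Error: subject:time"]][[1]]["time", "F value"],
    limb = s[["Error: subject:limb"]][[1]]["limb", "F value"],
    interaction = s[["Error: subject:time:limb"]][[1]]["time:limb", "F value"])
}

# linear-trend F via orthogonal-polynomial contrast split of a one-way aov
oracle_trend_F <- function(m) {
  k <- ncol(m); nu <- nrow(m)
  y <- as.vector(m)
  g <- factor(rep(seq_len(k), each = nu))
  stats::contrasts(g) <- stats::contr.poly(k)
  a <- stats::aov(y ~ g)
  s <- summary(a, split = list(g = list(linear = 1)))[[1]]
  unname(s[grep("linear", rownames(s)), "F value"])
}

# manual type-7 percentile (same definition, independent code)
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, length(x))] - xs[lo])
}

# vectorized re-implementation of the consecutive-bin percentile rule
oracle_modulation_rate <- function(X, n_baseline = 50L, test_cols,
                                   percentile = 0.99, min_consecutive = 2L) {
  hits <- vapply(seq_len(nrow(X)), function(i) {
    thr <- oracle_quantile7(X[i, seq_len(n_baseline)], percentile)
    a <- X[i, test_cols] > thr
    any(a[-length(a)] & a[-1])
  }, logical(1))
  mean(hits)
}
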