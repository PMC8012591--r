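## Rank-based two-sample and paired tests.  Exact null distributions are
## computed by dynamic programming over doubled midranks (doubling keeps the
## grid integral in the presence of ties), which reproduces full enumeration
## of group relabellings / sign flips at a cost polynomial in n.

## distribution of the doubled-rank-sum of a size-k subset of `dr` (integers):
## returns counts over sums 0..sum(dr)
.subset_sum_counts <- function(dr, k) {
  total <- sum(dr)
  f <- matrix(0, nrow = k + 1L, ncol = total + 1L)
  f[1L, 1L] <- 1
  for (r in dr) {
    kk <- min(k, nrow(f) - 1L)
    for (j in seq.int(kk, 1L)) {
      src <- f[j, ]
      if (any(src > 0)) {
        shifted <- c(rep(0, r), src[seq_len(total + 1L - r)])
        f[j + 1L, ] <- f[j + 1L, ] + shifted
      }
    }
  }
  f[k + 1L, ]
}

#' Mann-Whitney U-test with AUC
#'
#' Two-sided Mann-Whitney U-test between two groups of a continuous marker.
#' `U` counts pairs where a case exceeds a control, plus half-ties, so
#' `AUC = U / (n1 * n2)` is the probability-of-superiority estimate reused by
#' the ROC module.  The p-value is exact (full enumeration of group
#' relabellings, computed by dynamic programming and valid under ties) when
#' `n1 * n2 <= exact_limit`, otherwise a tie-corrected normal approximation.
#' When every pooled value is tied the test is degenerate: `p = 1`,
#' `AUC = 0.5`.
#'
#' @param cases,controls numeric vectors, each of length >= 1.
#' @param exact_limit use the exact distribution when `n1 * n2` does not
#'   exceed this.
#' @return list with `U`, `p`, `auc`, `n1`, `n2`, `exact`.
#' @export
mannWhitney <- function(cases, controls, exact_limit = 400L) {
  a <- cases[!is.na(cases)]; b <- controls[!is.na(controls)]
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 1L, n2 >= 1L)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n2)
  mu <- n1 * n2 / 2
  if (length(unique(pooled)) == 1L)
    return(list(U = U, p = 1, auc = 0.5, n1 = n1, n2 = n2, exact = FALSE))
  if (n1 * n2 <= exact_limit) {
    dr <- as.integer(round(2 * r))
    counts <- .subset_sum_counts(dr, n1)
    ## doubled rank-sum -> U on the doubled scale
    du <- seq_along(counts) - 1 - n1 * (n1 + 1)   # 2 * U values
    keep <- counts > 0
    dev <- abs(du[keep] - 2 * mu)
    p <- sum(counts[keep][dev >= abs(2 * U - 2 * mu) - 1e-9]) /
      sum(counts[keep])
    exact <- TRUE
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    exact <- FALSE
  }
  list(U = U, p = min(1, p), auc = auc, n1 = n1, n2 = n2, exact = exact)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided Wilcoxon signed-rank test on paired differences
#' `post - pre`.  Zero differences are dropped (the Wilcoxon convention) and
#' their count returned.  The p-value is exact — full enumeration of the
#' `2^n` sign flips, computed by dynamic programming over doubled midranks —
#' for up to `exact_limit` informative pairs, otherwise a tie-corrected
#' normal approximation with `Var(W) = sum(r_i^2) / 4`.  With no informative
#' pairs, `p = 1`.
#'
#' @param pre,post equal-length numeric vectors paired by subject.
#' @param exact_limit exact enumeration bound on informative pairs.
#' @return list with `W` (sum of ranks of positive differences), `p`,
#'   `n_used`, `n_zero`, `exact`.
#' @export
wilcoxonSignedRank <- function(pre, post, exact_limit = 25L) {
  stopifnot(length(pre) == length(post))
  d <- post - pre
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(W = 0, p = 1, n_used = 0L, n_zero = n_zero, exact = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= exact_limit) {
    dr <- as.integer(round(2 * r))
    total <- sum(dr)
    ## distribution of doubled W over all sign flips
    f <- numeric(total + 1L); f[1L] <- 1
    for (rr in dr)
      f <- f + c(rep(0, rr), f[seq_len(total + 1L - rr)])
    dw <- seq_along(f) - 1
    keep <- f > 0
    dev <- abs(dw[keep] - 2 * mu)
    p <- sum(f[keep][dev >= abs(2 * W - 2 * mu) - 1e-9]) / sum(f[keep])
    exact <- TRUE
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- (W - mu) / sigma
    p <- 2 * pnorm(-abs(z))
    exact <- FALSE
  }
  list(W = W, p = min(1, p), n_used = n, n_zero = n_zero, exact = exact)
}

#' Bonferroni significance threshold
#'
#' The family-wise threshold `alpha / m` used by the discovery and
#' replication screens; with `alpha = 0.05` over 324 retained metabolites
#' this is 1.54e-4.
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return numeric(1) threshold.
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha <= 1, m >= 1)
  alpha / m
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotonicity enforced;
#' adjusted p >= raw p), as used within each site-pair family of the
#' gradient analysis.
#'
#' @param p numeric vector of p-values (`NA` allowed, preserved).
#' @return numeric vector of adjusted p-values.
#' @export
benjaminiHochberg <- function(p) p.adjust(p, method = "BH")
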