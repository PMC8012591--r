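## small, fast configurations for unit tests; acceptance tests set their own
small_cfg <- function(...) {
  args <- list(m = 60, n_hc_discovery = 25, n_hc_replication = 20,
               n_cteph_discovery = 40, n_cteph_replication = 35,
               n_dc = 20, n_cted = 20, n_ipah = 25,
               n_pre_unpaired = 30, n_post_unpaired = 30, n_paired = 20,
               n_trisite_cteph = 40, n_trisite_ipah = 10, seed = 42)
  do.call(synthConfig, utils::modifyList(args, list(...)))
}

## tiny complete experiment on a given scale, for operation-level tests
toy_experiment <- function(m, scale_tag = "imputed", colData = NULL) {
  MetabExperiment(m, colData = colData, scale_tag = scale_tag)
}

quiet_preprocess <- function(e, ...)
  suppressMessages(suppressWarnings(preprocess(e, ...)))

## independent two-sided Mann-Whitney oracle: full enumeration over group
## relabellings (utils::combn), midrank U statistic
mw_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  list(U = U, p = mean(abs(us - mu) >= abs(U - mu) - 1e-9))
}

## independent signed-rank oracle: full enumeration of sign flips
wsr_oracle <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  W <- sum(r[d > 0]); mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  ws <- signs %*% r
  mean(abs(ws - mu) >= abs(W - mu) - 1e-9)
}

## independent BH step-up reference
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

## independent two-sided Fisher oracle from the hypergeometric density
fisher_oracle <- function(k, K, n, N) {
  supp <- max(0, n - (N - K)):min(K, n)
  dens <- dhyper(supp, K, N - K, n)
  sum(dens[dens <= dhyper(k, K, N - K, n) * (1 + 1e-7)])
}
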