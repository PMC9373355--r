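# Independent brute-force oracles used to check the closed-form statistics.

# Step-up FDR selection by direct enumeration over ranks.
bh_brute_force <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  if (!length(k)) return(list(selected = rep(FALSE, m), threshold = NA_real_))
  thr <- ps[max(k)]
  list(selected = p <= thr, threshold = thr)
}

# Exhaustive two-sided rank-sum p-value over all group assignments.
wilcoxon_enumerate <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2L, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Upper-tail hypergeometric by pmf summation.
hyper_tail_sum <- function(k, nA, nB, nU) {
  kk <- k:min(nA, nB)
  sum(stats::dhyper(kk, nA, nU - nA, nB))
}

# Simulate an eQTL/GWAS summary pair for one gene under the TWMR model
# (independent instruments, standardized effect noise 1/n).
sim_twmr_gene <- function(alpha, k = 10, n_eqtl = 3000, n_gwas = 50000,
                          beta_range = c(0.3, 0.7)) {
  b <- runif(k, beta_range[1], beta_range[2])
  E_hat <- matrix(b + rnorm(k, 0, 1 / sqrt(n_eqtl)), ncol = 1,
                  dimnames = list(sprintf("s%02d", seq_len(k)), "gene"))
  G_hat <- alpha * b + rnorm(k, 0, 1 / sqrt(n_gwas))
  structure(list(focal_gene = "gene", snp_ids = rownames(E_hat),
                 E = E_hat, G = G_hat, C = diag(k),
                 n_eqtl = n_eqtl, n_gwas = n_gwas),
            class = "InstrumentSet")
}
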