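# Shared fixtures: small panels, kinship matrices, and quick chain settings.

quick_mcmc <- function(seed = 1, burn = 300, iter = 1500, thin = 2) {
  mcmc_settings(burn, iter, thin = thin, seed = seed)
}

# small DH panel with family-structured kinship
small_kinship <- function(n_lines = 120, n_markers = 400, n_families = 6, seed = 3) {
  mk <- simulate_markers(n_lines, n_markers, n_families, seed = seed)
  list(markers = mk, K = kinship_from_markers(mk))
}

# block kinship matrix (families of `size`, within-family relatedness `rho`)
block_kinship <- function(n, size = 8, rho = 0.5) {
  fam <- rep(seq_len(ceiling(n / size)), each = size)[seq_len(n)]
  K <- outer(fam, fam, function(a, b) ifelse(a == b, rho, 0)) + (1 - rho) * diag(n)
  rownames(K) <- colnames(K) <- sprintf("L%04d", seq_len(n))
  K
}

# 3-trait chain truth T1 -> T2 -> T3 with unit coefficients and unit psi:
# implied covariance [[1,1,2],[1,2,3],[2,3,6]]
chain_truth_unit <- function() {
  lu <- matrix(0, 3, 3); lu[2, 1] <- 1; lu[3, 2] <- 1
  synthetic_truth(lu, matrix(0, 3, 3), psi_u = rep(1, 3), psi_e = rep(1, 3))
}

# deterministic multivariate normal draws with exact-ish sample behavior
rmvn <- function(n, Sigma) {
  matrix(stats::rnorm(n * nrow(Sigma)), n) %*% chol(Sigma)
}
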