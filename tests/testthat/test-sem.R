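# Structured covariance reconstruction, parameter counting, SEM fitting.

test_that("reconstructed covariances match closed forms", {
  expect_equal(reconstruct_covariance(matrix(0, 3, 3), c(1, 2, 3)),
               diag(c(1, 2, 3)), ignore_attr = TRUE)
  # d = 2 single coefficient
  b <- 0.7; psi <- c(1.3, 0.4)
  L <- matrix(0, 2, 2); L[2, 1] <- b
  expect_equal(reconstruct_covariance(L, psi),
               matrix(c(psi[1], b * psi[1], b * psi[1], b^2 * psi[1] + psi[2]), 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  # d = 3 fully recursive unit coefficients, Psi = I
  Lf <- matrix(0, 3, 3); Lf[lower.tri(Lf)] <- 1
  A <- solve(diag(3) - Lf)
  expect_equal(reconstruct_covariance(Lf, rep(1, 3)), A %*% t(A),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(reconstruct_covariance(Lf, rep(1, 3)),
               matrix(c(1, 1, 2, 1, 2, 3, 2, 3, 6), 3),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("reconstruction is positive definite for random coefficients", {
  set.seed(1)
  for (rep in 1:25) {
    d <- sample(2:6, 1)
    L <- matrix(0, d, d)
    L[lower.tri(L)] <- rnorm(d * (d - 1) / 2, sd = 3) *
      rbinom(d * (d - 1) / 2, 1, 0.6)
    psi <- rexp(d) + 0.01
    C <- reconstruct_covariance(L, psi)
    expect_silent(chol(C))
  }
})

test_that("coefficient-prior floors reproduce the stated thresholds", {
  expect_equal(coeff_prior_floor(5.0), 6.25)
  expect_equal(coeff_prior_floor(0.52), 0.0676)
  # the package defaults clear their floors
  spec <- sem_spec(structure_genomic = fully_recursive_structure(sprintf("T%d", 1:5)))
  expect_gt(spec$coeff_prior_var_genomic, coeff_prior_floor(5.0))
  expect_gt(spec$coeff_prior_var_residual, coeff_prior_floor(0.52))
})

test_that("parameter counting matches the fully recursive, empty, and chain cases", {
  nodes <- sprintf("T%d", 1:5)
  spec_full <- sem_spec(structure_genomic = fully_recursive_structure(nodes),
                        structure_residual = fully_recursive_structure(nodes))
  cnt <- count_parameters(spec_full, 5)
  expect_equal(cnt$connections_genomic, 10, ignore_attr = TRUE)
  expect_equal(cnt$nonnull_genomic, 15, ignore_attr = TRUE)
  expect_equal(cnt$connections_residual, 10, ignore_attr = TRUE)
  expect_equal(cnt$nonnull_residual, 15, ignore_attr = TRUE)
  spec_empty <- sem_spec(structure_genomic = empty_structure(nodes))
  cnt0 <- count_parameters(spec_empty, 5)
  expect_equal(cnt0$connections_genomic, 0, ignore_attr = TRUE)
  expect_equal(cnt0$nonnull_genomic, 5, ignore_attr = TRUE)
  # unstructured counts as fully recursive
  expect_equal(cnt0$connections_residual, 10, ignore_attr = TRUE)
  expect_equal(cnt0$nonnull_residual, 15, ignore_attr = TRUE)
  # chain A -> B -> C: 2 connections, dense reconstruction (6 nonnull)
  ch <- bn_dag(c("A", "B", "C"), data.frame(from = c("A", "B"), to = c("B", "C")))
  spec_ch <- sem_spec(structure_genomic = to_structure_matrix(ch))
  cnt_ch <- count_parameters(spec_ch, 3)
  expect_equal(cnt_ch$connections_genomic, 2, ignore_attr = TRUE)
  expect_equal(cnt_ch$nonnull_genomic, 6, ignore_attr = TRUE)
  # two disconnected arcs A -> B, C -> D: sparse reconstruction
  g2 <- bn_dag(c("A", "B", "C", "D"),
               data.frame(from = c("A", "C"), to = c("B", "D")))
  cnt2 <- count_parameters(sem_spec(structure_genomic = to_structure_matrix(g2)), 4)
  expect_equal(cnt2$nonnull_genomic, 6, ignore_attr = TRUE)  # 4 diag + 2 covariances
})

test_that("sem_spec validates its inputs", {
  expect_error(sem_spec(), "at least one")
  expect_error(sem_spec(structure_genomic = "nonsense"), "structure_matrix")
})

test_that("SEM recovers free coefficients and keeps structural zeros at zero", {
  # sparse truth, learning input generated at the component level
  lu <- matrix(0, 3, 3); lu[2, 1] <- 0.8; lu[3, 2] <- 0.6
  le <- matrix(0, 3, 3); le[2, 1] <- 0.5
  truth <- synthetic_truth(lu, le, rep(0.5, 3), rep(0.5, 3))
  K <- block_kinship(400, size = 8, rho = 0.5)
  panel <- simulate_panel(truth, K, seed = 42)
  nodes <- trait_names(panel)
  dag_u <- bn_dag(nodes, data.frame(from = c("T1", "T2"), to = c("T2", "T3")))
  dag_e <- bn_dag(nodes, data.frame(from = "T1", to = "T2"))
  spec <- sem_spec(structure_genomic = to_structure_matrix(dag_u),
                   structure_residual = to_structure_matrix(dag_e))
  fit <- fit_sem(panel, K, spec, mcmc = mcmc_settings(400, 2000, 2, seed = 43))
  lamg <- fit$lambda_genomic
  expect_equal(nrow(lamg), 2)
  truth_coef <- c(0.8, 0.6)
  found <- lamg$estimate[match(c("T2", "T3"), lamg$child)]
  sds <- lamg$sd[match(c("T2", "T3"), lamg$child)]
  expect_true(all(abs(found - truth_coef) < 3 * sds))
  lamr <- fit$lambda_residual
  expect_true(abs(lamr$estimate - 0.5) < 3.5 * lamr$sd)
  # structural zeros: reconstructed G* has zero mass outside the fill-in
  # pattern only through Lambda entries; check the stored pattern is respected
  expect_setequal(paste(lamg$child, lamg$parent), c("T2 T1", "T3 T2"))
  expect_true(all(eigen(fit$G_hat, only.values = TRUE)$values > 0))
  # deviance draws finite and DIC computable
  dic <- compute_dic(fit)
  expect_true(is.finite(dic$dic))
})

test_that("a forced-diagonal genomic structure degrades fit on correlated data", {
  lu <- matrix(0, 3, 3); lu[2, 1] <- 1; lu[3, 2] <- 0.8
  truth <- synthetic_truth(lu, matrix(0, 3, 3), rep(0.4, 3), rep(0.4, 3))
  K <- block_kinship(300, size = 10, rho = 0.6)
  panel <- simulate_panel(truth, K, seed = 7)
  nodes <- trait_names(panel)
  mc <- mcmc_settings(300, 1200, 2, seed = 8)
  spec_diag <- sem_spec(structure_genomic = empty_structure(nodes))
  fit_diag <- fit_sem(panel, K, spec_diag, mcmc = mc)
  fit_full <- fit_mtm(panel, K, mcmc = mc)
  # G* forced diagonal
  offdiag <- fit_diag$G_hat[upper.tri(fit_diag$G_hat)]
  expect_true(all(offdiag == 0))
  m_diag <- fit_metrics(fit_diag, panel, K, "diag")
  m_full <- fit_metrics(fit_full, panel, K, "MTM")
  expect_gt(m_diag$dic, m_full$dic)
  expect_lt(m_diag$log_marginal, m_full$log_marginal)
})

test_that("the SEM sampler passes a prior-predictive calibration check", {
  # parameters from the prior, data from the model, rank of each true
  # parameter among its posterior draws ~ uniform
  set.seed(99)
  n <- 50; d <- 2
  K <- block_kinship(n, 5, 0.5)
  Lk <- t(chol(K))
  nodes <- c("T1", "T2")
  arc <- to_structure_matrix(bn_dag(nodes, data.frame(from = "T1", to = "T2")))
  none <- empty_structure(nodes)
  spec <- sem_spec(structure_genomic = arc, structure_residual = none,
                   coeff_prior_var_genomic = 0.5)
  n_rep <- 20
  ranks <- NULL
  for (r in seq_len(n_rep)) {
    lam <- rnorm(1, 0, sqrt(spec$coeff_prior_var_genomic))
    psi_u <- 3 / rchisq(d, df = 4)
    psi_e <- 3 / rchisq(d, df = 4)
    L <- matrix(0, d, d); L[2, 1] <- lam
    Gstar <- reconstruct_covariance(L, psi_u)
    U <- Lk %*% matrix(rnorm(n * d), n, d) %*% chol(Gstar)
    E <- matrix(rnorm(n * d), n, d) %*% chol(diag(psi_e))
    Y <- U + E; colnames(Y) <- nodes
    panel <- tibble::tibble(genotype_id = rownames(K), family_id = "F01")
    panel <- dplyr::bind_cols(panel, tibble::as_tibble(Y))
    class(panel) <- c("trait_panel", class(panel))
    fit <- fit_sem(panel, K, spec,
                   mcmc = mcmc_settings(300, 1200, 3, seed = 1000 + r),
                   include_mu = FALSE)
    draws_lam <- fit$lambda_g_samples[, 1]
    ranks <- rbind(ranks, c(
      lambda = mean(draws_lam < lam),
      psi_u1 = mean(fit$psi_g_samples[, 1] < psi_u[1]),
      psi_u2 = mean(fit$psi_g_samples[, 2] < psi_u[2]),
      psi_e1 = mean(fit$R_samples[1, 1, ] < psi_e[1]),
      psi_e2 = mean(fit$R_samples[2, 2, ] < psi_e[2])))
  }
  for (j in seq_len(ncol(ranks))) {
    # break rank ties before the KS uniformity test
    p <- stats::ks.test(ranks[, j] + runif(n_rep, 0, 1e-3), "punif")$p.value
    expect_gt(p, 0.005)
  }
})
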