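# MTM decomposition: priors, Gibbs sampler, posterior summaries.

test_that("inverse-Wishart mode follows Sigma / (nu + d + 1)", {
  expect_equal(diag(inverse_wishart_mode(8, 7 * diag(5), 5)), rep(0.5, 5))
  expect_equal(inverse_wishart_mode(4, (4 + 4 + 1) * diag(4), 4), diag(4))
  # d = 1 scaled-inverse chi-square special case: mode = scale / (nu + 2)
  expect_equal(inverse_wishart_mode(4, 3, 1), matrix(0.5))
  expect_error(inverse_wishart_mode(2, diag(3), 3), "degrees of freedom")
})

test_that("residual identity E = Y - 1 mu' - U holds to machine precision", {
  kk <- small_kinship(60, 200, 3, seed = 1)
  truth <- chain_truth_unit()
  panel <- simulate_panel(truth, kk$K, seed = 2, family_ids = kk$markers$family_ids)
  fit <- fit_mtm(panel, kk$K, mcmc = quick_mcmc(seed = 3, burn = 100, iter = 300))
  recon <- fit$Y - outer(rep(1, fit$n), fit$mu_hat) - fit$U_hat
  expect_equal(fit$E_hat, recon, tolerance = 1e-12)
  expect_equal(fit$G_hat, t(fit$G_hat))
  expect_true(all(eigen(fit$G_hat, only.values = TRUE)$values > 0))
  expect_true(all(eigen(fit$R_hat, only.values = TRUE)$values > 0))
})

test_that("with fixed variance components the posterior mean of u is the GLS BLUP", {
  kk <- small_kinship(120, 400, 6, seed = 3)
  K <- unclass(kk$K)
  truth <- synthetic_truth(matrix(0, 1, 1), matrix(0, 1, 1), 0.6, 0.4)
  panel <- simulate_panel(truth, kk$K, seed = 5, family_ids = kk$markers$family_ids)
  y <- trait_matrix(panel)[, 1]
  sg <- 0.6; se <- 0.4
  V <- sg * K + se * diag(120)
  one <- rep(1, 120)
  mu_gls <- drop(solve(t(one) %*% solve(V, one), t(one) %*% solve(V, y)))
  blup <- drop(sg * K %*% solve(V, y - mu_gls))
  fit <- fit_mtm(panel, kk$K, mcmc = mcmc_settings(500, 6000, 3, seed = 9),
                 fix_G = matrix(sg), fix_R = matrix(se))
  expect_gt(stats::cor(fit$U_hat[, 1], blup), 0.998)
  expect_lt(sqrt(mean((fit$U_hat[, 1] - blup)^2)), 0.08)
})

test_that("the sampler recovers known covariance components", {
  lu <- matrix(0, 3, 3); lu[2, 1] <- 0.8; lu[3, 2] <- 0.6
  truth <- synthetic_truth(lu, matrix(0, 3, 3), rep(0.5, 3), rep(0.5, 3))
  kk <- small_kinship(300, 800, 10, seed = 11)
  panel <- simulate_panel(truth, kk$K, seed = 13, family_ids = kk$markers$family_ids)
  fit <- fit_mtm(panel, kk$K, mcmc = mcmc_settings(400, 2000, 2, seed = 17))
  # every free covariance entry within 3 posterior SDs of the truth
  for (i in 1:3) for (j in i:3) {
    draws_G <- fit$G_samples[i, j, ]
    expect_lt(abs(mean(draws_G) - truth$implied_G[i, j]), 3.5 * stats::sd(draws_G))
    draws_R <- fit$R_samples[i, j, ]
    expect_lt(abs(mean(draws_R) - truth$implied_R[i, j]), 3.5 * stats::sd(draws_R))
  }
})

test_that("zero-variance traits are rejected", {
  kk <- small_kinship(30, 100, 2, seed = 19)
  panel <- tibble::tibble(genotype_id = kk$markers$line_ids,
                          family_id = kk$markers$family_ids,
                          T1 = rnorm(30), T2 = rep(1, 30))
  class(panel) <- c("trait_panel", class(panel))
  expect_error(fit_mtm(panel, kk$K, mcmc = quick_mcmc()), "zero-variance")
})

test_that("posterior correlations average per draw with the documented SD denominator", {
  fit <- structure(list(
    traits = c("A", "B"),
    G_samples = array(c(1, .5, .5, 1, 1, .9, .9, 1), c(2, 2, 2)),
    R_samples = array(rep(c(1, 0, 0, 1), 2), c(2, 2, 2))),
    class = "mtm_fit")
  pc <- posterior_correlations(fit)
  g <- pc[pc$component == "genomic", ]
  expect_equal(g$correlation, 0.7)
  expect_equal(g$sd, stats::sd(c(0.5, 0.9)))   # n - 1 denominator: 0.28284...
  expect_equal(g$sd, 0.2828427, tolerance = 1e-6)
  r <- pc[pc$component == "residual", ]
  expect_equal(r$correlation, 0)
  expect_equal(r$sd, 0)
  # scale invariance: rescaling a trait's draws by a positive constant
  # (rows and columns of every draw) leaves correlations unchanged
  fit2 <- fit
  D <- diag(c(4, 1))
  for (s in 1:2) fit2$G_samples[, , s] <- D %*% fit$G_samples[, , s] %*% D
  pc2 <- posterior_correlations(fit2)
  expect_equal(pc2$correlation, pc$correlation, tolerance = 1e-12)
})

test_that("single-trait fit agrees with the d = 1 MTM under matched priors", {
  kk <- small_kinship(100, 300, 5, seed = 23)
  truth <- synthetic_truth(matrix(0, 1, 1), matrix(0, 1, 1), 0.6, 0.4)
  panel <- simulate_panel(truth, kk$K, seed = 25, family_ids = kk$markers$family_ids)
  y <- trait_matrix(panel)[, 1]
  st <- fit_single_trait(y, kk$K, mcmc = mcmc_settings(400, 3000, 2, seed = 27))
  mt <- fit_mtm(panel, kk$K,
                hyper = mtm_hyperparams(1, nu_G = 4, Sigma_G = matrix(3),
                                        nu_R = 4, Sigma_R = matrix(3)),
                mcmc = mcmc_settings(400, 3000, 2, seed = 27))
  expect_equal(st$G_hat[1, 1], mt$G_hat[1, 1], tolerance = 0.1)
  expect_gt(stats::cor(st$U_hat[, 1], mt$U_hat[, 1]), 0.99)
  # no-signal trait: genomic variance concentrates below the prior mode
  y0 <- rep(0, 100) + rnorm(100, sd = 1e-3)
  st0 <- fit_single_trait(y0, kk$K, mcmc = mcmc_settings(300, 1500, 2, seed = 29))
  expect_lt(st0$G_hat[1, 1], 0.5)
  # near-heritability-1: genomic variance approaches the sample variance of y
  truth1 <- synthetic_truth(matrix(0, 1, 1), matrix(0, 1, 1), 1.0, 1e-4)
  p1 <- simulate_panel(truth1, kk$K, seed = 31, family_ids = kk$markers$family_ids)
  y1 <- trait_matrix(p1)[, 1]
  st1 <- fit_single_trait(y1, kk$K, mcmc = mcmc_settings(400, 3000, 2, seed = 33))
  expect_gt(st1$G_hat[1, 1] / stats::var(y1), 0.6)
  expect_lt(st1$R_hat[1, 1], st1$G_hat[1, 1] / 2)
})

test_that("tidy and glance summarize fits as tibbles", {
  kk <- small_kinship(50, 150, 3, seed = 35)
  truth <- chain_truth_unit()
  panel <- simulate_panel(truth, kk$K, seed = 37, family_ids = kk$markers$family_ids)
  fit <- fit_mtm(panel, kk$K, mcmc = quick_mcmc(seed = 39, burn = 100, iter = 400))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$component), c("intercept", "genomic", "residual"))
  expect_equal(nrow(td), 3 + 6 + 6)
  gl <- glance(fit)
  expect_equal(gl$n, 50)
  expect_true(is.finite(gl$dic))
})
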