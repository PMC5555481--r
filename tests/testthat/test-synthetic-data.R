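# Synthetic marker, kinship, and panel generation.

test_that("simulated markers are homozygous-coded, polymorphic, and reproducible", {
  mk <- simulate_markers(60, 200, 4, seed = 1)
  expect_true(all(mk$values %in% c(0L, 2L)))
  expect_true(all(apply(mk$values, 2, function(g) length(unique(g)) > 1)))
  mk2 <- simulate_markers(60, 200, 4, seed = 1)
  expect_identical(mk$values, mk2$values)
  mk3 <- simulate_markers(60, 200, 4, seed = 2)
  expect_false(identical(mk$values, mk3$values))
})

test_that("monomorphic-heavy settings error with the allele-frequency settings named", {
  # Beta(0.02, 0.02) pushes family frequencies to 0/1: most markers fixed
  expect_error(simulate_markers(4, 40, 1, seed = 1, beta_shape = c(0.02, 0.02)),
               "allele-frequency")
})

test_that("family structure raises within-family similarity above between-family", {
  mk <- simulate_markers(800, 2000, 10, seed = 1)
  K <- kinship_from_markers(mk)
  same <- outer(mk$family_ids, mk$family_ids, "==")
  off <- upper.tri(K)
  within <- mean(K[off & same])
  between <- mean(K[off & !same])
  expect_gt(within, between)
})

test_that("simple-matching kinship has unit diagonal and matches a brute-force oracle", {
  mk <- simulate_markers(30, 50, 3, seed = 7)
  K <- kinship_from_markers(mk)
  expect_equal(unname(diag(unclass(K))), rep(1, 30))
  expect_true(all(K >= 0 & K <= 1))
  expect_equal(unclass(K), t(unclass(K)))
  # O(n^2 m) double loop
  V <- mk$values
  K_oracle <- matrix(0, 30, 30)
  for (i in 1:30) for (j in 1:30) K_oracle[i, j] <- mean(V[i, ] == V[j, ])
  expect_equal(unname(unclass(K)), K_oracle, tolerance = 1e-12)
  # hand examples
  expect_equal(unname(unclass(kinship_from_markers(rbind(c(0, 0, 2, 2), c(0, 0, 2, 2))))[1, 2]), 1)
  expect_equal(unname(unclass(kinship_from_markers(rbind(c(0, 0, 2, 2), c(0, 2, 2, 0))))[1, 2]), 0.5)
  expect_error(kinship_from_markers(matrix(0, 2, 0)), "markers")
})

test_that("independent components give trait covariance ~ 2I and K = I decorrelates genotypes", {
  truth <- synthetic_truth(matrix(0, 2, 2), matrix(0, 2, 2),
                           psi_u = c(1, 1), psi_e = c(1, 1))
  n <- 5000
  K <- diag(n); rownames(K) <- colnames(K) <- sprintf("L%04d", 1:n)
  panel <- simulate_panel(truth, K, seed = 11)
  S <- stats::cov(trait_matrix(panel))
  # var of a sample variance of 2*chi2-ish: se ~ sqrt(2/n)*var
  se <- sqrt(2 / n) * 2
  expect_lt(max(abs(diag(S) - 2)), 3 * se)
  expect_lt(abs(S[1, 2]), 3 * sqrt(4 / n))
  # cross-genotype independence of u under K = I
  U <- attr(panel, "U")
  cc <- stats::cor(U[seq(1, n, by = 2), 1], U[seq(2, n, by = 2), 1])
  expect_lt(abs(cc), 0.1)
})

test_that("implied covariances match direct (I - Lambda)^-1 Psi (I - Lambda)^-T products", {
  # chain T1 -> T2 -> T3 with unit coefficients
  truth <- chain_truth_unit()
  expect_equal(truth$implied_G,
               matrix(c(1, 1, 1, 1, 2, 2, 1, 2, 3), 3), ignore_attr = TRUE)
  # fully recursive unit coefficients: the dense d = 3 case
  Lf <- matrix(0, 3, 3); Lf[lower.tri(Lf)] <- 1
  tf <- synthetic_truth(Lf, matrix(0, 3, 3), rep(1, 3), rep(1, 3))
  expect_equal(tf$implied_G,
               matrix(c(1, 1, 2, 1, 2, 3, 2, 3, 6), 3), ignore_attr = TRUE)
  n <- 5000
  K <- diag(n); rownames(K) <- colnames(K) <- sprintf("L%04d", 1:n)
  panel <- simulate_panel(truth, K, seed = 13)
  S_u <- stats::cov(attr(panel, "U"))
  # Monte-Carlo tolerance: ~3 relative standard errors on covariances
  expect_lt(max(abs(S_u - truth$implied_G) / (1 + abs(truth$implied_G))),
            3 * sqrt(2 / n) * 1.6)
  S_e <- stats::cov(attr(panel, "E"))
  expect_lt(max(abs(S_e - truth$implied_R)), 3 * sqrt(2 / n) * 1.6)
})

test_that("panel regeneration with one seed is bit-identical; seeds differ", {
  kk <- small_kinship(40, 100, 2, seed = 5)
  truth <- chain_truth_unit()
  p1 <- simulate_panel(truth, kk$K, seed = 9, family_ids = kk$markers$family_ids)
  p2 <- simulate_panel(truth, kk$K, seed = 9, family_ids = kk$markers$family_ids)
  expect_identical(trait_matrix(p1), trait_matrix(p2))
  p3 <- simulate_panel(truth, kk$K, seed = 10, family_ids = kk$markers$family_ids)
  expect_false(identical(trait_matrix(p1), trait_matrix(p3)))
})

test_that("standardization centers family means, scales to unit variance, and is idempotent", {
  kk <- small_kinship(90, 150, 3, seed = 21)
  truth <- default_truth()
  panel <- simulate_panel(truth, kk$K, seed = 23, family_ids = kk$markers$family_ids)
  std <- standardize_panel(panel)
  Y <- trait_matrix(std)
  for (fam in unique(std$family_id)) {
    expect_lt(max(abs(colMeans(Y[std$family_id == fam, , drop = FALSE]))), 1e-10)
  }
  expect_equal(unname(apply(Y, 2, stats::var)), rep(1, 5), tolerance = 1e-10)
  std2 <- standardize_panel(std)
  expect_equal(trait_matrix(std2), Y, tolerance = 1e-12)
})

test_that("truth validation rejects non-triangular structures and non-PD outputs are PD", {
  bad <- matrix(0, 3, 3); bad[1, 2] <- 0.5
  expect_error(synthetic_truth(bad, matrix(0, 3, 3), rep(1, 3), rep(1, 3)),
               "lower triangular")
  tr <- default_truth()
  expect_true(all(eigen(tr$implied_G, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_true(all(eigen(tr$implied_R, symmetric = TRUE, only.values = TRUE)$values > 0))
  # zero structures imply diagonal covariances
  tr0 <- synthetic_truth(matrix(0, 2, 2), matrix(0, 2, 2), c(2, 3), c(1, 1))
  expect_equal(tr0$implied_G, diag(c(2, 3)), ignore_attr = TRUE)
})

test_that("panel, kinship and truth round-trip through CSV and YAML", {
  kk <- small_kinship(30, 80, 2, seed = 31)
  truth <- default_truth()
  panel <- simulate_panel(truth, kk$K, seed = 33, family_ids = kk$markers$family_ids)
  tmp <- withr::local_tempdir()
  write_panel(panel, file.path(tmp, "p.csv"))
  p2 <- read_panel(file.path(tmp, "p.csv"))
  expect_equal(trait_matrix(p2), trait_matrix(panel), tolerance = 1e-12)
  write_kinship(kk$K, file.path(tmp, "k.csv"))
  K2 <- read_kinship(file.path(tmp, "k.csv"))
  expect_equal(unclass(K2), unclass(kk$K), tolerance = 1e-12, ignore_attr = TRUE)
  write_truth(truth, file.path(tmp, "t.yaml"))
  t2 <- read_truth(file.path(tmp, "t.yaml"))
  expect_equal(t2$lambda_u, truth$lambda_u, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(t2$implied_G, truth$implied_G, tolerance = 1e-9, ignore_attr = TRUE)
})
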