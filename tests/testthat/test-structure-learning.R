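# Scores, Grow-Shrink, tabu search, and bootstrap averaging.

test_that("empty-graph BIC is the sum of univariate Gaussian fits minus penalties", {
  set.seed(1)
  X <- data.frame(A = rnorm(200), B = rnorm(200), C = rnorm(200))
  g0 <- bn_dag(c("A", "B", "C"))
  n <- 200
  expected <- sum(vapply(X, function(col) {
    s2 <- mean((col - mean(col))^2)
    -n / 2 * (log(2 * pi * s2) + 1) - 2 / 2 * log(n)
  }, numeric(1)))
  expect_equal(score_network(X, g0, "bic"), expected, tolerance = 1e-10)
})

test_that("BIC and BGe are score equivalent on reversible arcs", {
  set.seed(2)
  X <- data.frame(A = rnorm(150))
  X$B <- 0.5 * X$A + rnorm(150)
  fwd <- bn_dag(c("A", "B"), data.frame(from = "A", to = "B"))
  bwd <- bn_dag(c("A", "B"), data.frame(from = "B", to = "A"))
  expect_equal(score_network(X, fwd, "bic"), score_network(X, bwd, "bic"),
               tolerance = 1e-8)
  expect_equal(score_network(X, fwd, "bge"), score_network(X, bwd, "bge"),
               tolerance = 1e-8)
})

test_that("scores over all 25 three-node DAGs match per-node regression oracles", {
  set.seed(3)
  n <- 300
  X <- data.frame(A = rnorm(n))
  X$B <- 0.7 * X$A + rnorm(n)
  X$C <- -0.4 * X$B + rnorm(n)
  dags <- enumerate_dags(c("A", "B", "C"))
  oracle_bic <- function(g) {
    pa <- traitnets:::dag_parents(g)
    sum(vapply(g$nodes, function(v) {
      fit <- if (length(pa[[v]]))
        stats::lm(stats::reformulate(pa[[v]], v), data = X)
      else stats::lm(stats::reformulate("1", v), data = X)
      s2 <- mean(stats::residuals(fit)^2)
      -n / 2 * (log(2 * pi * s2) + 1) - (length(pa[[v]]) + 2) / 2 * log(n)
    }, numeric(1)))
  }
  for (g in dags) {
    expect_equal(score_network(X, g, "bic"), oracle_bic(g), tolerance = 1e-8)
  }
  # score equivalence across every equivalence class, both scores
  keys <- vapply(dags, cpdag_key, character(1))
  for (sc in c("bic", "bge")) {
    scores <- vapply(dags, function(g) score_network(X, g, sc), numeric(1))
    spread <- tapply(scores, keys, function(s) diff(range(s)))
    expect_lt(max(spread), 1e-8)
  }
})

test_that("BGe of a complete DAG equals the joint normal-Wishart marginal likelihood", {
  set.seed(4)
  n <- 120; d <- 3
  X <- as.data.frame(matrix(rnorm(n * d), n, d))
  colnames(X) <- c("A", "B", "C")
  full <- bn_dag(c("A", "B", "C"),
                 data.frame(from = c("A", "A", "B"), to = c("B", "C", "C")))
  am <- 1; aw <- d + 2; t_sc <- am * (aw - d - 1) / (am + 1)
  Xc <- scale(as.matrix(X), scale = FALSE)
  R <- t_sc * diag(d) + crossprod(Xc)
  joint <- -n * d / 2 * log(pi) + d / 2 * log(am / (n + am)) +
    traitnets:::lmvgamma((n + aw) / 2, d) - traitnets:::lmvgamma(aw / 2, d) +
    aw / 2 * d * log(t_sc) -
    (n + aw) / 2 * determinant(R, logarithm = TRUE)$modulus[[1]]
  expect_equal(score_network(X, full, "bge"), joint, tolerance = 1e-8)
})

test_that("Grow-Shrink recovers independence, colliders, and chains", {
  set.seed(5)
  n <- 2000
  # mutually independent columns -> empty graph
  D0 <- data.frame(X = rnorm(1000), Y = rnorm(1000), Z = rnorm(1000))
  g0 <- grow_shrink(D0, ci_test_config("pearson_exact_t", alpha = 0.01))
  expect_equal(nrow(g0$arcs) + nrow(g0$undirected), 0)
  # collider Z = X + Y + noise
  x <- rnorm(n); y <- rnorm(n); z <- x + y + rnorm(n)
  gc <- grow_shrink(data.frame(X = x, Y = y, Z = z),
                    ci_test_config("pearson_exact_t", alpha = 0.01))
  expect_setequal(paste(gc$arcs$from, gc$arcs$to), c("X Z", "Y Z"))
  # chain X -> Y -> Z: skeleton X - Y - Z without a collider at Y
  x2 <- rnorm(n); y2 <- x2 + rnorm(n); z2 <- y2 + rnorm(n)
  gch <- grow_shrink(data.frame(X = x2, Y = y2, Z = z2),
                     ci_test_config("mutual_information_chi2", alpha = 0.01))
  expect_setequal(traitnets:::skeleton_key(gch), c("X~Y", "Y~Z"))
  expect_length(traitnets:::v_structure_key(gch), 0)
})

test_that("tabu search attains the exhaustive-search optimum on four nodes", {
  set.seed(6)
  n <- 1000
  X <- data.frame(A = rnorm(n))
  X$B <- 0.8 * X$A + rnorm(n)
  X$C <- 0.6 * X$B + rnorm(n)
  X$D <- -0.5 * X$A + 0.4 * X$C + rnorm(n)
  dags <- enumerate_dags(c("A", "B", "C", "D"))
  for (sc in c("bic", "bge")) {
    found <- tabu_search(X, score = sc)
    best <- max(vapply(dags, function(g) score_network(X, g, sc), numeric(1)))
    expect_equal(score_network(X, found, sc), best, tolerance = 1e-8)
  }
  # determinism
  expect_identical(tabu_search(X, "bic")$arcs, tabu_search(X, "bic")$arcs)
  # independent columns -> empty graph
  D0 <- data.frame(X = rnorm(500), Y = rnorm(500), Z = rnorm(500))
  expect_equal(nrow(tabu_search(D0, "bic")$arcs), 0)
})

test_that("bootstrap averaging reproduces a fixed learner and honors B = 1", {
  set.seed(7)
  X <- data.frame(A = rnorm(80), B = rnorm(80), C = rnorm(80))
  fixed <- bn_dag(c("A", "B", "C"), data.frame(from = "A", to = "B"))
  avg <- bootstrap_average(X, function(d) fixed, B = 50, seed = 1)
  st <- avg$strengths
  expect_equal(st$strength[st$from == "A" & st$to == "B"], 1)
  expect_equal(st$direction[st$from == "A" & st$to == "B"], 1)
  expect_equal(max(st$strength[!(pmin(st$from, st$to) == "A" &
                                   pmax(st$from, st$to) == "B")]), 0)
  expect_identical(sort(paste(avg$averaged$arcs$from, avg$averaged$arcs$to)), "A B")
  # B = 1: averaged network equals the single learned network
  one <- bootstrap_average(X, function(d) fixed, B = 1, seed = 2)
  expect_identical(one$averaged$arcs, fixed$arcs)
  # strengths are symmetric in the unordered pair
  sym <- merge(st, st, by.x = c("from", "to"), by.y = c("to", "from"))
  expect_equal(sym$strength.x, sym$strength.y)
})

test_that("a strong simulated dependence earns arc strength above 0.7", {
  set.seed(8)
  n <- 800
  X <- data.frame(A = rnorm(n))
  X$B <- X$A + rnorm(n)
  X$C <- rnorm(n)
  avg <- bootstrap_average(X, learner_setting("gs3"), B = 100, seed = 3)
  st <- avg$strengths
  expect_gt(st$strength[st$from == "A" & st$to == "B"], 0.7)
})

test_that("bootstrap averaging fails loudly when too many replicates fail", {
  X <- data.frame(A = rnorm(40), B = rnorm(40))
  counter <- new.env(); counter$i <- 0
  flaky <- function(d) {
    counter$i <- counter$i + 1
    if (counter$i %% 2 == 0) stop("boom")
    bn_dag(c("A", "B"))
  }
  expect_error(bootstrap_average(X, flaky, B = 20, seed = 1),
               "failed on")
})

test_that("constraint-based learning is deterministic for fixed alpha", {
  set.seed(9)
  n <- 600
  X <- data.frame(A = rnorm(n)); X$B <- 0.6 * X$A + rnorm(n); X$C <- rnorm(n)
  for (alpha in c(0.001, 0.01, 0.05)) {
    cfg <- ci_test_config("pearson_exact_t", alpha = alpha)
    g1 <- grow_shrink(X, cfg); g2 <- grow_shrink(X, cfg)
    expect_identical(g1$arcs, g2$arcs)
    expect_identical(g1$undirected, g2$undirected)
  }
})
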