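# Gaussian Bayesian-network structure learning: node-wise BIC and BGe
# scores, the Grow-Shrink constraint-based algorithm, tabu search over DAG
# space, and nonparametric bootstrap averaging with an arc-strength
# significance threshold.

# ---- sufficient statistics and node-wise scores ----------------------------

# centered scatter matrix and BGe hyperparameters for a data set
score_suffstats <- function(data, alpha_mu = 1, alpha_w = NULL) {
  X <- as.matrix(as.data.frame(data))
  n <- nrow(X); d <- ncol(X)
  alpha_w <- alpha_w %||% (d + 2)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  S <- crossprod(Xc)
  t_scale <- alpha_mu * (alpha_w - d - 1) / (alpha_mu + 1)
  list(n = n, d = d, nodes = colnames(X), S = S, R = t_scale * diag(d) + S,
       t_scale = t_scale, alpha_mu = alpha_mu, alpha_w = alpha_w)
}

logdet_sub <- function(M, idx) {
  if (!length(idx)) return(0)
  determinant(M[idx, idx, drop = FALSE], logarithm = TRUE)$modulus[[1]]
}

# log BIC contribution of one node given its parents:
# Gaussian regression log-likelihood at the MLE minus (p + 2)/2 * log(n)
# (coefficients + intercept + residual variance; larger is better)
local_score_bic <- function(node, parents, ss) {
  k <- match(node, ss$nodes); P <- match(parents, ss$nodes)
  n <- ss$n
  rss <- ss$S[k, k]
  if (length(P)) {
    SP <- ss$S[P, P, drop = FALSE]
    sp <- ss$S[P, k, drop = FALSE]
    rss <- rss - drop(crossprod(sp, solve(SP, sp)))
  }
  sigma2 <- max(rss / n, .Machine$double.eps)
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  loglik - (length(P) + 2) / 2 * log(n)
}

# log BGe contribution of one node given its parents (Geiger-Heckerman
# normal-Wishart family, Kuipers-Moffa-Heckerman corrected form), with
# imaginary sample sizes alpha_mu (mean) and alpha_w (precision), prior
# mean equal to the sample mean, and prior scale t * I with
# t = alpha_mu (alpha_w - d - 1) / (alpha_mu + 1)
local_score_bge <- function(node, parents, ss) {
  k <- match(node, ss$nodes); P <- match(parents, ss$nodes)
  n <- ss$n; d <- ss$d; aw <- ss$alpha_w; am <- ss$alpha_mu
  p <- length(P)
  lt <- log(ss$t_scale)
  base <- 0.5 * log(am / (n + am)) - n / 2 * log(pi) +
    lgamma((n + aw - d + p + 1) / 2) - lgamma((aw - d + p + 1) / 2)
  top <- (aw - d + p + 1) / 2 * ((p + 1) * lt) -
    (n + aw - d + p + 1) / 2 * logdet_sub(ss$R, c(P, k))
  bot <- if (p) {
    (aw - d + p) / 2 * (p * lt) - (n + aw - d + p) / 2 * logdet_sub(ss$R, P)
  } else 0
  base + top - bot
}

local_score <- function(node, parents, ss, score, cache = NULL) {
  key <- paste0(node, "|", paste(sort(parents), collapse = ","))
  if (!is.null(cache)) {
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  val <- switch(score,
                bic = local_score_bic(node, parents, ss),
                bge = local_score_bge(node, parents, ss),
                stop("unknown score: ", score))
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' Score a directed acyclic network
#'
#' Decomposable node-wise network score, either the Gaussian BIC
#' (`loglik - (|pa| + 2)/2 * log(n)` per node, counting regression
#' coefficients, intercept and residual variance; larger is better) or the
#' Bayesian Gaussian equivalent (BGe) marginal likelihood. Both are
#' score-equivalent: all DAGs in one Markov-equivalence class receive the
#' same score.
#'
#' @param data n x d data frame or matrix with named columns.
#' @param dag a fully directed acyclic `bn_dag` over the columns.
#' @param score `"bic"` or `"bge"`.
#' @return scalar score (larger is better).
#' @export
score_network <- function(data, dag, score = c("bic", "bge")) {
  score <- match.arg(score)
  if (nrow(dag$undirected)) stop("network must be fully directed")
  if (!is_acyclic(dag)) stop("network contains a cycle")
  ss <- score_suffstats(data)
  stopifnot(all(dag$nodes %in% ss$nodes))
  pa <- dag_parents(dag)
  sum(vapply(dag$nodes, function(v) local_score(v, pa[[v]], ss, score), numeric(1)))
}

# ---- Grow-Shrink ------------------------------------------------------------

#' Learn a network with the Grow-Shrink algorithm
#'
#' Constraint-based learning: per-node Markov blankets are estimated with a
#' grow phase (add variables dependent given the current blanket) and a
#' shrink phase (remove variables independent given the rest), blankets are
#' symmetrized, direct neighbors are resolved by searching for separating
#' subsets within the smaller blanket, v-structures are oriented where the
#' collider is outside the recorded separating set, and remaining edges are
#' oriented by propagation rules that create neither cycles nor new
#' v-structures. The output may retain undirected edges (an equivalence
#' class).
#'
#' @param data n x d data frame or matrix with named columns.
#' @param config a [ci_test_config()].
#' @return a `bn_dag`, possibly with undirected edges.
#' @export
grow_shrink <- function(data, config = ci_test_config()) {
  data <- as.matrix(as.data.frame(data))
  nodes <- colnames(data)
  d <- length(nodes); n <- nrow(data)
  if (n <= d + 2) stop("need n > d + 2 observations")
  indep <- function(x, y, Z) {
    if (length(Z) > n - 3) return(TRUE)
    ci_test(data, x, y, Z, config)$p_value > config$alpha
  }
  # Markov blankets: grow then shrink, deterministic canonical scan order
  mb <- stats::setNames(vector("list", d), nodes)
  for (x in nodes) {
    S <- character(0)
    repeat {
      added <- FALSE
      for (y in setdiff(nodes, c(x, S))) {
        if (!indep(x, y, S)) { S <- c(S, y); added <- TRUE; break }
      }
      if (!added) break
    }
    repeat {
      removed <- FALSE
      for (y in S) {
        if (indep(x, y, setdiff(S, y))) { S <- setdiff(S, y); removed <- TRUE; break }
      }
      if (!removed) break
    }
    mb[[x]] <- S
  }
  # symmetry correction (AND rule)
  for (x in nodes) mb[[x]] <- Filter(function(y) x %in% mb[[y]], mb[[x]])
  # direct neighbors: x - y adjacent unless some subset of the smaller
  # blanket separates them; record separating sets
  sepset <- list()
  adj <- matrix(FALSE, d, d, dimnames = list(nodes, nodes))
  find_sep <- function(x, y, B) {
    for (size in 0:length(B)) {
      subs <- if (size == 0) list(character(0)) else
        apply(utils::combn(B, size), 2, identity, simplify = FALSE)
      for (T in subs) if (indep(x, y, T)) return(T)
    }
    NULL
  }
  for (x in nodes) for (y in mb[[x]]) {
    if (x >= y) next
    Bx <- setdiff(mb[[x]], y); By <- setdiff(mb[[y]], x)
    B <- if (length(Bx) <= length(By)) Bx else By
    Tsep <- find_sep(x, y, B)
    if (is.null(Tsep)) {
      adj[x, y] <- adj[y, x] <- TRUE
    } else {
      sepset[[pair_key(x, y)]] <- Tsep
    }
  }
  # v-structures: for non-adjacent x, z with common neighbor y, collider at
  # y when y is outside the separating set of (x, z)
  amat_dir <- matrix(0L, d, d, dimnames = list(nodes, nodes))
  for (y in nodes) {
    nb <- nodes[adj[y, ]]
    if (length(nb) < 2) next
    cmb <- utils::combn(sort(nb), 2)
    for (j in seq_len(ncol(cmb))) {
      x <- cmb[1, j]; z <- cmb[2, j]
      if (adj[x, z]) next
      Tsep <- sepset[[pair_key(x, z)]]
      if (is.null(Tsep)) {
        B <- union(setdiff(nodes[adj[x, ]], z), setdiff(nodes[adj[z, ]], x))
        Tsep <- find_sep(x, z, B)
      }
      if (is.null(Tsep)) next
      if (!(y %in% Tsep)) {
        # orient x -> y <- z unless it contradicts an existing orientation
        if (amat_dir[y, x] == 0L) amat_dir[x, y] <- 1L
        if (amat_dir[y, z] == 0L) amat_dir[z, y] <- 1L
      }
    }
  }
  arcs <- which(amat_dir == 1L, arr.ind = TRUE)
  arcs <- data.frame(from = nodes[arcs[, 1]], to = nodes[arcs[, 2]])
  und <- which(adj & upper.tri(adj), arr.ind = TRUE)
  und <- data.frame(from = nodes[und[, 1]], to = nodes[und[, 2]])
  if (nrow(arcs)) {
    directed_key <- pair_key(arcs$from, arcs$to)
    und <- und[!(pair_key(und$from, und$to) %in% directed_key), , drop = FALSE]
  }
  g <- bn_dag(nodes, arcs, und)
  meek_orient(g)
}

# ---- tabu search ------------------------------------------------------------

#' Learn a network by tabu search
#'
#' Greedy hill climbing over DAG space with arc additions, deletions, and
#' reversals; a tabu list of recently visited structures allows worsening
#' moves to escape local optima. The highest-scoring DAG visited is
#' returned. Deterministic for given data (ties between moves are broken in
#' canonical enumeration order).
#'
#' @param data n x d data frame or matrix with named columns.
#' @param score `"bic"` or `"bge"`.
#' @param tabu_length number of recent structures kept tabu (also the
#'   number of non-improving moves tolerated before stopping).
#' @param max_iter hard iteration cap.
#' @param seed kept for interface symmetry; the search itself is
#'   deterministic.
#' @return a fully directed `bn_dag`.
#' @export
tabu_search <- function(data, score = c("bic", "bge"), tabu_length = 10,
                        max_iter = 100, seed = 1) {
  score <- match.arg(score)
  ss <- score_suffstats(data)
  nodes <- ss$nodes
  d <- length(nodes)
  cache <- new.env(parent = emptyenv())
  ls_fun <- function(node, A) {
    local_score(node, nodes[A[, match(node, nodes)] == 1L], ss, score, cache)
  }
  A <- matrix(0L, d, d, dimnames = list(nodes, nodes))
  node_scores <- vapply(nodes, function(v) ls_fun(v, A), numeric(1))
  amat_key <- function(A) paste(A, collapse = "")
  cur_score <- sum(node_scores)
  best_A <- A; best_score <- cur_score
  tabu <- amat_key(A)
  stall <- 0L
  for (iter in seq_len(max_iter)) {
    best_move <- NULL; best_delta <- -Inf
    for (i in seq_len(d)) for (j in seq_len(d)) {
      if (i == j) next
      if (A[i, j] == 0L && A[j, i] == 0L) {
        A2 <- A; A2[i, j] <- 1L
        if (!amat_is_acyclic(A2) || amat_key(A2) %in% tabu) next
        delta <- ls_fun(nodes[j], A2) - node_scores[j]
      } else if (A[i, j] == 1L) {
        # deletion
        A2 <- A; A2[i, j] <- 0L
        if (!(amat_key(A2) %in% tabu)) {
          delta <- ls_fun(nodes[j], A2) - node_scores[j]
          if (delta > best_delta + 1e-12) {
            best_delta <- delta; best_move <- A2
          }
        }
        # reversal
        A2 <- A; A2[i, j] <- 0L; A2[j, i] <- 1L
        if (!amat_is_acyclic(A2) || amat_key(A2) %in% tabu) next
        delta <- (ls_fun(nodes[j], A2) - node_scores[j]) +
          (ls_fun(nodes[i], A2) - node_scores[i])
      } else next
      if (delta > best_delta + 1e-12) {
        best_delta <- delta; best_move <- A2
      }
    }
    if (is.null(best_move)) break
    A <- best_move
    node_scores <- vapply(nodes, function(v) ls_fun(v, A), numeric(1))
    cur_score <- sum(node_scores)
    tabu <- c(tabu, amat_key(A))
    if (length(tabu) > tabu_length) tabu <- tabu[-1]
    if (cur_score > best_score + 1e-12) {
      best_score <- cur_score; best_A <- A; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > tabu_length) break
    }
  }
  arcs <- which(best_A == 1L, arr.ind = TRUE)
  bn_dag(nodes, data.frame(from = nodes[arcs[, 1]], to = nodes[arcs[, 2]]))
}

# ---- bootstrap averaging ----------------------------------------------------

#' Learner factories for the six study settings
#'
#' Convenience constructors returning a `function(data) -> bn_dag` for use
#' with [bootstrap_average()]: the Grow-Shrink algorithm under one of four
#' conditional-independence tests, or tabu search under BIC or BGe.
#'
#' @param setting one of `"gs1"` (correlation, exact t), `"gs2"`
#'   (correlation, permutation), `"gs3"` (mutual information, chi-squared),
#'   `"gs4"` (mutual information, permutation), `"tabu1"` (BIC),
#'   `"tabu2"` (BGe).
#' @param alpha significance level for the constraint-based settings.
#' @param n_permutations Monte Carlo permutations for permutation tests.
#' @param seed seed for permutation draws.
#' @return a learner function.
#' @export
learner_setting <- function(setting = c("gs1", "gs2", "gs3", "gs4", "tabu1", "tabu2"),
                            alpha = 0.01, n_permutations = 450, seed = 1) {
  setting <- match.arg(setting)
  stat <- switch(setting,
                 gs1 = "pearson_exact_t", gs2 = "pearson_permutation",
                 gs3 = "mutual_information_chi2",
                 gs4 = "mutual_information_permutation", NA)
  if (startsWith(setting, "gs")) {
    cfg <- ci_test_config(stat, alpha = alpha, n_permutations = n_permutations,
                          seed = seed)
    function(data) grow_shrink(data, cfg)
  } else {
    sc <- if (setting == "tabu1") "bic" else "bge"
    function(data) tabu_search(data, score = sc, seed = seed)
  }
}

#' Bootstrap model averaging of learned networks
#'
#' Resamples genotypes (rows, jointly across all columns) with replacement,
#' learns a structure per replicate, and accumulates for every unordered
#' pair the edge strength (fraction of replicate networks containing the
#' edge in either direction) and per-orientation direction fractions
#' (undirected edges contribute one half to each orientation). The
#' inclusion threshold is estimated from the strength distribution by the
#' L1-minimizing step-function fit to its empirical CDF; the averaged
#' network keeps edges above the threshold, oriented by majority direction
#' (exact ties broken toward the earlier node in canonical order), and any
#' directed cycle produced by majority orientation is broken by removing
#' the weakest-strength arc in the cycle.
#'
#' @param data n x d data frame or matrix with named columns.
#' @param learner function mapping a data subset to a `bn_dag` (see
#'   [learner_setting()]).
#' @param B number of bootstrap replicates.
#' @param seed integer seed for the resampling.
#' @return list of class `bn_strength` with elements `strengths` (tibble:
#'   `from`, `to`, `strength`, `direction`), `threshold`, `B`,
#'   `n_failed`, and `averaged` (the averaged `bn_dag`).
#' @export
bootstrap_average <- function(data, learner, B = 500, seed = 1) {
  stopifnot(B >= 1)
  data <- as.data.frame(data)
  nodes <- colnames(data)
  n <- nrow(data)
  pairs <- if (length(nodes) >= 2) utils::combn(nodes, 2) else
    matrix(character(0), 2, 0)
  m <- ncol(pairs)
  present <- numeric(m)
  dir_fwd <- numeric(m)   # pairs[1, ] -> pairs[2, ]
  dir_bwd <- numeric(m)
  key <- pair_key(pairs[1, ], pairs[2, ])
  seeds <- derive_seeds(seed, B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    g <- tryCatch(learner(data[idx, , drop = FALSE]), error = function(e) NULL)
    if (is.null(g)) { n_failed <- n_failed + 1L; next }
    if (nrow(g$arcs)) {
      ik <- match(pair_key(g$arcs$from, g$arcs$to), key)
      present[ik] <- present[ik] + 1
      fwd <- g$arcs$from == pairs[1, ik]
      dir_fwd[ik[fwd]] <- dir_fwd[ik[fwd]] + 1
      dir_bwd[ik[!fwd]] <- dir_bwd[ik[!fwd]] + 1
    }
    if (nrow(g$undirected)) {
      ik <- match(pair_key(g$undirected$from, g$undirected$to), key)
      present[ik] <- present[ik] + 1
      dir_fwd[ik] <- dir_fwd[ik] + 0.5
      dir_bwd[ik] <- dir_bwd[ik] + 0.5
    }
  }
  B_ok <- B - n_failed
  if (n_failed > 0.1 * B) {
    stop(sprintf("structure learning failed on %d of %d bootstrap replicates", n_failed, B))
  }
  strength <- present / B_ok
  frac_fwd <- ifelse(present > 0, dir_fwd / present, 0)
  frac_bwd <- ifelse(present > 0, dir_bwd / present, 0)
  strengths <- tibble::tibble(
    from = c(pairs[1, ], pairs[2, ]),
    to = c(pairs[2, ], pairs[1, ]),
    strength = rep(strength, 2),
    direction = c(frac_fwd, frac_bwd))
  threshold <- strength_threshold(strength)
  sig <- strength > threshold
  if (!any(sig) && any(strength == 1)) sig <- strength == 1
  from <- to <- character(0); arc_strength <- numeric(0)
  for (i in which(sig)) {
    fwd <- frac_fwd[i] > frac_bwd[i] ||
      (frac_fwd[i] == frac_bwd[i])   # tie: earlier node (pairs[1, ]) as parent
    from <- c(from, if (fwd) pairs[1, i] else pairs[2, i])
    to <- c(to, if (fwd) pairs[2, i] else pairs[1, i])
    arc_strength <- c(arc_strength, strength[i])
  }
  averaged <- break_cycles(nodes, from, to, arc_strength)
  structure(list(strengths = strengths, threshold = threshold, B = B,
                 n_failed = n_failed, averaged = averaged, nodes = nodes),
            class = "bn_strength")
}

#' @export
print.bn_strength <- function(x, ...) {
  cat(sprintf("<bn_strength> B = %d (failed %d), threshold = %.3f\n",
              x$B, x$n_failed, x$threshold))
  print(x$averaged)
  invisible(x)
}

# Arc-strength significance threshold (Scutari-Nagarajan style): the
# empirical CDF of strengths is approximated in L1 by the CDF of an ideal
# distribution putting mass only on 0 and 1; the estimated noise fraction
# t-hat is the Lebesgue median of the empirical CDF on [0, 1), and the
# threshold is the type-1 quantile of the strengths at t-hat.
strength_threshold <- function(strength) {
  s <- sort(strength)
  u <- unique(s)
  Fu <- stats::ecdf(s)(u)
  # piecewise-constant F on [0, 1): value 0 before the smallest strength
  breaks <- c(0, u[u < 1], 1)
  vals <- c(0, Fu[u < 1])
  if (breaks[1] == breaks[2]) { breaks <- breaks[-1]; vals <- vals[-1] }
  widths <- diff(breaks)
  ord <- order(vals)
  cum <- cumsum(widths[ord])
  t_hat <- vals[ord][which(cum >= 0.5)[1]]
  as.numeric(stats::quantile(s, probs = t_hat, type = 1, names = FALSE))
}

# orient-and-repair: build a DAG from majority-oriented arcs, removing the
# weakest-strength arc inside a cycle until acyclic
break_cycles <- function(nodes, from, to, strength) {
  while (TRUE) {
    A <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    if (length(from)) A[cbind(from, to)] <- 1L
    if (amat_is_acyclic(A)) break
    # nodes remaining after sink/source stripping participate in a cycle
    B <- A
    repeat {
      drop_idx <- which(colSums(B) == 0 | rowSums(B) == 0)
      if (!length(drop_idx)) break
      B <- B[-drop_idx, -drop_idx, drop = FALSE]
    }
    cyc_nodes <- rownames(B)
    in_cycle <- from %in% cyc_nodes & to %in% cyc_nodes
    victim <- which(in_cycle)[which.min(strength[in_cycle])]
    message(sprintf("breaking cycle: removing arc %s -> %s (strength %.2f)",
                    from[victim], to[victim], strength[victim]))
    from <- from[-victim]; to <- to[-victim]; strength <- strength[-victim]
  }
  bn_dag(nodes, if (length(from)) data.frame(from = from, to = to) else NULL)
}
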