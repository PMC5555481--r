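# Directed-acyclic-graph plumbing for Gaussian Bayesian networks:
# a light arc-list representation, acyclicity and orientation machinery,
# Markov-equivalence utilities, and translation to SEM structure matrices.

#' Construct a Bayesian-network structure
#'
#' A partially directed graph over trait labels: a set of directed arcs and
#' (optionally, for CPDAG output of constraint-based learners) undirected
#' edges. The directed part must be acyclic and no pair may be both
#' directed and undirected.
#'
#' @param nodes character vector of node labels (canonical order).
#' @param arcs two-column matrix/data frame (from, to) of directed arcs.
#' @param undirected two-column matrix/data frame of undirected edges.
#' @return object of class `bn_dag`.
#' @export
bn_dag <- function(nodes, arcs = NULL, undirected = NULL) {
  as_pairs <- function(x) {
    if (is.null(x) || NROW(x) == 0)
      return(tibble::tibble(from = character(), to = character()))
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    tibble::tibble(from = as.character(x[[1]]), to = as.character(x[[2]]))
  }
  arcs <- dplyr::distinct(as_pairs(arcs))
  undirected <- as_pairs(undirected)
  if (nrow(undirected)) {
    swap <- match(undirected$from, nodes) > match(undirected$to, nodes)
    tmp <- undirected$from[swap]
    undirected$from[swap] <- undirected$to[swap]
    undirected$to[swap] <- tmp
    undirected <- dplyr::distinct(undirected)
  }
  stopifnot(all(c(arcs$from, arcs$to, undirected$from, undirected$to) %in% nodes))
  if (any(arcs$from == arcs$to)) stop("self-loops are not allowed")
  both <- intersect(pair_key(arcs$from, arcs$to), pair_key(undirected$from, undirected$to))
  if (length(both)) stop("an edge cannot be both directed and undirected")
  g <- structure(list(nodes = nodes, arcs = arcs, undirected = undirected),
                 class = "bn_dag")
  if (!is_acyclic(g)) stop("directed part of the graph contains a cycle")
  g
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")

#' @export
print.bn_dag <- function(x, ...) {
  cat(sprintf("<bn_dag> %d nodes, %d directed arcs, %d undirected edges\n",
              length(x$nodes), nrow(x$arcs), nrow(x$undirected)))
  if (nrow(x$arcs)) cat("  ", paste(x$arcs$from, "->", x$arcs$to, collapse = ", "), "\n")
  if (nrow(x$undirected)) cat("  ", paste(x$undirected$from, "--", x$undirected$to, collapse = ", "), "\n")
  invisible(x)
}

# adjacency matrix of the directed part (amat[i, j] = 1 for i -> j)
dag_amat <- function(g) {
  d <- length(g$nodes)
  A <- matrix(0L, d, d, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$arcs)) A[cbind(g$arcs$from, g$arcs$to)] <- 1L
  A
}

amat_is_acyclic <- function(A) {
  # repeated elimination of sink-free nodes (Kahn)
  repeat {
    if (nrow(A) == 0) return(TRUE)
    deg <- colSums(A)
    src <- which(deg == 0)
    if (!length(src)) return(FALSE)
    A <- A[-src, -src, drop = FALSE]
  }
}

#' Is the directed part of a graph acyclic?
#' @param g a `bn_dag`.
#' @return logical.
#' @export
is_acyclic <- function(g) amat_is_acyclic(dag_amat(g))

# topological order of a DAG (parents before children); error with the
# offending cycle if one exists
topo_order <- function(g) {
  A <- dag_amat(g)
  nodes <- g$nodes
  order <- character(0)
  while (length(nodes)) {
    deg <- colSums(A)
    src <- names(which(deg == 0))
    if (!length(src)) {
      stop("graph contains a cycle among: ", paste(nodes, collapse = ", "))
    }
    take <- src[1]
    order <- c(order, take)
    keep <- setdiff(nodes, take)
    A <- A[keep, keep, drop = FALSE]
    nodes <- keep
  }
  order
}

# parents of each node as a named list (directed arcs only)
dag_parents <- function(g) {
  stats::setNames(lapply(g$nodes, function(v) g$arcs$from[g$arcs$to == v]), g$nodes)
}

# unordered skeleton edges (directed + undirected) as a sorted key vector
skeleton_key <- function(g) {
  sort(unique(c(pair_key(g$arcs$from, g$arcs$to),
                pair_key(g$undirected$from, g$undirected$to))))
}

# v-structures a -> c <- b with a, b non-adjacent, as sorted "a|b -> c" keys
v_structure_key <- function(g) {
  A <- dag_amat(g)
  und <- matrix(0L, nrow(A), ncol(A), dimnames = dimnames(A))
  if (nrow(g$undirected)) {
    und[cbind(g$undirected$from, g$undirected$to)] <- 1L
    und[cbind(g$undirected$to, g$undirected$from)] <- 1L
  }
  adj <- (A + t(A) + und) > 0
  out <- character(0)
  for (child in g$nodes) {
    pa <- g$nodes[A[, child] == 1L]
    if (length(pa) < 2) next
    cmb <- utils::combn(sort(pa), 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      if (!adj[a, b]) out <- c(out, paste0(a, "|", b, "->", child))
    }
  }
  sort(out)
}

#' Canonical key of a structure's Markov-equivalence class
#'
#' Two DAGs are Markov equivalent iff they share skeleton and v-structures;
#' the key concatenates both, so equal keys identify one equivalence class.
#'
#' @param g a `bn_dag`.
#' @return character scalar.
#' @export
cpdag_key <- function(g) {
  paste(c("S:", skeleton_key(g), "V:", v_structure_key(g)), collapse = ";")
}

# Meek orientation rules 1-3 applied to a partially directed graph until
# fixpoint; orientations never create cycles or new v-structures.
meek_orient <- function(g) {
  repeat {
    changed <- FALSE
    A <- dag_amat(g)
    U <- g$undirected
    if (!nrow(U)) break
    adj <- function(a, b) {
      any(g$arcs$from == a & g$arcs$to == b) ||
        any(g$arcs$from == b & g$arcs$to == a) ||
        pair_key(a, b) %in% pair_key(U$from, U$to)
    }
    orient <- function(a, b) {
      # a -- b becomes a -> b
      keep <- pair_key(U$from, U$to) != pair_key(a, b)
      g$undirected <<- U[keep, , drop = FALSE]
      g$arcs <<- dplyr::bind_rows(g$arcs, tibble::tibble(from = a, to = b))
      changed <<- TRUE
    }
    for (i in seq_len(nrow(U))) {
      a <- U$from[i]; b <- U$to[i]
      for (pair in list(c(a, b), c(b, a))) {
        x <- pair[1]; y <- pair[2]   # candidate x -> y
        # R1: exists z -> x with z, y non-adjacent
        z1 <- g$arcs$from[g$arcs$to == x]
        if (any(vapply(z1, function(z) z != y && !adj(z, y), logical(1)))) {
          orient(x, y); break
        }
        # R2: exists directed path x -> z -> y
        z2 <- intersect(g$arcs$to[g$arcs$from == x], g$arcs$from[g$arcs$to == y])
        if (length(setdiff(z2, c(x, y)))) { orient(x, y); break }
        # R3: x -- z1, x -- z2, z1 -> y, z2 -> y, z1 z2 non-adjacent
        nb_un <- c(U$to[U$from == x], U$from[U$to == x])
        zin <- intersect(nb_un, g$arcs$from[g$arcs$to == y])
        if (length(zin) >= 2) {
          cmb <- utils::combn(zin, 2)
          hit <- any(vapply(seq_len(ncol(cmb)), function(j)
            !adj(cmb[1, j], cmb[2, j]), logical(1)))
          if (hit) { orient(x, y); break }
        }
      }
      if (changed) break
    }
    if (!changed) break
  }
  g
}

#' Enumerate all DAGs over a node set
#'
#' Every pair of nodes is in state none / forward / backward; the 3^(d(d-1)/2)
#' digraphs are filtered for acyclicity. Intended for exhaustive-search
#' oracles at d <= 4 (543 DAGs on 4 nodes).
#'
#' @param nodes character vector of labels.
#' @return list of `bn_dag` objects.
#' @export
enumerate_dags <- function(nodes) {
  d <- length(nodes)
  if (d < 1) stop("need at least one node")
  pairs <- if (d >= 2) utils::combn(nodes, 2) else matrix(character(0), 2, 0)
  np <- ncol(pairs)
  states <- expand.grid(rep(list(0:2), np))
  out <- vector("list", nrow(states))
  kept <- 0L
  for (i in seq_len(nrow(states))) {
    st <- as.integer(states[i, ])
    from <- character(0); to <- character(0)
    for (j in seq_len(np)) {
      if (st[j] == 1L) { from <- c(from, pairs[1, j]); to <- c(to, pairs[2, j]) }
      if (st[j] == 2L) { from <- c(from, pairs[2, j]); to <- c(to, pairs[1, j]) }
    }
    A <- matrix(0L, d, d, dimnames = list(nodes, nodes))
    if (length(from)) A[cbind(from, to)] <- 1L
    if (amat_is_acyclic(A)) {
      kept <- kept + 1L
      out[[kept]] <- bn_dag(nodes, data.frame(from = from, to = to))
    }
  }
  out[seq_len(kept)]
}

# all consistent extensions of a partially directed bn_dag: orientations of
# its undirected edges that create neither cycles nor new v-structures
consistent_extensions <- function(g) {
  U <- g$undirected
  if (!nrow(U)) return(list(g))
  vkey <- v_structure_key(g)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), nrow(U)))
  out <- list()
  for (i in seq_len(nrow(combos))) {
    fl <- as.logical(combos[i, ])
    from <- ifelse(fl, U$to, U$from)
    to <- ifelse(fl, U$from, U$to)
    cand <- tryCatch(
      bn_dag(g$nodes, rbind(as.data.frame(g$arcs), data.frame(from = from, to = to))),
      error = function(e) NULL)
    if (!is.null(cand) && identical(v_structure_key(cand), vkey)) {
      out <- c(out, list(cand))
    }
  }
  out
}

# deterministic equivalence-class representative: the consistent extension
# whose sorted "from->to" arc list is first in lexicographic order
class_representative <- function(g) {
  ext <- consistent_extensions(g)
  if (!length(ext)) stop("graph admits no consistent extension")
  keys <- vapply(ext, function(x) {
    paste(sort(paste(x$arcs$from, x$arcs$to, sep = "->")), collapse = ";")
  }, character(1))
  ext[[order(keys)[1]]]
}

#' Translate a learned DAG into an SEM structure matrix
#'
#' Each arc parent -> child becomes a freely varying coefficient at the
#' (child, parent) position of a d x d matrix whose remaining entries are
#' structural zeros. A node permutation making the pattern strictly lower
#' triangular always exists because the graph is acyclic. Undirected edges
#' (a CPDAG result) are first resolved to the lexicographically first
#' consistent extension of the equivalence class; representatives of one
#' class share fit and likelihood, so the choice does not affect ranking.
#'
#' @param dag a `bn_dag` (directed, or a CPDAG).
#' @return object of class `structure_matrix`: list with `pattern` (d x d
#'   logical, rows = children, columns = parents, in the original node
#'   order), `node_order` (permutation under which the pattern is strictly
#'   lower triangular), `nodes`, and `arcs`.
#' @export
to_structure_matrix <- function(dag) {
  g <- class_representative(dag)
  ord <- topo_order(g)
  d <- length(g$nodes)
  pattern <- matrix(FALSE, d, d, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$arcs)) pattern[cbind(g$arcs$to, g$arcs$from)] <- TRUE
  structure(list(pattern = pattern, node_order = ord, nodes = g$nodes,
                 arcs = g$arcs),
            class = "structure_matrix")
}

#' @export
print.structure_matrix <- function(x, ...) {
  cat(sprintf("<structure_matrix> %d free coefficients over %d traits (order: %s)\n",
              sum(x$pattern), length(x$nodes), paste(x$node_order, collapse = " < ")))
  invisible(x)
}

#' Unstructured (fully recursive) structure over a set of traits
#'
#' Free coefficient at every (child, parent) pair below the diagonal in the
#' given order: the saturated recursive system whose reconstructed
#' covariance is unrestricted.
#'
#' @param nodes trait labels.
#' @return a `structure_matrix`.
#' @export
fully_recursive_structure <- function(nodes) {
  d <- length(nodes)
  arcs <- NULL
  if (d >= 2) {
    idx <- which(lower.tri(matrix(0, d, d)), arr.ind = TRUE)
    arcs <- data.frame(from = nodes[idx[, 2]], to = nodes[idx[, 1]])
  }
  to_structure_matrix(bn_dag(nodes, arcs))
}

#' Empty structure (diagonal covariance) over a set of traits
#' @param nodes trait labels.
#' @return a `structure_matrix` with no free coefficients.
#' @export
empty_structure <- function(nodes) to_structure_matrix(bn_dag(nodes))
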