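# Synthetic doubled-haploid panels with known genomic and residual network
# truths: marker matrices, simple-matching kinship, and multi-trait panels
# whose components obey user-specified sparse recursive structures.

#' Simulate doubled-haploid marker matrices with family structure
#'
#' Lines are organized in families; each family draws its own allele
#' frequency per marker from a Beta(2, 2) distribution, and line genotypes
#' are then Bernoulli draws within family. This creates the block-structured
#' kinship typical of multi-family DH panels without modeling meiosis.
#' Genotypes are coded `{0, 2}` because DH lines are fully homozygous.
#' Markers that are monomorphic across the panel are dropped.
#'
#' @param n_lines number of lines.
#' @param n_markers number of markers simulated (before the polymorphism
#'   filter).
#' @param n_families number of families; lines are split as evenly as
#'   possible.
#' @param seed integer seed.
#' @param beta_shape two shape parameters of the family allele-frequency
#'   distribution.
#' @return an object of class `marker_matrix`: list with `values`
#'   (n_lines x n_kept integer matrix coded 0/2, line ids as rownames),
#'   `line_ids`, `family_ids`.
#' @export
simulate_markers <- function(n_lines, n_markers, n_families, seed,
                             beta_shape = c(2, 2)) {
  stopifnot(n_lines >= 1, n_markers >= 1, n_families >= 1, n_families <= n_lines)
  set.seed(as.integer(seed))
  family_ids <- sort(rep_len(sprintf("F%02d", seq_len(n_families)), n_lines))
  line_ids <- sprintf("L%04d", seq_len(n_lines))
  # family-specific allele frequencies, one row per family
  p <- matrix(stats::rbeta(n_families * n_markers, beta_shape[1], beta_shape[2]),
              nrow = n_families)
  fam_index <- as.integer(factor(family_ids))
  values <- matrix(0L, n_lines, n_markers)
  for (f in seq_len(n_families)) {
    rows <- which(fam_index == f)
    values[rows, ] <- 2L * matrix(
      stats::rbinom(length(rows) * n_markers, 1L, rep(p[f, ], each = length(rows))),
      nrow = length(rows))
  }
  poly <- apply(values, 2, function(g) length(unique(g)) > 1L)
  if (mean(!poly) > 0.5) {
    stop(sprintf(paste0("more than 50%% of simulated markers were monomorphic ",
                        "(%d of %d); revisit the Beta(%g, %g) allele-frequency settings"),
                 sum(!poly), n_markers, beta_shape[1], beta_shape[2]))
  }
  if (!any(poly)) stop("all simulated markers were monomorphic")
  values <- values[, poly, drop = FALSE]
  rownames(values) <- line_ids
  colnames(values) <- sprintf("M%05d", which(poly))
  structure(list(values = values, line_ids = line_ids, family_ids = family_ids),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("<marker_matrix> %d lines x %d polymorphic markers, %d families\n",
              nrow(x$values), ncol(x$values), length(unique(x$family_ids))))
  invisible(x)
}

#' Realized kinship from simple matching coefficients
#'
#' `K[i, j]` is the proportion of markers at which lines i and j carry the
#' same genotype code. For homozygous DH lines coded `{0, 2}` this is the
#' simple matching coefficient; the diagonal is exactly 1. Raw proportion
#' matching is used without any affine rescaling (a rescaling of K only
#' rescales genomic variance estimates).
#'
#' @param markers a [simulate_markers()] result, or a 0/2 coded matrix.
#' @return an n x n matrix with line ids as dimnames, class `kinship_matrix`.
#' @export
kinship_from_markers <- function(markers) {
  values <- if (inherits(markers, "marker_matrix")) markers$values else as.matrix(markers)
  if (ncol(values) < 2) stop("at least 2 polymorphic markers are required")
  X <- values / 2                       # 0/1 coding
  m <- ncol(X)
  K <- (tcrossprod(X) + tcrossprod(1 - X)) / m
  dimnames(K) <- list(rownames(values), rownames(values))
  class(K) <- c("kinship_matrix", class(K))
  K
}

#' Define a synthetic network truth
#'
#' Holds the strictly-lower-triangular genomic and residual structure
#' matrices, diagonal innovation variances, and trait intercepts that
#' generate a panel, together with the implied covariance matrices
#' `(I - Lambda)^-1 Psi (I - Lambda)^-T`.
#'
#' @param lambda_u,lambda_e d x d strictly-lower-triangular structure
#'   matrices of the genomic and residual components.
#' @param psi_u,psi_e length-d positive innovation variances.
#' @param mu length-d trait intercepts (default 0).
#' @param trait_names optional trait labels.
#' @return object of class `synthetic_truth` with elements `lambda_u`,
#'   `lambda_e`, `psi_u`, `psi_e`, `mu`, `implied_G`, `implied_R`, `d`,
#'   `trait_names`.
#' @export
synthetic_truth <- function(lambda_u, lambda_e, psi_u, psi_e, mu = NULL,
                            trait_names = NULL) {
  lambda_u <- as.matrix(lambda_u); lambda_e <- as.matrix(lambda_e)
  d <- nrow(lambda_u)
  stopifnot(ncol(lambda_u) == d, all(dim(lambda_e) == d),
            length(psi_u) == d, length(psi_e) == d,
            all(psi_u > 0), all(psi_e > 0))
  if (any(lambda_u[upper.tri(lambda_u, diag = TRUE)] != 0) ||
      any(lambda_e[upper.tri(lambda_e, diag = TRUE)] != 0)) {
    stop("structure matrices must be strictly lower triangular")
  }
  mu <- mu %||% rep(0, d)
  trait_names <- trait_names %||% sprintf("T%d", seq_len(d))
  structure(list(
    lambda_u = lambda_u, lambda_e = lambda_e,
    psi_u = as.numeric(psi_u), psi_e = as.numeric(psi_e),
    mu = as.numeric(mu), d = d, trait_names = trait_names,
    implied_G = reconstruct_covariance(lambda_u, psi_u),
    implied_R = reconstruct_covariance(lambda_e, psi_e)
  ), class = "synthetic_truth")
}

#' Default sparse five-trait truth emulating a DH study panel
#'
#' Five standardized traits with a sparse recursive genomic structure
#' (4 arcs) and a sparser residual structure (3 arcs); innovation variances
#' 0.5, matching the prior mode used by the samplers. Coefficients are in
#' the range that reproduces the moderate-to-strong between-trait
#' correlations seen in multi-family DH panels.
#'
#' @return a [synthetic_truth()] object with d = 5.
#' @export
default_truth <- function() {
  d <- 5
  lu <- matrix(0, d, d)
  # genomic arcs (child, parent): T1 -> T2, T2 -> T3, T3 -> T5, T1 -> T4
  lu[2, 1] <- 0.9; lu[3, 2] <- 0.7; lu[5, 3] <- 0.8; lu[4, 1] <- -0.7
  le <- matrix(0, d, d)
  # residual arcs: T1 -> T2, T2 -> T3, T3 -> T5
  le[2, 1] <- 0.65; le[3, 2] <- 0.5; le[5, 3] <- 0.45
  synthetic_truth(lu, le, psi_u = rep(0.5, d), psi_e = rep(0.5, d))
}

#' Simulate a multi-trait panel from a known truth
#'
#' Draws genomic innovations with variances `psi_u`, propagates them through
#' `(I - lambda_u)^-1` and correlates genotypes through the Cholesky factor
#' of the kinship matrix; residual innovations are propagated through
#' `(I - lambda_e)^-1` with independent genotypes. Phenotypes are
#' `y = mu + u + e`. The true components are stored alongside `y` for
#' recovery testing.
#'
#' @param truth a [synthetic_truth()] object.
#' @param kinship n x n kinship matrix (positive definite after ridge
#'   repair).
#' @param n number of genotypes; must equal `nrow(kinship)`.
#' @param seed integer seed, expanded into independent substreams for the
#'   genomic and residual draws.
#' @param family_ids optional family labels (taken from kinship rownames'
#'   attribute or "F01" otherwise).
#' @return a `trait_panel`: tibble with `genotype_id`, `family_id` and one
#'   column per trait, plus attributes `U` and `E` (true components),
#'   `truth`, and `standardized = FALSE`.
#' @export
simulate_panel <- function(truth, kinship, n = nrow(kinship), seed = 1,
                           family_ids = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  kinship <- unclass(kinship)
  if (n != nrow(kinship)) stop("n must equal nrow(kinship)")
  rep_k <- repair_pd(kinship, label = "kinship")
  Lk <- t(rep_k$chol)                    # lower-triangular factor
  d <- truth$d
  seeds <- derive_seeds(seed, 2)
  Au <- solve(diag(d) - truth$lambda_u)  # (I - Lambda_U)^-1
  Ae <- solve(diag(d) - truth$lambda_e)
  set.seed(seeds[1])
  Pu <- matrix(stats::rnorm(n * d, sd = rep(sqrt(truth$psi_u), each = n)), n, d)
  Ustar <- Pu %*% t(Au)
  U <- Lk %*% Ustar
  set.seed(seeds[2])
  Pe <- matrix(stats::rnorm(n * d, sd = rep(sqrt(truth$psi_e), each = n)), n, d)
  E <- Pe %*% t(Ae)
  Y <- sweep(U + E, 2, truth$mu, "+")
  colnames(Y) <- colnames(U) <- colnames(E) <- truth$trait_names
  genotype_id <- rownames(kinship) %||% sprintf("L%04d", seq_len(n))
  family_id <- family_ids %||% rep("F01", n)
  panel <- tibble::tibble(genotype_id = genotype_id, family_id = family_id)
  panel <- dplyr::bind_cols(panel, tibble::as_tibble(Y))
  attr(panel, "U") <- U
  attr(panel, "E") <- E
  attr(panel, "truth") <- truth
  attr(panel, "standardized") <- FALSE
  class(panel) <- c("trait_panel", class(panel))
  panel
}

#' Trait columns of a panel
#' @param panel a trait panel tibble.
#' @return character vector of trait column names.
#' @export
trait_names <- function(panel) {
  setdiff(names(panel), c("genotype_id", "family_id"))
}

#' Trait values of a panel as a numeric matrix
#' @param panel a trait panel tibble.
#' @return n x d numeric matrix with genotype ids as rownames.
#' @export
trait_matrix <- function(panel) {
  Y <- as.matrix(panel[trait_names(panel)])
  rownames(Y) <- panel$genotype_id
  Y
}

#' Standardize a trait panel
#'
#' Centers every trait on its family mean (allelic rather than population
#' effects), then divides by the overall sample standard deviation so each
#' column has unit sample variance. Idempotent.
#'
#' @param panel a trait panel tibble with `family_id`.
#' @return the standardized panel (attribute `standardized = TRUE`).
#' @export
standardize_panel <- function(panel) {
  traits <- trait_names(panel)
  out <- panel |>
    dplyr::group_by(.data$family_id) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(traits), ~ .x - mean(.x))) |>
    dplyr::ungroup() |>
    dplyr::mutate(dplyr::across(dplyr::all_of(traits), ~ .x / stats::sd(.x)))
  for (a in c("U", "E", "truth")) attr(out, a) <- attr(panel, a)
  attr(out, "standardized") <- TRUE
  class(out) <- unique(c("trait_panel", class(out)))
  out
}

#' Write / read panels, kinship matrices, and truths
#'
#' Panels are CSV with header `genotype_id, family_id, <traits>`; kinship is
#' a square CSV with genotype ids as both header and first column; truths
#' are YAML.
#'
#' @param panel,kinship,truth objects to write.
#' @param path file path.
#' @name panel_io
NULL

#' @rdname panel_io
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(panel)), path)
  invisible(path)
}

#' @rdname panel_io
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("genotype_id", "family_id") %in% names(panel)))
  attr(panel, "standardized") <- FALSE
  class(panel) <- c("trait_panel", class(panel))
  panel
}

#' @rdname panel_io
#' @export
write_kinship <- function(kinship, path) {
  K <- unclass(kinship)
  ids <- rownames(K) %||% sprintf("L%04d", seq_len(nrow(K)))
  df <- tibble::tibble(genotype_id = ids)
  df <- dplyr::bind_cols(df, tibble::as_tibble(K, .name_repair = ~ids))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname panel_io
#' @export
read_kinship <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  K <- as.matrix(df[, -1])
  rownames(K) <- df[[1]]
  class(K) <- c("kinship_matrix", class(K))
  K
}

#' @rdname panel_io
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(list(
    trait_names = truth$trait_names,
    lambda_u = apply(truth$lambda_u, 1, as.numeric, simplify = FALSE),
    lambda_e = apply(truth$lambda_e, 1, as.numeric, simplify = FALSE),
    psi_u = truth$psi_u, psi_e = truth$psi_e, mu = truth$mu
  ), path)
  invisible(path)
}

#' @rdname panel_io
#' @export
read_truth <- function(path) {
  y <- yaml::read_yaml(path)
  synthetic_truth(
    do.call(rbind, y$lambda_u), do.call(rbind, y$lambda_e),
    psi_u = unlist(y$psi_u), psi_e = unlist(y$psi_e),
    mu = unlist(y$mu), trait_names = unlist(y$trait_names))
}
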