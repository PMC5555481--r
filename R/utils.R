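# Internal numerical helpers shared across modules.

#' Repair a covariance/kinship matrix to positive definiteness
#'
#' Adds a ridge `delta * I`, doubling `delta` from `ridge_start` until the
#' Cholesky factorization succeeds or `ridge_cap` is exceeded.
#'
#' @param K symmetric matrix.
#' @param ridge_start initial ridge (default `1e-8`).
#' @param ridge_cap largest ridge attempted before giving up.
#' @param label name used in messages.
#' @return list with `matrix` (repaired), `ridge` (0 when no repair was
#'   needed) and `chol` (upper-triangular Cholesky factor of the repaired
#'   matrix).
#' @keywords internal
repair_pd <- function(K, ridge_start = 1e-8, ridge_cap = 1e-2, label = "matrix") {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (max(abs(K - t(K))) > 1e-8) {
    stop(label, " is not symmetric")
  }
  K <- (K + t(K)) / 2
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (!is.null(ch)) {
    return(list(matrix = K, ridge = 0, chol = ch))
  }
  delta <- ridge_start
  while (delta <= ridge_cap) {
    Kr <- K + diag(delta, nrow(K))
    ch <- tryCatch(chol(Kr), error = function(e) NULL)
    if (!is.null(ch)) {
      message(sprintf("%s repaired to positive definiteness with ridge %.3g", label, delta))
      return(list(matrix = Kr, ridge = delta, chol = ch))
    }
    delta <- delta * 2
  }
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  stop(sprintf("%s could not be repaired below ridge cap %.3g (minimum eigenvalue %.3g)",
               label, ridge_cap, ev))
}

#' Draw from an inverse-Wishart distribution
#'
#' Parametrized so the density is proportional to
#' `|W|^-((nu + d + 1)/2) * exp(-tr(Sigma W^-1)/2)`, with mode
#' `Sigma / (nu + d + 1)`. Equivalently `W^-1 ~ Wishart(nu, Sigma^-1)`.
#'
#' @param nu degrees of freedom, must exceed `d - 1`.
#' @param Sigma d x d positive-definite scale matrix.
#' @return a d x d matrix draw.
#' @keywords internal
riwish <- function(nu, Sigma) {
  d <- nrow(Sigma)
  stopifnot(nu > d - 1)
  W <- stats::rWishart(1, df = nu, Sigma = chol2inv(chol(Sigma)))[, , 1]
  Winv <- chol2inv(chol(W))
  (Winv + t(Winv)) / 2
}

# Scaled-inverse-chi-square draw under the d = 1 inverse-Wishart convention:
# density proportional to psi^-((nu + 2)/2) exp(-scale / (2 psi)), i.e.
# psi = scale / chi^2_nu, with mode scale / (nu + 2).
rscinvchisq <- function(n, nu, scale) {
  scale / stats::rchisq(n, df = nu)
}

#' Expand a master seed into per-stage substreams
#'
#' Deterministically derives `n` independent integer seeds (all below 2^31)
#' from one master seed so that pipeline stages are independently
#' reproducible.
#'
#' @param master integer master seed.
#' @param n number of substream seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(length(master) == 1, is.finite(master))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Batch-means Monte-Carlo standard error of the mean of a (possibly
# autocorrelated) chain of draws.
mcse_batch <- function(x, n_batches = 25) {
  x <- as.numeric(x)
  n <- length(x)
  b <- max(2L, floor(n / n_batches))
  m <- floor(n / b)
  if (m < 2) return(stats::sd(x) / sqrt(n))
  means <- vapply(seq_len(m), function(i) mean(x[((i - 1) * b + 1):(i * b)]), numeric(1))
  stats::sd(means) / sqrt(m)
}

# log of the multivariate gamma function Gamma_d(a)
lmvgamma <- function(a, d) {
  d * (d - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
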