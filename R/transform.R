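# Decorrelation of the genomic component across genotypes via the Cholesky
# factor of the kinship matrix, preserving the between-trait covariance G.

#' Cholesky factor of a kinship matrix
#'
#' Returns the lower-triangular factor `L` with `K = L L'` after ridge
#' repair if the matrix is not positive definite (ridge doubling from
#' `1e-8`; the ridge actually used is recorded, 0 when none was needed).
#'
#' @param kinship symmetric n x n kinship matrix.
#' @param ridge_start,ridge_cap repair policy.
#' @return object of class `cholesky_transform`: list with `L`
#'   (lower-triangular), `ridge_used`, `n`.
#' @export
cholesky_factor <- function(kinship, ridge_start = 1e-8, ridge_cap = 1e-2) {
  rep_k <- repair_pd(unclass(kinship), ridge_start = ridge_start,
                     ridge_cap = ridge_cap, label = "kinship")
  structure(list(L = t(rep_k$chol), ridge_used = rep_k$ridge,
                 n = nrow(rep_k$matrix)),
            class = "cholesky_transform")
}

#' Decorrelate genomic values across genotypes
#'
#' Applies `u* = (I (x) L^-1) u` column by column: each trait column of `U`
#' is replaced by the forward-substitution solution of `L x = column`. The
#' transformed rows are independent across genotypes while the
#' between-trait covariance G is preserved; the residual component needs no
#' transformation because residuals are already independent across
#' genotypes under the model.
#'
#' @param U n x d matrix of genomic values (genotypes in rows, in the order
#'   of the kinship matrix behind `transform`).
#' @param transform a [cholesky_factor()] result.
#' @return n x d matrix `U_star`.
#' @export
decorrelate <- function(U, transform) {
  U <- as.matrix(U)
  stopifnot(inherits(transform, "cholesky_transform"), nrow(U) == transform$n)
  Ustar <- forwardsolve(transform$L, U)
  dimnames(Ustar) <- dimnames(U)
  Ustar
}
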