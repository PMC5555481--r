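# Marginal and conditional independence tests for Gaussian Bayesian-network
# learning: partial correlation with an exact Student t reference, the
# Gaussian mutual-information G^2 statistic against chi^2(1), and Monte
# Carlo permutation versions of both.

#' Configure a conditional-independence test
#'
#' @param statistic one of `"pearson_exact_t"`, `"pearson_permutation"`,
#'   `"mutual_information_chi2"`, `"mutual_information_permutation"`.
#' @param alpha significance level in (0, 1); arcs are kept when the test
#'   rejects independence at this level.
#' @param n_permutations Monte Carlo permutations for the permutation
#'   variants.
#' @param seed integer seed for the permutation draws.
#' @return list of class `ci_test_config`.
#' @export
ci_test_config <- function(statistic = c("pearson_exact_t", "pearson_permutation",
                                         "mutual_information_chi2",
                                         "mutual_information_permutation"),
                           alpha = 0.01, n_permutations = 450, seed = 1) {
  statistic <- match.arg(statistic)
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 1)
  structure(list(statistic = statistic, alpha = alpha,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "ci_test_config")
}

# partial correlation of columns x and y of data matrix given columns Z,
# computed from the inverse of the correlation submatrix
partial_cor <- function(data, x, y, Z = character(0)) {
  sub <- data[, c(x, y, Z), drop = FALSE]
  if (any(apply(sub, 2, stats::sd) == 0)) {
    stop("constant column in conditional-independence test: ",
         paste(c(x, y, Z)[apply(sub, 2, stats::sd) == 0], collapse = ", "))
  }
  S <- stats::cor(sub)
  if (length(Z) == 0) return(S[1, 2])
  Om <- tryCatch(solve(S), error = function(e) MASS_ginv(S))
  -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
}

# pseudo-inverse fallback for numerically singular correlation matrices
MASS_ginv <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  pos <- e$values > tol * e$values[1]
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

ci_stat_value <- function(r, n, nz, statistic) {
  r <- max(-1, min(1, r))
  if (abs(r) >= 1 - 1e-12) return(Inf)   # collinear pair: flagged infinite
  if (startsWith(statistic, "pearson")) {
    df <- n - nz - 2
    r * sqrt(df / (1 - r^2))
  } else {
    -n * log(1 - r^2)
  }
}

#' Test (conditional) independence of two variables
#'
#' Computes the partial correlation `r` of `x` and `y` given `Z` by
#' inverting the correlation submatrix. For `pearson_exact_t` the statistic
#' is `t = r * sqrt((n - |Z| - 2) / (1 - r^2))` with `n - |Z| - 2` degrees
#' of freedom (two-sided). For `mutual_information_chi2` it is
#' `G^2 = -n * log(1 - r^2)` against chi^2 with 1 df. The permutation
#' variants permute the `x` column and report
#' `p = (1 + #(|stat_perm| >= |stat_obs|)) / (1 + n_permutations)`, so a
#' permutation p-value is never exactly zero.
#'
#' @param data n x d numeric matrix or data frame with named columns.
#' @param x,y column names of the tested pair.
#' @param Z character vector of conditioning column names (may be empty).
#' @param config a [ci_test_config()].
#' @return tibble with `statistic`, `p_value`, `r`, `df`.
#' @export
ci_test <- function(data, x, y, Z = character(0), config = ci_test_config()) {
  data <- as.matrix(as.data.frame(data))
  n <- nrow(data)
  nz <- length(Z)
  stopifnot(x != y, !(x %in% Z), !(y %in% Z))
  if (nz > n - 3) stop("conditioning set too large for the sample size")
  r <- partial_cor(data, x, y, Z)
  stat <- ci_stat_value(r, n, nz, config$statistic)
  perm <- grepl("permutation", config$statistic)
  if (!perm) {
    if (!is.finite(stat)) {
      p <- 0
    } else if (startsWith(config$statistic, "pearson")) {
      p <- 2 * stats::pt(-abs(stat), df = n - nz - 2)
    } else {
      p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    }
  } else {
    set.seed(config$seed + 1000L * nz + n)
    exceed <- 0L
    for (b in seq_len(config$n_permutations)) {
      dp <- data
      dp[, x] <- dp[sample.int(n), x]
      rp <- partial_cor(dp, x, y, Z)
      sp <- ci_stat_value(rp, n, nz, config$statistic)
      if (abs(sp) >= abs(stat)) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + config$n_permutations)
  }
  tibble::tibble(statistic = stat, p_value = p, r = r,
                 df = if (startsWith(config$statistic, "pearson")) n - nz - 2 else 1)
}
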