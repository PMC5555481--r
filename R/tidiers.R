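# broom-style tidy() and glance() methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted multivariate kinship model
#'
#' One row per free covariance entry (and intercept) with posterior mean
#' and SD across retained draws.
#'
#' @param x an `mtm_fit`.
#' @param ... unused.
#' @return tibble with `component`, `trait_1`, `trait_2`, `estimate`,
#'   `sd`.
#' @export
tidy.mtm_fit <- function(x, ...) {
  d <- x$d; traits <- x$traits
  cov_rows <- function(samples, label) {
    idx <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
    purrr::map_dfr(seq_len(nrow(idx)), function(r) {
      i <- idx[r, 1]; j <- idx[r, 2]
      tibble::tibble(component = label, trait_1 = traits[i], trait_2 = traits[j],
                     estimate = mean(samples[i, j, ]),
                     sd = stats::sd(samples[i, j, ]))
    })
  }
  mu_rows <- tibble::tibble(component = "intercept", trait_1 = traits,
                            trait_2 = NA_character_,
                            estimate = colMeans(x$mu_samples),
                            sd = apply(x$mu_samples, 2, stats::sd))
  dplyr::bind_rows(mu_rows, cov_rows(x$G_samples, "genomic"),
                   cov_rows(x$R_samples, "residual"))
}

#' Tidy a fitted structural equation model
#'
#' As [tidy.mtm_fit()], plus one row per free structure coefficient and
#' innovation variance.
#'
#' @param x an `sem_fit`.
#' @param ... unused.
#' @return tibble with `component`, `trait_1` (child), `trait_2`
#'   (parent), `estimate`, `sd`.
#' @export
tidy.sem_fit <- function(x, ...) {
  base <- tidy.mtm_fit(x, ...)
  lam_rows <- function(tbl, label) {
    if (is.null(tbl)) return(NULL)
    tibble::tibble(component = label, trait_1 = tbl$child, trait_2 = tbl$parent,
                   estimate = tbl$estimate, sd = tbl$sd)
  }
  psi_rows <- function(samples, label) {
    if (is.null(samples)) return(NULL)
    tibble::tibble(component = label, trait_1 = x$traits, trait_2 = NA_character_,
                   estimate = colMeans(samples),
                   sd = apply(samples, 2, stats::sd))
  }
  dplyr::bind_rows(base,
                   lam_rows(x$lambda_genomic, "lambda_genomic"),
                   lam_rows(x$lambda_residual, "lambda_residual"),
                   psi_rows(x$psi_g_samples, "psi_genomic"),
                   psi_rows(x$psi_r_samples, "psi_residual"))
}

#' One-row fit summary
#'
#' @param x an `mtm_fit` or `sem_fit`.
#' @param ... unused.
#' @return tibble with `model`, `n`, `d`, `n_retained`, `dic`, `p_d`,
#'   `mean_deviance`.
#' @export
glance.mtm_fit <- function(x, ...) {
  d_tbl <- compute_dic(x)
  tibble::tibble(model = x$model, n = x$n, d = x$d, n_retained = x$n_retained,
                 dic = d_tbl$dic, p_d = d_tbl$p_d,
                 mean_deviance = d_tbl$mean_deviance)
}

#' Tidy bootstrap arc strengths
#'
#' @param x a `bn_strength`.
#' @param ... unused.
#' @return the strengths tibble (`from`, `to`, `strength`, `direction`)
#'   with the estimated `threshold` attached as a column.
#' @export
tidy.bn_strength <- function(x, ...) {
  dplyr::mutate(x$strengths, threshold = x$threshold)
}

#' Tidy a cross-validation result
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return per-trait mean and SD of predictive ability by model.
#' @export
tidy.cv_result <- function(x, ...) x$ability
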