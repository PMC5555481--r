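# Model assessment: DIC and its effective-parameter penalty from posterior
# deviance draws, a plug-in Gaussian marginal log-likelihood, replicated
# cross-validated predictive ability with fold assignments shared across
# models, and the comparison table ranking MTM, SEM variants, and the
# single-trait baseline.

#' Deviance information criterion from posterior deviance draws
#'
#' `p_d = mean(deviance) - deviance_at_mean` and
#' `dic = mean(deviance) + p_d`. The deviance used throughout the package
#' is the conditional deviance `-2 log N(y | mu + u, R (x) I)` evaluated
#' per retained draw, whose effective-parameter count is of the order of
#' the dimension of u.
#'
#' @param deviance_draws numeric vector of per-iteration deviances (or an
#'   `mtm_fit`/`sem_fit`, from which draws and the plug-in deviance are
#'   taken).
#' @param deviance_at_mean deviance evaluated at the posterior means.
#' @return tibble with `dic`, `p_d`, `mean_deviance`, `deviance_at_mean`.
#' @export
compute_dic <- function(deviance_draws, deviance_at_mean = NULL) {
  if (inherits(deviance_draws, "mtm_fit")) {
    deviance_at_mean <- deviance_draws$deviance_at_mean
    deviance_draws <- deviance_draws$deviance_draws
  }
  if (length(deviance_draws) < 2) stop("need at least 2 deviance draws")
  bad <- which(!is.finite(deviance_draws))
  if (length(bad)) stop("non-finite deviance at draw ", bad[1])
  if (!is.finite(deviance_at_mean)) stop("non-finite deviance at the posterior mean")
  dbar <- mean(deviance_draws)
  p_d <- dbar - deviance_at_mean
  tibble::tibble(dic = dbar + p_d, p_d = p_d, mean_deviance = dbar,
                 deviance_at_mean = deviance_at_mean)
}

#' Plug-in marginal log-likelihood
#'
#' Evaluates the Gaussian log-density of the phenotypes under
#' `N(mu_hat (x) 1, G_hat (x) K + R_hat (x) I)` at the posterior means,
#' using the eigendecomposition of K so genotypes decouple into d x d
#' solves. This is a deterministic plug-in evaluation, not a fully
#' Bayesian evidence estimate; differences between models fitted to the
#' same data are the quantity of interest.
#'
#' @param posterior an `mtm_fit` or `sem_fit`.
#' @param panel trait panel the model was fitted to.
#' @param kinship kinship matrix used in the fit.
#' @return scalar log-likelihood.
#' @export
marginal_loglik <- function(posterior, panel, kinship) {
  Y <- trait_matrix(panel)
  n <- nrow(Y); d <- ncol(Y)
  K <- repair_pd(unclass(kinship), label = "kinship")$matrix
  eg <- eigen(K, symmetric = TRUE)
  Yc <- sweep(Y, 2, posterior$mu_hat)
  Ytil <- crossprod(eg$vectors, Yc)
  G <- posterior$G_hat; R <- posterior$R_hat
  ll <- 0
  for (i in seq_len(n)) {
    Ci <- eg$values[i] * G + R
    ch <- tryCatch(chol(Ci), error = function(e)
      stop("plug-in covariance not positive definite at genotype ", i))
    z <- forwardsolve(t(ch), Ytil[i, ])
    ll <- ll - 0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  }
  ll
}

#' Goodness-of-fit metrics for one fitted model
#'
#' @param fit an `mtm_fit` or `sem_fit`.
#' @param panel,kinship the data the model was fitted to.
#' @param label model label for comparison tables.
#' @return tibble with `model_label`, `dic`, `p_d`, `log_marginal`.
#' @export
fit_metrics <- function(fit, panel, kinship, label = fit$model) {
  d_tbl <- compute_dic(fit)
  tibble::tibble(model_label = label, dic = d_tbl$dic, p_d = d_tbl$p_d,
                 log_marginal = marginal_loglik(fit, panel, kinship))
}

# conditional multivariate-normal prediction of test phenotypes from
# training phenotypes under plug-in covariances (trait-major ordering)
predict_conditional <- function(mu, G, R, K, train, test, Y) {
  d <- length(mu)
  Ktr <- K[train, train, drop = FALSE]
  Kts <- K[test, train, drop = FALSE]
  Sig_tr <- kronecker(G, Ktr) + kronecker(R, diag(length(train)))
  C_ts <- kronecker(G, Kts)
  resid <- as.numeric(sweep(Y[train, , drop = FALSE], 2, mu))
  pred <- C_ts %*% solve(Sig_tr, resid)
  sweep(matrix(pred, ncol = d), 2, mu, "+")
}

#' Replicated cross-validated predictive ability
#'
#' Runs `replicates` independent `folds`-fold cross-validations with
#' uniform random fold assignment of genotypes; the identical fold
#' assignments are shared by every model (including the single-trait
#' baseline). Each model is refit on the training genotypes; held-out
#' genotypes are predicted by the conditional multivariate normal given
#' all training phenotypes, the plug-in posterior-mean covariances, and
#' the cross-kinship block. Predictive ability is the per-trait
#' correlation between observed and predicted values on the test sets,
#' averaged over all `replicates * folds` splits. A constant prediction
#' (no information flows to held-out genotypes, e.g. under identity
#' kinship) has undefined correlation and is scored as ability 0.
#'
#' @param panel trait panel tibble in the kinship genotype order.
#' @param kinship n x n kinship matrix.
#' @param models named list of model specifications; each element is a
#'   list with `type` one of `"mtm"`, `"single"`, `"sem"` and, for SEM,
#'   `spec` (a [sem_spec()]).
#' @param replicates,folds cross-validation design (default 10 x 5).
#' @param seed master seed; fold assignments are derived from it and are
#'   bit-identical across models and repeated calls.
#' @param mcmc chain settings used for every refit.
#' @return object of class `cv_result`: list with `folds` (tibble:
#'   replicate, genotype_id, fold), `per_split` (tibble: model, replicate,
#'   fold, trait, ability), `ability` (tibble: model, trait, mean, sd over
#'   splits), `replicates`, `folds_k`, `seed`.
#' @export
cross_validate <- function(panel, kinship, models, replicates = 10, folds = 5,
                           seed = 1, mcmc = mcmc_settings(200, 800, thin = 2)) {
  Y <- trait_matrix(panel)
  n <- nrow(Y); d <- ncol(Y)
  traits <- colnames(Y)
  if (n < folds) stop("need at least as many genotypes as folds")
  K <- repair_pd(unclass(kinship), label = "kinship")$matrix
  seeds <- derive_seeds(seed, replicates + 1)
  assignments <- purrr::map(seq_len(replicates), function(r) {
    set.seed(seeds[r])
    sample(rep_len(seq_len(folds), n))
  })
  fold_tbl <- purrr::map_dfr(seq_len(replicates), function(r) {
    tibble::tibble(replicate = r, genotype_id = panel$genotype_id,
                   fold = assignments[[r]])
  })
  per_split <- purrr::map_dfr(seq_len(replicates), function(r) {
    purrr::map_dfr(seq_len(folds), function(f) {
      test <- which(assignments[[r]] == f)
      train <- setdiff(seq_len(n), test)
      if (length(test) < 2) stop("fold with fewer than 2 test genotypes")
      sub_panel <- panel[train, ]
      class(sub_panel) <- unique(c("trait_panel", class(sub_panel)))
      Ktr <- K[train, train]
      mc <- mcmc; mc$seed <- seeds[replicates + 1] + 1000L * r + f
      purrr::map_dfr(names(models), function(mname) {
        mspec <- models[[mname]]
        pred <- switch(
          mspec$type,
          mtm = {
            fit <- fit_mtm(sub_panel, Ktr, hyper = mspec$hyper, mcmc = mc)
            predict_conditional(fit$mu_hat, fit$G_hat, fit$R_hat, K, train, test, Y)
          },
          sem = {
            fit <- fit_sem(sub_panel, Ktr, spec = mspec$spec, mcmc = mc,
                           hyper = mspec$hyper)
            predict_conditional(fit$mu_hat, fit$G_hat, fit$R_hat, K, train, test, Y)
          },
          single = {
            preds <- purrr::map(seq_len(d), function(k) {
              fit <- fit_single_trait(Y[train, k], Ktr, mcmc = mc)
              predict_conditional(fit$mu_hat, fit$G_hat, fit$R_hat, K, train, test,
                                  Y[, k, drop = FALSE])
            })
            do.call(cbind, preds)
          },
          stop("unknown model type: ", mspec$type))
        tibble::tibble(model = mname, replicate = r, fold = f, trait = traits,
                       ability = vapply(seq_len(d), function(k) {
                         # a constant prediction (e.g. K = I leaves the
                         # conditional mean at the intercept) carries no
                         # signal: ability 0 by convention
                         if (stats::sd(pred[, k]) < 1e-12) return(0)
                         stats::cor(Y[test, k], pred[, k])
                       }, numeric(1)))
      })
    })
  })
  ability <- per_split |>
    dplyr::group_by(.data$model, .data$trait) |>
    dplyr::summarise(mean = mean(.data$ability), sd = stats::sd(.data$ability),
                     n_splits = dplyr::n(), .groups = "drop")
  structure(list(folds = fold_tbl, per_split = per_split, ability = ability,
                 replicates = replicates, folds_k = folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d x %d-fold cross-validation\n", x$replicates, x$folds_k))
  print(x$ability)
  invisible(x)
}

#' Rank models by goodness of fit and predictive ability
#'
#' Produces the comparison table of DIC, effective-parameter and marginal
#' log-likelihood differences relative to a reference model (differences,
#' not absolutes), ordered by DIC delta, optionally joined with
#' cross-validated predictive ability averaged over traits and with
#' connection/nonnull-parameter counts.
#'
#' @param metrics tibble of [fit_metrics()] rows, one per model.
#' @param cv optional [cross_validate()] result whose model names match
#'   `metrics$model_label`.
#' @param reference label of the reference model (default `"MTM"` if
#'   present, else the first row).
#' @return tibble with one row per model: deltas `delta_dic`, `delta_p_d`,
#'   `delta_log_marginal` plus any count columns carried in `metrics`.
#' @export
rank_models <- function(metrics, cv = NULL, reference = NULL) {
  stopifnot(nrow(metrics) >= 1)
  reference <- reference %||%
    (if ("MTM" %in% metrics$model_label) "MTM" else metrics$model_label[1])
  ref <- metrics[metrics$model_label == reference, ]
  stopifnot(nrow(ref) == 1)
  out <- metrics |>
    dplyr::mutate(delta_dic = .data$dic - ref$dic,
                  delta_p_d = .data$p_d - ref$p_d,
                  delta_log_marginal = .data$log_marginal - ref$log_marginal,
                  reference = reference) |>
    dplyr::arrange(.data$delta_dic)
  if (!is.null(cv)) {
    mean_ability <- cv$ability |>
      dplyr::group_by(.data$model) |>
      dplyr::summarise(mean_ability = mean(.data$mean), .groups = "drop")
    out <- dplyr::left_join(out, mean_ability,
                            by = c(model_label = "model"))
  }
  out
}
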