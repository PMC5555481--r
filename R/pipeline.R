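# End-to-end orchestration: simulate or load a panel, fit the MTM,
# decorrelate the genomic component, learn networks under the six
# settings on both components with bootstrap averaging, fit SEM variants
# for each distinct learned structure, and emit the comparison report.

#' Configuration for a full pipeline run
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed; every stage derives its own substream.
#' @param truth a [synthetic_truth()] for the synthetic path (default
#'   [default_truth()]); ignored when `panel_csv` is given.
#' @param n_lines,n_markers,n_families synthetic panel design.
#' @param panel_csv,kinship_csv optional paths to load data instead of
#'   simulating.
#' @param settings which of the six learning settings to run.
#' @param alpha significance level for constraint-based settings.
#' @param n_permutations Monte Carlo permutations for permutation tests.
#' @param bootstrap_B bootstrap replicates per setting.
#' @param sem_variants subset of `"GstarR"`, `"GRstar"`, `"GstarRstar"`
#'   (structured genomic, structured residual, both); empty vector skips
#'   SEM fitting.
#' @param mcmc_mtm,mcmc_sem chain settings for the decomposition and SEM
#'   stages.
#' @param cv_replicates,cv_folds cross-validation design; `cv_enabled`
#'   turns the (expensive) CV stage on.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, truth = default_truth(),
                       n_lines = 800, n_markers = 2000, n_families = 10,
                       panel_csv = NULL, kinship_csv = NULL,
                       settings = c("gs1", "gs3", "tabu1", "tabu2"),
                       alpha = 0.01, n_permutations = 450, bootstrap_B = 500,
                       sem_variants = c("GstarR", "GRstar", "GstarRstar"),
                       mcmc_mtm = mcmc_settings(500, 2000, thin = 2),
                       mcmc_sem = mcmc_settings(500, 2000, thin = 2),
                       cv_enabled = FALSE, cv_replicates = 10, cv_folds = 5) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), truth = truth,
                 n_lines = n_lines, n_markers = n_markers,
                 n_families = n_families, panel_csv = panel_csv,
                 kinship_csv = kinship_csv, settings = settings,
                 alpha = alpha, n_permutations = n_permutations,
                 bootstrap_B = bootstrap_B, sem_variants = sem_variants,
                 mcmc_mtm = mcmc_mtm, mcmc_sem = mcmc_sem,
                 cv_enabled = cv_enabled, cv_replicates = cv_replicates,
                 cv_folds = cv_folds),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with any of the `run_config()` fields.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("truth", "mcmc_mtm", "mcmc_sem"))]
  args <- lapply(args, function(x) if (is.list(x)) unlist(x) else x)
  cfg <- do.call(run_config, args)
  if (!is.null(y$truth)) {
    cfg$truth <- synthetic_truth(
      do.call(rbind, y$truth$lambda_u), do.call(rbind, y$truth$lambda_e),
      psi_u = unlist(y$truth$psi_u), psi_e = unlist(y$truth$psi_e))
  }
  for (m in c("mcmc_mtm", "mcmc_sem")) {
    if (!is.null(y[[m]])) cfg[[m]] <- do.call(mcmc_settings, y[[m]])
  }
  cfg
}

#' Export a learned network as DOT and GraphML
#'
#' Edge labels carry the bootstrap strength and direction fraction
#' formatted to two decimals, `"1.00 (0.80)"`, mirroring the conventional
#' network-figure labels.
#'
#' @param dag a `bn_dag`.
#' @param strengths a `bn_strength` (or `NULL`: unlabeled edges).
#' @param path base path; `.dot` and `.graphml` are appended.
#' @return invisibly, the two file paths.
#' @export
export_network <- function(dag, strengths = NULL, path) {
  edge_label <- function(from, to) {
    if (is.null(strengths)) return("")
    row <- strengths$strengths[strengths$strengths$from == from &
                                 strengths$strengths$to == to, ]
    if (!nrow(row)) return("")
    sprintf("%.2f (%.2f)", row$strength[1], row$direction[1])
  }
  dot_path <- paste0(path, ".dot")
  lines <- c("digraph trait_network {")
  lines <- c(lines, paste0("  \"", dag$nodes, "\";"))
  if (nrow(dag$arcs)) {
    for (i in seq_len(nrow(dag$arcs))) {
      lab <- edge_label(dag$arcs$from[i], dag$arcs$to[i])
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                                dag$arcs$from[i], dag$arcs$to[i], lab))
    }
  }
  if (nrow(dag$undirected)) {
    for (i in seq_len(nrow(dag$undirected))) {
      lab <- edge_label(dag$undirected$from[i], dag$undirected$to[i])
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [dir=none, label=\"%s\"];",
                                dag$undirected$from[i], dag$undirected$to[i], lab))
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, dot_path)
  graphml_path <- paste0(path, ".graphml")
  edges <- dplyr::bind_rows(
    dplyr::mutate(dag$arcs, undirected = FALSE),
    dplyr::mutate(dag$undirected, undirected = TRUE))
  if (nrow(edges)) {
    edges$strength <- vapply(seq_len(nrow(edges)), function(i) {
      if (is.null(strengths)) return(NA_real_)
      row <- strengths$strengths[strengths$strengths$from == edges$from[i] &
                                   strengths$strengths$to == edges$to[i], ]
      if (nrow(row)) row$strength[1] else NA_real_
    }, numeric(1))
    edges$direction <- vapply(seq_len(nrow(edges)), function(i) {
      if (is.null(strengths)) return(NA_real_)
      row <- strengths$strengths[strengths$strengths$from == edges$from[i] &
                                   strengths$strengths$to == edges$to[i], ]
      if (nrow(row)) row$direction[1] else NA_real_
    }, numeric(1))
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = dag$nodes))
  igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(c(dot = dot_path, graphml = graphml_path))
}

#' Read a network back from GraphML
#'
#' @param path a `.graphml` file written by [export_network()].
#' @return a `bn_dag`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::vertex_attr(g, "name")
  el <- igraph::as_edgelist(g)
  und <- igraph::edge_attr(g, "undirected")
  if (is.null(und)) und <- rep(FALSE, nrow(el))
  und <- as.logical(und)
  bn_dag(nodes,
         if (any(!und)) el[!und, , drop = FALSE] else NULL,
         if (any(und)) el[und, , drop = FALSE] else NULL)
}

# write a filled or pattern structure matrix as CSV; structural zeros are
# rendered as empty cells
write_structure_csv <- function(pattern, path, values = NULL) {
  d <- nrow(pattern)
  out <- matrix("", d, d, dimnames = dimnames(pattern))
  fill <- if (is.null(values)) "1" else
    sprintf("%.6g", values[pattern])
  out[pattern] <- fill
  df <- tibble::as_tibble(out, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(child = rownames(pattern)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the stages in order -- simulate/load, MTM decomposition,
#' genomic decorrelation, structure learning on both components under the
#' configured settings, SEM fitting for each distinct learned structure
#' (deduplicated at the Markov-equivalence-class level), and model
#' assessment -- writing every artifact under `config$out_dir`. Any stage
#' error aborts with the stage name; artifacts of completed stages are
#' preserved.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the fitted objects and the comparison
#'   table.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 6)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out <- list()

  stage("simulate", {
    if (!is.null(config$panel_csv)) {
      panel <- read_panel(config$panel_csv)
      kinship <- read_kinship(config$kinship_csv)
    } else {
      markers <- simulate_markers(config$n_lines, config$n_markers,
                                  config$n_families, seed = seeds[1])
      kinship <- kinship_from_markers(markers)
      panel <- simulate_panel(config$truth, kinship, seed = seeds[2],
                              family_ids = markers$family_ids)
      write_truth(config$truth, file.path(config$out_dir, "truth.yaml"))
    }
    panel <- standardize_panel(panel)
    write_panel(panel, file.path(config$out_dir, "panel.csv"))
    write_kinship(kinship, file.path(config$out_dir, "kinship.csv"))
    out$panel <- panel; out$kinship <- kinship
  })

  stage("decompose", {
    mc <- config$mcmc_mtm; mc$seed <- seeds[3]
    fit <- fit_mtm(out$panel, out$kinship, mcmc = mc)
    for (nm in c("U_hat", "E_hat", "G_hat", "R_hat")) {
      readr::write_csv(tibble::as_tibble(fit[[nm]]),
                       file.path(config$out_dir, paste0(tolower(nm), ".csv")))
    }
    readr::write_csv(posterior_correlations(fit),
                     file.path(config$out_dir, "correlations.csv"))
    out$mtm <- fit
  })

  stage("transform", {
    tr <- cholesky_factor(unclass(out$kinship))
    Ustar <- decorrelate(out$mtm$U_hat, tr)
    readr::write_csv(tibble::as_tibble(Ustar),
                     file.path(config$out_dir, "u_star_hat.csv"))
    out$transform <- tr; out$U_star <- Ustar
  })

  stage("learn", {
    components <- list(genomic = out$U_star, residual = out$mtm$E_hat)
    learned <- list()
    for (comp in names(components)) {
      for (setting in config$settings) {
        learner <- learner_setting(setting, alpha = config$alpha,
                                   n_permutations = config$n_permutations,
                                   seed = seeds[4])
        avg <- bootstrap_average(components[[comp]], learner,
                                 B = config$bootstrap_B, seed = seeds[4])
        base <- file.path(config$out_dir, paste0("network_", comp, "_", setting))
        export_network(avg$averaged, avg, base)
        sm <- to_structure_matrix(avg$averaged)
        write_structure_csv(sm$pattern, paste0(base, "_structure.csv"))
        learned[[paste(comp, setting, sep = "_")]] <-
          list(component = comp, setting = setting, average = avg, structure = sm)
      }
    }
    out$learned <- learned
  })

  stage("sem", {
    if (!length(config$sem_variants) || !length(out$learned)) {
      out$sems <- list()
    } else {
      # deduplicate structures per component at the equivalence-class level
      distinct_structures <- function(comp) {
        items <- Filter(function(x) x$component == comp, out$learned)
        keys <- vapply(items, function(x) cpdag_key(x$average$averaged), character(1))
        keep <- !duplicated(keys)
        stats::setNames(lapply(items[keep], `[[`, "structure"),
                        vapply(items[keep], function(x)
                          paste(x$setting, collapse = "+"), character(1)))
      }
      gen <- distinct_structures("genomic")
      res <- distinct_structures("residual")
      sems <- list()
      mc <- config$mcmc_sem; mc$seed <- seeds[5]
      fit_one <- function(label, spec) {
        fit <- fit_sem(out$panel, out$kinship, spec, mcmc = mc)
        if (!is.null(fit$lambda_genomic)) {
          lam <- matrix(0, fit$d, fit$d, dimnames = list(fit$traits, fit$traits))
          lam[spec$structure_genomic$pattern] <- fit$lambda_genomic$estimate
          write_structure_csv(spec$structure_genomic$pattern,
                              file.path(config$out_dir, paste0("lambda_genomic_", label, ".csv")),
                              values = lam)
        }
        if (!is.null(fit$lambda_residual)) {
          lam <- matrix(0, fit$d, fit$d, dimnames = list(fit$traits, fit$traits))
          lam[spec$structure_residual$pattern] <- fit$lambda_residual$estimate
          write_structure_csv(spec$structure_residual$pattern,
                              file.path(config$out_dir, paste0("lambda_residual_", label, ".csv")),
                              values = lam)
        }
        fit
      }
      if ("GstarR" %in% config$sem_variants) {
        for (gname in names(gen)) {
          label <- paste0("GstarR_", gname)
          sems[[label]] <- fit_one(label, sem_spec(structure_genomic = gen[[gname]]))
        }
      }
      if ("GRstar" %in% config$sem_variants) {
        for (rname in names(res)) {
          label <- paste0("GRstar_", rname)
          sems[[label]] <- fit_one(label, sem_spec(structure_residual = res[[rname]]))
        }
      }
      if ("GstarRstar" %in% config$sem_variants) {
        for (gname in names(gen)) for (rname in names(res)) {
          label <- paste0("GstarRstar_", gname, "_", rname)
          sems[[label]] <- fit_one(label, sem_spec(structure_genomic = gen[[gname]],
                                                   structure_residual = res[[rname]]))
        }
      }
      out$sems <- sems
    }
  })

  stage("assess", {
    metrics <- fit_metrics(out$mtm, out$panel, out$kinship, label = "MTM")
    for (label in names(out$sems)) {
      m <- fit_metrics(out$sems[[label]], out$panel, out$kinship, label = label)
      cnt <- count_parameters(out$sems[[label]]$spec, out$mtm$d)
      metrics <- dplyr::bind_rows(metrics, dplyr::bind_cols(m, cnt))
    }
    cv <- NULL
    if (config$cv_enabled) {
      models <- c(list(MTM = list(type = "mtm"),
                       single_trait = list(type = "single")),
                  purrr::map(out$sems, function(f) list(type = "sem", spec = f$spec)))
      cv <- cross_validate(out$panel, out$kinship, models,
                           replicates = config$cv_replicates,
                           folds = config$cv_folds, seed = seeds[6])
      readr::write_csv(cv$ability, file.path(config$out_dir, "cv_ability.csv"))
    }
    comparison <- rank_models(metrics, cv)
    readr::write_csv(comparison, file.path(config$out_dir, "comparison.csv"))
    report <- c(
      "Model comparison (differences relative to MTM)",
      utils::capture.output(print(as.data.frame(comparison), digits = 4)))
    writeLines(report, file.path(config$out_dir, "report.txt"))
    out$metrics <- metrics; out$comparison <- comparison; out$cv <- cv
  })

  yaml::write_yaml(list(
    seed = config$seed,
    settings = config$settings, bootstrap_B = config$bootstrap_B,
    alpha = config$alpha, sem_variants = config$sem_variants,
    package_version = as.character(utils::packageVersion("traitnets"))),
    file.path(config$out_dir, "provenance.yaml"))
  invisible(out)
}
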