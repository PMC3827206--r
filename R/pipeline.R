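#' Pipeline configuration
#'
#' All stage toggles and parameters for [run_pipeline()], fully
#' serialisable to JSON; the effective configuration of a run is always
#' written next to its outputs.
#'
#' @param output_dir run directory (created if needed).
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @param simulate `TRUE` to generate synthetic inputs from `sim`, `FALSE`
#'   to read `benign_tsv`/`cancer_tsv`/`gmt`.
#' @param sim an [simulation_config()] (used when `simulate = TRUE`).
#' @param benign_tsv,cancer_tsv,gmt input paths (when `simulate = FALSE`).
#' @param networks_dir optional directory of pre-built condition networks
#'   (edge lists named `benign.txt` / `cancer.txt`); skips inference.
#' @param estimator,alpha,n_permutations,null C3NET settings, see
#'   [infer_c3net()].
#' @param min_genes subgraph size filter, see [extract_term_subgraphs()].
#' @param battery descriptor battery for the measure stage.
#' @param grid hyperparameter grid, see [svm_grid()].
#' @param folds,inner_folds cross-validation shape.
#' @param k_features number of genes kept by information gain in the
#'   biomarker arm.
#' @param tol ndv tolerance, see [ndv()].
#' @param stages character vector of stages to run, a subset (kept in
#'   order) of `simulate`, `infer`, `extract`, `measure`, `classify`,
#'   `uniqueness`.
#' @return list of class `"smk_pipeline_config"`.
#' @export
pipeline_config <- function(output_dir, seed = 1,
                            simulate = TRUE, sim = simulation_config(seed = seed),
                            benign_tsv = NULL, cancer_tsv = NULL,
                            gmt = NULL, networks_dir = NULL,
                            estimator = "gaussian", alpha = 0.05,
                            n_permutations = 100, null = "max",
                            min_genes = 5, battery = "both",
                            grid = svm_grid(), folds = 10,
                            inner_folds = 3, k_features = 10,
                            tol = 1e-10,
                            stages = c("simulate", "infer", "extract",
                                       "measure", "classify",
                                       "uniqueness")) {
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 simulate = simulate, sim = sim, benign_tsv = benign_tsv,
                 cancer_tsv = cancer_tsv, gmt = gmt,
                 networks_dir = networks_dir, estimator = estimator,
                 alpha = alpha, n_permutations = n_permutations,
                 null = null, min_genes = min_genes, battery = battery,
                 grid = grid, folds = folds, inner_folds = inner_folds,
                 k_features = k_features, tol = tol, stages = stages),
            class = "smk_pipeline_config")
}

#' Serialise / restore a pipeline configuration (JSON)
#' @param cfg an `smk_pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(cfg, path) {
  obj <- unclass(cfg)
  obj$sim <- unclass(obj$sim)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- if (!is.null(obj$sim)) do.call(simulation_config, obj$sim)
         else simulation_config(seed = obj$seed)
  pipeline_config(output_dir = obj$output_dir, seed = obj$seed,
                  simulate = obj$simulate, sim = sim,
                  benign_tsv = obj$benign_tsv, cancer_tsv = obj$cancer_tsv,
                  gmt = obj$gmt, networks_dir = obj$networks_dir,
                  estimator = obj$estimator, alpha = obj$alpha,
                  n_permutations = obj$n_permutations, null = obj$null,
                  min_genes = obj$min_genes, battery = obj$battery,
                  grid = as.data.frame(obj$grid), folds = obj$folds,
                  inner_folds = obj$inner_folds,
                  k_features = obj$k_features, tol = obj$tol,
                  stages = obj$stages)
}

# drop graphs isomorphic to an earlier one in the list (the degeneracy
# analysis requires pairwise non-equivalent networks)
dedupe_isomorphic <- function(graphs) {
  keep <- logical(length(graphs))
  kept <- list()
  for (i in seq_along(graphs)) {
    dup <- any(vapply(kept, function(h) are_isomorphic(h, graphs[[i]]),
                      logical(1)))
    keep[i] <- !dup
    if (!dup) kept[[length(kept) + 1]] <- graphs[[i]]
  }
  graphs[keep]
}

#' Run the structural-biomarker pipeline
#'
#' Executes the toggled stages: simulate (or load) two-condition expression
#' data and gene sets; infer one C3NET network per condition; extract
#' gene-set-induced subgraph populations; compute descriptor tables;
#' cross-validate the three classification arms (eigenvalue descriptors,
#' entropy descriptors, gene-expression biomarkers); and report descriptor
#' degeneracy (ndv). All outputs are plain text (TSV/CSV/GMT/GraphML/JSON)
#' inside `cfg$output_dir`, along with the effective configuration and a
#' run log; a rerun with the same configuration is byte-identical.
#'
#' @param cfg an [pipeline_config()].
#' @return invisible list with the in-memory stage results (`networks`,
#'   `subgraphs`, `labels`, `descriptors`, `cv` (three reports),
#'   `uniqueness`).
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$output_dir, "run.log")
  cat(sprintf("structmark %s | master seed %d\n",
              as.character(utils::packageVersion("structmark")), cfg$seed),
      file = logf)
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  write_pipeline_config(cfg, file.path(cfg$output_dir, "config.json"))
  res <- list()

  ## inputs ------------------------------------------------------------
  if ("simulate" %in% cfg$stages && isTRUE(cfg$simulate)) {
    stage("simulate", {
      sim <- simulate_expression(cfg$sim)
      gs <- simulate_gene_sets(cfg$sim)
      write_expression_tsv(sim$benign,
                           file.path(cfg$output_dir, "benign.tsv"))
      write_expression_tsv(sim$cancer,
                           file.path(cfg$output_dir, "cancer.tsv"))
      write_gmt(gs, file.path(cfg$output_dir, "gene_sets.gmt"))
      jsonlite::write_json(sim$truth,
                           file.path(cfg$output_dir, "truth.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      res$expression <- sim[c("benign", "cancer")]
      res$gene_sets <- gs
      log_line("simulate: %d genes, %d+%d samples, seed %d",
               cfg$sim$n_genes, ncol(sim$benign$values),
               ncol(sim$cancer$values), cfg$sim$seed)
    })
  } else {
    stage("load-inputs", {
      res$expression <- list(
        benign = read_expression_tsv(cfg$benign_tsv, "benign"),
        cancer = read_expression_tsv(cfg$cancer_tsv, "cancer"))
      res$gene_sets <- read_gmt(cfg$gmt)
      log_line("load-inputs: %s, %s, %s", cfg$benign_tsv, cfg$cancer_tsv,
               cfg$gmt)
    })
  }

  ## inference ----------------------------------------------------------
  if (!is.null(cfg$networks_dir)) {
    stage("load-networks", {
      res$networks <- list(
        benign = read_edgelist(
          file.path(cfg$networks_dir, "benign.txt"),
          vertex_path = file.path(cfg$networks_dir, "benign.vertices")),
        cancer = read_edgelist(
          file.path(cfg$networks_dir, "cancer.txt"),
          vertex_path = file.path(cfg$networks_dir, "cancer.vertices")))
      log_line("load-networks: %s (inference skipped)", cfg$networks_dir)
    })
  } else if ("infer" %in% cfg$stages) {
    stage("infer", {
      seeds <- cfg$seed + c(benign = 101L, cancer = 202L)
      res$networks <- lapply(c(benign = "benign", cancer = "cancer"),
                              function(cond) {
        g <- infer_c3net(res$expression[[cond]], estimator = cfg$estimator,
                         alpha = cfg$alpha,
                         n_permutations = cfg$n_permutations,
                         seed = seeds[[cond]], null = cfg$null)
        write_edgelist(g, file.path(cfg$output_dir,
                                    paste0(cond, "_network.txt")),
                       vertex_path = file.path(cfg$output_dir,
                                               paste0(cond,
                                                      "_network.vertices")))
        write_graphml(g, file.path(cfg$output_dir,
                                   paste0(cond, "_network.graphml")))
        log_line("infer %s: %d edges, threshold %.4g, seed %d", cond,
                 graph_size(g), attr(g, "threshold"), seeds[[cond]])
        g
      })
    })
  }

  ## subgraph extraction -------------------------------------------------
  if ("extract" %in% cfg$stages) {
    stage("extract", {
      res$subgraphs <- list()
      res$labels <- character(0)
      for (cond in names(res$networks)) {
        subs <- extract_term_subgraphs(res$networks[[cond]], res$gene_sets,
                                       min_genes = cfg$min_genes)
        write_subgraph_dir(subs, file.path(cfg$output_dir, "subgraphs"),
                           cond)
        names(subs) <- paste0(cond, "__", names(subs))
        res$subgraphs <- c(res$subgraphs, subs)
        res$labels <- c(res$labels, rep(cond, length(subs)))
        log_line("extract %s: %d subgraphs (min_genes %d)", cond,
                 length(subs), cfg$min_genes)
      }
      res$labels <- factor(res$labels, levels = c("benign", "cancer"))
    })
  }

  ## measures ------------------------------------------------------------
  if ("measure" %in% cfg$stages) {
    stage("measure", {
      res$descriptors <- descriptor_table(res$subgraphs,
                                           battery = cfg$battery)
      write_descriptor_csv(res$descriptors,
                           file.path(cfg$output_dir, "descriptors.csv"))
      log_line("measure: %d networks x %d descriptors",
               nrow(res$descriptors), ncol(res$descriptors))
    })
  }

  ## classification ------------------------------------------------------
  if ("classify" %in% cfg$stages) {
    stage("classify", {
      res$cv <- list()
      eig_cols <- intersect(colnames(res$descriptors), spectral_battery())
      ent_cols <- intersect(colnames(res$descriptors), entropy_battery())
      arms <- list()
      if (length(eig_cols) > 0) {
        arms$eigenvalue <- feature_table(
          res$descriptors[, eig_cols, drop = FALSE], res$labels)
      }
      if (length(ent_cols) > 0) {
        arms$entropy <- feature_table(
          res$descriptors[, ent_cols, drop = FALSE], res$labels)
      }
      bm_values <- cbind(res$expression$benign$values,
                         res$expression$cancer$values)
      bm_labels <- c(res$expression$benign$condition,
                     res$expression$cancer$condition)
      arms$biomarker <- feature_table(t(bm_values), bm_labels)
      for (arm in names(arms)) {
        tab <- arms[[arm]]
        folds <- min(cfg$folds, min(table(tab$labels)))
        if (folds < cfg$folds) {
          log_line("classify %s: folds reduced to %d (small class)",
                   arm, folds)
        }
        k <- if (arm == "biomarker") cfg$k_features else NULL
        cvrep <- cross_validated_svm(tab, grid = cfg$grid, folds = folds,
                                   seed = cfg$seed + 7L, k_features = k,
                                   inner_folds = cfg$inner_folds)
        write_cv_report(cvrep, file.path(cfg$output_dir,
                                       paste0("cv_", arm, ".json")))
        log_line("classify %s: accuracy %.3f +/- %.3f", arm,
                 cvrep$mean[["accuracy"]], cvrep$se[["accuracy"]])
        res$cv[[arm]] <- cvrep
      }
    })
  }

  ## uniqueness ----------------------------------------------------------
  if ("uniqueness" %in% cfg$stages) {
    stage("uniqueness", {
      ok <- apply(res$descriptors, 1, function(r) all(is.finite(r)))
      if (!all(ok)) {
        log_line("uniqueness: dropped %d network(s) with undefined values",
                 sum(!ok))
      }
      groups <- split(which(ok), res$labels[ok])
      tabs <- list(); gls <- list()
      for (gname in names(groups)) {
        gl <- dedupe_isomorphic(res$subgraphs[groups[[gname]]])
        dropped <- length(groups[[gname]]) - length(gl)
        if (dropped > 0) {
          log_line("uniqueness %s: dropped %d isomorphic duplicate(s)",
                   gname, dropped)
        }
        gls[[gname]] <- gl
        tabs[[gname]] <- res$descriptors[names(gl), , drop = FALSE]
      }
      res$uniqueness <- uniqueness_report(tabs, tol = cfg$tol,
                                           graphs = gls)
      write_uniqueness_csv(res$uniqueness,
                           file.path(cfg$output_dir, "uniqueness.csv"))
      log_line("uniqueness: %d descriptor x group rows",
               nrow(res$uniqueness))
    })
  }
  invisible(res)
}
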