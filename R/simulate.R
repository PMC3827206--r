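#' Simulation configuration for the synthetic two-condition benchmark
#'
#' The generator stands in for two-condition microarray studies: genes are
#' partitioned into equicorrelated co-expression modules embedded in
#' independent noise genes, the module membership map differs between the
#' two conditions (a fraction of module slots is re-assigned, so the two
#' conditions carry different network topology), and a subset of genes gets
#' a mean shift in the cancer condition (the differential-expression signal
#' for the biomarker arm).
#'
#' Defaults: 120 genes, 50 samples per condition (the real studies range
#' from 4 to 56 per condition), 8 modules of 5 genes at within-module
#' correlation 0.8, half of each module re-assigned in the cancer
#' condition, 10 DE genes at 2 within-gene SDs, 60 gene sets of 5-20 genes
#' with half of the sets aligned to a planted module.
#'
#' @param n_genes total number of genes.
#' @param n_samples_per_condition samples per condition.
#' @param n_modules,module_size planted co-expression modules.
#' @param within_module_correlation equicorrelation inside a module, in
#'   `[0, 1)`; length 1 (both conditions) or 2 (benign, cancer).
#' @param rewire_fraction fraction of each module's genes re-assigned to
#'   fresh noise genes in the cancer condition.
#' @param n_de_genes,de_effect_size differentially expressed genes and
#'   their mean shift in units of within-gene SD.
#' @param n_gene_sets,gene_set_size_range gene-set collection shape.
#' @param module_aligned_fraction fraction of gene sets containing one
#'   whole planted (benign) module.
#' @param seed integer seed; every generator is deterministic given it.
#' @return list of class `"smk_sim_config"`.
#' @export
simulation_config <- function(n_genes = 120, n_samples_per_condition = 50,
                              n_modules = 8, module_size = 5,
                              within_module_correlation = 0.8,
                              rewire_fraction = 0.5,
                              n_de_genes = 10, de_effect_size = 2,
                              n_gene_sets = 60,
                              gene_set_size_range = c(5, 20),
                              module_aligned_fraction = 0.5, seed = 1) {
  if (n_modules * module_size > n_genes) {
    stop("n_modules * module_size exceeds n_genes")
  }
  rho <- rep_len(within_module_correlation, 2)
  if (any(rho < 0 | rho >= 1)) stop("correlations must be in [0, 1)")
  stopifnot(n_genes > 0, n_samples_per_condition > 0, n_de_genes >= 0,
            de_effect_size >= 0,
            gene_set_size_range[1] >= 2,
            gene_set_size_range[2] <= n_genes)
  structure(list(n_genes = n_genes,
                 n_samples_per_condition = n_samples_per_condition,
                 n_modules = n_modules, module_size = module_size,
                 within_module_correlation = rho,
                 rewire_fraction = rewire_fraction,
                 n_de_genes = n_de_genes, de_effect_size = de_effect_size,
                 n_gene_sets = n_gene_sets,
                 gene_set_size_range = gene_set_size_range,
                 module_aligned_fraction = module_aligned_fraction,
                 seed = seed),
            class = "smk_sim_config")
}

sim_gene_ids <- function(n) {
  sprintf("g%0*d", nchar(as.character(n)), seq_len(n))
}

#' Simulate two-condition expression matrices with planted structure
#'
#' Module genes follow the one-factor equicorrelation model
#' \eqn{x_g = \sqrt{\rho}\, z_m + \sqrt{1-\rho}\,\varepsilon_g} with a
#' shared module factor \eqn{z_m} per sample, giving pairwise correlation
#' \eqn{\rho} inside the module; all other genes are independent standard
#' normals. The cancer condition uses a re-wired module map and adds the DE
#' mean shift.
#'
#' @param cfg an [simulation_config()].
#' @return list with `benign`, `cancer` (each an `smk_expression`) and
#'   `truth` (module maps per condition, DE genes).
#' @export
simulate_expression <- function(cfg) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$seed)
  genes <- sim_gene_ids(cfg$n_genes)
  n_mod_genes <- cfg$n_modules * cfg$module_size
  modules_benign <- split(genes[seq_len(n_mod_genes)],
                          rep(seq_len(cfg$n_modules),
                              each = cfg$module_size))
  # cancer: re-assign a fraction of each module's slots to noise genes
  noise_pool <- setdiff(genes, genes[seq_len(n_mod_genes)])
  n_swap <- round(cfg$rewire_fraction * cfg$module_size)
  modules_cancer <- modules_benign
  for (m in seq_len(cfg$n_modules)) {
    k <- min(n_swap, length(noise_pool))
    if (k == 0) next
    out_genes <- sample(modules_cancer[[m]], k)
    in_genes <- sample(noise_pool, k)
    modules_cancer[[m]] <- sort(c(setdiff(modules_cancer[[m]], out_genes),
                                  in_genes))
    noise_pool <- setdiff(c(noise_pool, out_genes), in_genes)
  }
  de_genes <- if (cfg$n_de_genes > 0) sort(sample(genes, cfg$n_de_genes))
              else character(0)

  draw <- function(modules, rho, prefix) {
    ns <- cfg$n_samples_per_condition
    x <- matrix(stats::rnorm(cfg$n_genes * ns), cfg$n_genes, ns,
                dimnames = list(genes,
                                sprintf("%s_s%03d", prefix, seq_len(ns))))
    for (m in seq_along(modules)) {
      z <- stats::rnorm(ns)
      idx <- match(modules[[m]], genes)
      x[idx, ] <- sqrt(rho) * matrix(z, length(idx), ns, byrow = TRUE) +
        sqrt(1 - rho) * x[idx, ]
    }
    x
  }
  xb <- draw(modules_benign, cfg$within_module_correlation[1], "benign")
  xc <- draw(modules_cancer, cfg$within_module_correlation[2], "cancer")
  if (length(de_genes) > 0) {
    xc[de_genes, ] <- xc[de_genes, ] + cfg$de_effect_size
  }
  list(benign = expression_matrix(xb, "benign"),
       cancer = expression_matrix(xc, "cancer"),
       truth = list(modules_benign = modules_benign,
                    modules_cancer = modules_cancer,
                    de_genes = de_genes))
}

#' Simulate an overlapping gene-set collection
#'
#' Set sizes are uniform on `gene_set_size_range`; genes are sampled
#' without replacement within a set and with replacement across sets (so
#' sets overlap). A `module_aligned_fraction` of the sets contains one
#' whole planted (benign-map) module, which makes the extracted subgraphs
#' structurally different between the two conditions.
#'
#' @param cfg an [simulation_config()].
#' @return an `smk_gene_sets`.
#' @export
simulate_gene_sets <- function(cfg) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$seed)
  genes <- sim_gene_ids(cfg$n_genes)
  n_mod_genes <- cfg$n_modules * cfg$module_size
  modules <- split(genes[seq_len(n_mod_genes)],
                   rep(seq_len(cfg$n_modules), each = cfg$module_size))
  n_aligned <- round(cfg$module_aligned_fraction * cfg$n_gene_sets)
  sets <- vector("list", cfg$n_gene_sets)
  names(sets) <- sprintf("GS%04d", seq_len(cfg$n_gene_sets))
  for (i in seq_len(cfg$n_gene_sets)) {
    size <- sample(seq(cfg$gene_set_size_range[1],
                       cfg$gene_set_size_range[2]), 1)
    if (i <= n_aligned) {
      core <- modules[[sample(cfg$n_modules, 1)]]
      extra <- sample(setdiff(genes, core),
                      max(0, size - length(core)))
      sets[[i]] <- sort(c(core, extra))
    } else {
      sets[[i]] <- sort(sample(genes, size))
    }
  }
  gene_set_collection(sets)
}

#' Simulate two classes of random graphs
#'
#' Erdős–Rényi \eqn{G(n, p)} populations with class labels, isolating the
#' measures-to-classification path from network inference.
#'
#' @param n_per_class graphs per class.
#' @param n_vertices vertices per graph.
#' @param class_a_density,class_b_density edge probabilities in (0, 1).
#' @param seed integer seed.
#' @return list with `graphs` (named list of `smk_graph`) and `labels`
#'   (factor with levels `classA`, `classB`).
#' @export
simulate_graph_classes <- function(n_per_class, n_vertices,
                                   class_a_density, class_b_density,
                                   seed = 1) {
  stopifnot(class_a_density > 0, class_a_density < 1,
            class_b_density > 0, class_b_density < 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  verts <- sprintf("v%02d", seq_len(n_vertices))
  pairs <- t(utils::combn(verts, 2))
  one <- function(p) {
    keep <- stats::runif(nrow(pairs)) < p
    smk_graph(if (any(keep)) pairs[keep, , drop = FALSE] else NULL,
              vertices = verts)
  }
  graphs <- list(); labels <- character(0)
  for (i in seq_len(n_per_class)) {
    graphs[[sprintf("classA_%03d", i)]] <- one(class_a_density)
    labels <- c(labels, "classA")
  }
  for (i in seq_len(n_per_class)) {
    graphs[[sprintf("classB_%03d", i)]] <- one(class_b_density)
    labels <- c(labels, "classB")
  }
  list(graphs = graphs, labels = factor(labels,
                                        levels = c("classA", "classB")))
}
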