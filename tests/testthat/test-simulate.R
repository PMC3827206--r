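test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(n_genes = 10, n_modules = 3,
                                 module_size = 4), "exceeds")
  expect_error(simulation_config(within_module_correlation = 1), "\\[0, 1\\)")
})

test_that("zero correlation gives uncorrelated genes", {
  cfg <- simulation_config(n_genes = 30, n_samples_per_condition = 200,
                           n_modules = 2, module_size = 5,
                           within_module_correlation = 0,
                           n_de_genes = 0, seed = 30)
  sim <- simulate_expression(cfg)
  r <- stats::cor(t(sim$benign$values))
  expect_lt(max(abs(r[upper.tri(r)])), 0.25)
  expect_lt(mean(abs(r[upper.tri(r)])), 0.1)
})

test_that("planted module correlation is near its target", {
  cfg <- simulation_config(n_genes = 40, n_samples_per_condition = 200,
                           n_modules = 2, module_size = 5,
                           within_module_correlation = 0.9,
                           rewire_fraction = 0, n_de_genes = 0, seed = 31)
  sim <- simulate_expression(cfg)
  r <- stats::cor(t(sim$benign$values))
  within <- unlist(lapply(sim$truth$modules_benign, function(m) {
    rm <- r[m, m]
    rm[upper.tri(rm)]
  }))
  expect_gte(mean(within), 0.85)
  expect_lte(mean(within), 0.95)
})

test_that("DE genes carry the planted mean shift (and only in cancer)", {
  cfg <- simulation_config(n_samples_per_condition = 150,
                           n_de_genes = 10, de_effect_size = 2, seed = 32)
  sim <- simulate_expression(cfg)
  de <- sim$truth$de_genes
  shift <- rowMeans(sim$cancer$values[de, ]) -
    rowMeans(sim$benign$values[de, ])
  expect_equal(mean(shift), 2, tolerance = 0.3)
  other <- setdiff(rownames(sim$benign$values), de)
  shift0 <- rowMeans(sim$cancer$values[other, ]) -
    rowMeans(sim$benign$values[other, ])
  expect_lt(abs(mean(shift0)), 0.2)
  # zero effect size: shifts behave like null t statistics
  cfg0 <- simulation_config(n_samples_per_condition = 150,
                            n_de_genes = 10, de_effect_size = 0, seed = 33)
  sim0 <- simulate_expression(cfg0)
  tstat <- vapply(sim0$truth$de_genes, function(g) {
    stats::t.test(sim0$cancer$values[g, ], sim0$benign$values[g, ])$statistic
  }, numeric(1))
  expect_gt(stats::ks.test(tstat, "pt", df = 290)$p.value, 0.01)
})

test_that("module rewiring changes the cancer module map", {
  cfg <- simulation_config(rewire_fraction = 0.5, seed = 34)
  sim <- simulate_expression(cfg)
  changed <- mapply(function(a, b) length(setdiff(b, a)),
                    sim$truth$modules_benign, sim$truth$modules_cancer)
  expect_true(all(changed >= 2))  # half of each 5-gene module re-assigned
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- simulation_config(seed = 35)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1$benign$values, s2$benign$values)
  expect_identical(s1$truth, s2$truth)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_gmt(simulate_gene_sets(cfg), p1)
  write_gmt(simulate_gene_sets(cfg), p2)
  expect_identical(readLines(p1), readLines(p2))  # identical GMT bytes
})

test_that("gene sets respect size range and module alignment", {
  cfg <- simulation_config(n_gene_sets = 20, gene_set_size_range = c(5, 5),
                           module_aligned_fraction = 1, seed = 36)
  gs <- simulate_gene_sets(cfg)
  expect_true(all(lengths(gs$sets) == 5))
  sim <- simulate_expression(cfg)
  aligned <- vapply(gs$sets, function(s) {
    any(vapply(sim$truth$modules_benign, function(m) all(m %in% s),
               logical(1)))
  }, logical(1))
  expect_true(all(aligned))
})

test_that("graph classes have the requested densities", {
  res <- simulate_graph_classes(20, 30, 0.1, 0.3, seed = 37)
  expect_length(res$graphs, 40)
  expect_identical(levels(res$labels), c("classA", "classB"))
  mdeg <- vapply(res$graphs, function(g) mean(graph_degrees(g)),
                 numeric(1))
  ratio <- mean(mdeg[res$labels == "classB"]) /
    mean(mdeg[res$labels == "classA"])
  expect_equal(ratio, 3, tolerance = 0.25)
  expect_length(simulate_graph_classes(0, 10, 0.1, 0.2, 1)$graphs, 0)
  # determinism
  res2 <- simulate_graph_classes(20, 30, 0.1, 0.3, seed = 37)
  expect_identical(res$graphs[[1]]$edges, res2$graphs[[1]]$edges)
})

test_that("c3net recovers planted module pairs end to end", {
  cfg <- simulation_config(n_genes = 60, n_samples_per_condition = 100,
                           n_modules = 4, module_size = 5,
                           within_module_correlation = 0.95,
                           rewire_fraction = 0, n_de_genes = 0, seed = 38)
  sim <- simulate_expression(cfg)
  g <- infer_c3net(sim$benign, alpha = 0.05, n_permutations = 80,
                   seed = 39)
  # every inferred edge should join two genes of one module
  same_module <- apply(g$edges, 1, function(e) {
    any(vapply(sim$truth$modules_benign, function(m) {
      all(e %in% m)
    }, logical(1)))
  })
  expect_gte(mean(same_module), 0.9)
  # and most module genes should be touched by an edge
  mod_genes <- unlist(sim$truth$modules_benign)
  expect_gte(mean(mod_genes %in% as.vector(g$edges)), 0.9)
})
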