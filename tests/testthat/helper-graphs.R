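# small named graphs used across the suite (labels chosen so canonical
# sorted order is the natural order)

g_path <- function(n, labels = letters[seq_len(n)]) {
  smk_graph(cbind(labels[-n], labels[-1]))
}

g_cycle <- function(n, labels = letters[seq_len(n)]) {
  smk_graph(cbind(labels, labels[c(2:n, 1)]))
}

g_complete <- function(n, labels = letters[seq_len(n)]) {
  smk_graph(t(utils::combn(labels, 2)))
}

g_star <- function(n, labels = letters[seq_len(n)]) {
  smk_graph(cbind(labels[1], labels[-1]))  # centre is first label
}

g_empty <- function(n, labels = letters[seq_len(n)]) {
  smk_graph(NULL, vertices = labels)
}

# smallest asymmetric graph: 6 vertices, 6 edges, trivial automorphism
# group (verified against the brute-force permutation oracle in tests)
g_asym6 <- function() {
  smk_graph(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"),
                  c("b", "f"), c("c", "f")))
}

# Erdos-Renyi graph over labelled vertices using the current RNG state
g_er <- function(n, p) {
  verts <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(verts, 2))
  keep <- stats::runif(nrow(pairs)) < p
  smk_graph(if (any(keep)) pairs[keep, , drop = FALSE] else NULL,
            vertices = verts)
}

# relabel a graph by a random permutation of fresh labels
g_relabel <- function(g, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- graph_order(g)
  new <- sprintf("z%03d", sample(n))
  map <- stats::setNames(new, g$vertices)
  em <- g$edges
  if (nrow(em) > 0) em <- cbind(map[em[, 1]], map[em[, 2]])
  smk_graph(if (nrow(em)) em else NULL, vertices = unname(map))
}
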