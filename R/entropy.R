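#' Shannon entropy of a probability vector (bits)
#'
#' @param p numeric vector; entries must be non-negative and sum to 1
#'   (within 1e-9).
#' @return \eqn{-\sum p_i \log_2 p_i} with \eqn{0 \log 0 := 0}.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

# entropy of a partition given block sizes (bits)
partition_entropy <- function(sizes) {
  if (length(sizes) == 0) return(0)
  shannon_entropy(sizes / sum(sizes))
}

# distance-scope graph: the graph itself when connected, else its largest
# component (ties by smallest vertex label) — the package-wide rule for
# every distance-based measure.
dist_scope <- function(g) {
  if (length(graph_components(g)) > 1) largest_component(g) else g
}

# distance matrix of the distance-scope graph, from mats if supplied;
# NULL when the scope degenerates to a single vertex (edgeless graph), in
# which case distance-based measures are undefined (NaN downstream)
dist_matrix <- function(g, mats = NULL) {
  if (is.null(mats)) mats <- build_matrices(g)
  D <- mats$distance
  if (nrow(D) < 2) return(NULL)
  D
}

#' Graph entropy from an information functional
#'
#' Assigns every vertex a positive value \eqn{f(v)}, converts to the
#' probability distribution \eqn{p_v = f(v)/\sum_u f(u)} and returns its
#' Shannon entropy in bits. Two preset functionals are provided:
#' \describe{
#'   \item{`fV_centrality`}{closeness centrality
#'     \eqn{f(v) = (n-1)/\sum_u d(v,u)}.}
#'   \item{`fP_spheres`}{\eqn{f(v) = \sum_{j=1}^{\rho} c_j |S_j(v)|} where
#'     \eqn{S_j(v)} is the j-sphere (vertices at distance exactly j from v),
#'     \eqn{\rho} the diameter, and the default coefficients are the
#'     linearly decreasing preset \eqn{c_j = \rho - j + 1}.}
#' }
#' Both presets are reconstructions of the cited functional families; the
#' `coefficients` argument keeps the j-sphere weighting swappable.
#' Disconnected graphs are reduced to their largest component first.
#'
#' @param g an `smk_graph` with at least 2 vertices.
#' @param functional `"fV_centrality"` or `"fP_spheres"`.
#' @param coefficients optional positive weights \eqn{c_j} for
#'   `fP_spheres` (recycled/truncated to the diameter).
#' @param mats optional precomputed [build_matrices()] result.
#' @return entropy in bits.
#' @export
dehmer_entropy <- function(g,
                           functional = c("fV_centrality", "fP_spheres"),
                           coefficients = NULL, mats = NULL) {
  functional <- match.arg(functional)
  D <- dist_matrix(g, mats)
  if (is.null(D)) return(NaN)
  n <- nrow(D)
  if (functional == "fV_centrality") {
    f <- (n - 1) / rowSums(D)
  } else {
    rho <- max(D)
    cj <- if (is.null(coefficients)) rev(seq_len(rho)) else {
      if (any(coefficients <= 0)) stop("coefficients must be positive")
      rep_len(coefficients, rho)
    }
    f <- vapply(seq_len(n), function(v) {
      sph <- tabulate(D[v, ][D[v, ] > 0], nbins = rho)
      sum(cj * sph)
    }, numeric(1))
  }
  if (any(f <= 0)) stop("information functional produced non-positive values")
  shannon_entropy(f / sum(f))
}

#' Topological information content
#'
#' Shannon entropy (bits) of the vertex-orbit size distribution
#' \eqn{|O_i|/n} under the automorphism group. Zero iff the graph is
#' vertex-transitive; \eqn{\log_2 n} on an asymmetric graph.
#'
#' @param g an `smk_graph`.
#' @param orbits optional precomputed [automorphism_orbits()] result.
#' @return entropy in bits.
#' @export
topological_info_content <- function(g, orbits = NULL) {
  if (is.null(orbits)) orbits <- automorphism_orbits(g)
  partition_entropy(lengths(orbits$blocks))
}

#' Partition- and distance-based graph entropies
#'
#' Five descriptors computed on the distance-scope graph (the graph itself
#' when connected, otherwise its largest component):
#' \describe{
#'   \item{`info_distance_degree`}{entropy of the vertex partition by
#'     distance degree (row sums of the distance matrix).}
#'   \item{`info_edge_equality`}{entropy of the edge partition by unordered
#'     endpoint-degree pair.}
#'   \item{`bonchev_ID`}{entropy of the distribution of distance values over
#'     the \eqn{n(n-1)/2} vertex pairs.}
#'   \item{`bonchev_IDW`}{magnitude variant
#'     \eqn{W \log_2 W - \sum_i k_i\, d_i \log_2 d_i}, with \eqn{W} the
#'     Wiener sum of all pairwise distances and \eqn{k_i} the number of
#'     pairs at distance \eqn{d_i}.}
#'   \item{`vertex_complexity`}{mean over vertices of the entropy of the
#'     vertex's distance profile \eqn{a_{vj}/n}, \eqn{j \ge 0} (the vertex
#'     itself counts at \eqn{j = 0}).}
#' }
#'
#' @param g an `smk_graph` with at least 2 vertices.
#' @param mats optional precomputed [build_matrices()] result.
#' @return named numeric vector of the five values (bits, except
#'   `bonchev_IDW`).
#' @export
partition_entropies <- function(g, mats = NULL) {
  D <- dist_matrix(g, mats)
  if (is.null(D)) {
    return(c(info_distance_degree = NaN, info_edge_equality = NaN,
             bonchev_ID = NaN, bonchev_IDW = NaN,
             vertex_complexity = NaN))
  }
  gc <- graph_induced(g, rownames(D))
  n <- nrow(D)
  # vertex partition by distance degree
  s <- rowSums(D)
  idd <- partition_entropy(as.integer(table(s)))
  # edge partition by unordered endpoint-degree pair
  deg <- graph_degrees(gc)
  iee <- if (graph_size(gc) == 0) 0 else {
    d1 <- deg[gc$edges[, 1]]; d2 <- deg[gc$edges[, 2]]
    key <- paste(pmin(d1, d2), pmax(d1, d2))
    partition_entropy(as.integer(table(key)))
  }
  # distance-value distribution over pairs
  dv <- D[upper.tri(D)]
  k <- table(dv)
  b_id <- partition_entropy(as.integer(k))
  d_i <- as.numeric(names(k))
  W <- sum(dv)
  b_idw <- W * log2(W) - sum(as.integer(k) * ifelse(d_i > 0,
                                                    d_i * log2(d_i), 0))
  # mean vertex distance-profile entropy
  vc <- mean(vapply(seq_len(n), function(v) {
    prof <- as.integer(table(D[v, ]))  # includes j = 0 (the vertex itself)
    partition_entropy(prof)
  }, numeric(1)))
  c(info_distance_degree = idd, info_edge_equality = iee,
    bonchev_ID = b_id, bonchev_IDW = b_idw, vertex_complexity = vc)
}

#' Balaban J index
#'
#' \eqn{J = \frac{m}{\mu + 1} \sum_{(u,v) \in E} (s_u s_v)^{-1/2}} with
#' \eqn{s_v} the distance degree of \eqn{v} and \eqn{\mu = m - n + 1} the
#' cyclomatic number, computed on the distance-scope graph.
#'
#' @param g an `smk_graph` with at least 2 vertices.
#' @param mats optional precomputed [build_matrices()] result.
#' @return the index value.
#' @export
balaban_j <- function(g, mats = NULL) {
  D <- dist_matrix(g, mats)
  if (is.null(D)) return(NaN)
  gc <- graph_induced(g, rownames(D))
  m <- graph_size(gc); n <- graph_order(gc)
  if (m == 0) return(0)
  s <- rowSums(D)
  mu <- m - n + 1
  m / (mu + 1) * sum(1 / sqrt(s[gc$edges[, 1]] * s[gc$edges[, 2]]))
}

#' Entropic symmetry index
#'
#' Default (reconstructed, configurable) definition:
#' \eqn{\log_2 |Aut(G)| + \sum_i (|O_i|/n) \log_2 |O_i|} over the vertex
#' orbits \eqn{O_i}. Zero for an asymmetric graph.
#'
#' @param g an `smk_graph`.
#' @param orbits optional precomputed [automorphism_orbits()] result.
#' @return index value in bits.
#' @export
symmetry_index <- function(g, orbits = NULL) {
  if (is.null(orbits)) orbits <- automorphism_orbits(g)
  n <- graph_order(g)
  sz <- lengths(orbits$blocks)
  log2(orbits$group_order) + sum((sz / n) * log2(sz))
}

#' Names of the ten entropy-based descriptors, in stable output order
#' @return character vector of length 10.
#' @export
entropy_battery <- function() {
  c("dehmer_fV", "topological_info_content", "vertex_complexity",
    "info_distance_degree", "info_edge_equality", "balaban_J",
    "symmetry_index", "bonchev_ID", "dehmer_fP", "bonchev_IDW")
}

#' The ten entropy-based structural descriptors of a graph
#'
#' Computes the full entropy battery (see [entropy_battery()] for the
#' stable order). Orbit-based measures use the full graph; distance-based
#' measures use the distance-scope (largest-component) rule.
#'
#' @param g an `smk_graph` with at least 2 vertices.
#' @param mats optional precomputed [build_matrices()] result.
#' @param orbits optional precomputed [automorphism_orbits()] result.
#' @return named numeric vector of length 10.
#' @export
entropy_descriptors <- function(g, mats = NULL, orbits = NULL) {
  if (is.null(mats)) mats <- build_matrices(g)
  if (is.null(orbits)) orbits <- automorphism_orbits(g)
  pe <- partition_entropies(g, mats)
  out <- c(dehmer_fV = dehmer_entropy(g, "fV_centrality", mats = mats),
           topological_info_content = topological_info_content(g, orbits),
           vertex_complexity = pe[["vertex_complexity"]],
           info_distance_degree = pe[["info_distance_degree"]],
           info_edge_equality = pe[["info_edge_equality"]],
           balaban_J = balaban_j(g, mats),
           symmetry_index = symmetry_index(g, orbits),
           bonchev_ID = pe[["bonchev_ID"]],
           dehmer_fP = dehmer_entropy(g, "fP_spheres", mats = mats),
           bonchev_IDW = pe[["bonchev_IDW"]])
  out[entropy_battery()]
}
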