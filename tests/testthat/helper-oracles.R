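# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph): distances by Floyd-Warshall, automorphisms
# by full n! enumeration, entropies by literal enumeration of spheres,
# partitions and pairs.

oracle_adjacency <- function(g) {
  n <- graph_order(g)
  A <- matrix(0, n, n, dimnames = list(g$vertices, g$vertices))
  for (k in seq_len(graph_size(g))) {
    A[g$edges[k, 1], g$edges[k, 2]] <- 1
    A[g$edges[k, 2], g$edges[k, 1]] <- 1
  }
  A
}

# Floyd-Warshall shortest paths (Inf when unreachable)
oracle_distances <- function(g) {
  A <- oracle_adjacency(g)
  n <- nrow(A)
  D <- ifelse(A == 1, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

perm_all <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perm_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# all automorphisms by n! enumeration; returns orbit blocks + group order
oracle_orbits <- function(g) {
  A <- oracle_adjacency(g)
  n <- nrow(A)
  perms <- perm_all(n)
  reach <- diag(n) > 0
  count <- 0
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    if (identical(A[p, p], unname(A)) || all(A[p, p] == A)) {
      count <- count + 1
      reach[cbind(seq_len(n), p)] <- TRUE
    }
  }
  # transitive closure of the "some automorphism maps i to j" relation
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  blocks <- unique(apply(reach, 1, function(r) paste(which(r),
                                                     collapse = ",")))
  blocks <- lapply(strsplit(blocks, ","), function(i) {
    sort(g$vertices[as.integer(i)])
  })
  blocks <- blocks[order(vapply(blocks, min, character(1)))]
  list(blocks = blocks, group_order = count)
}

oracle_isomorphic <- function(g1, g2) {
  if (graph_order(g1) != graph_order(g2)) return(FALSE)
  A1 <- oracle_adjacency(g1); A2 <- oracle_adjacency(g2)
  perms <- perm_all(nrow(A1))
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    if (all(A1[p, p] == A2)) return(TRUE)
  }
  FALSE
}

oracle_h <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# the ten entropy descriptors by literal enumeration, connected graphs only
oracle_entropy_battery <- function(g) {
  D <- oracle_distances(g)
  stopifnot(all(is.finite(D)))
  n <- nrow(D)
  deg <- rowSums(oracle_adjacency(g))
  orb <- oracle_orbits(g)
  rho <- max(D)
  # dehmer fV: closeness
  fv <- (n - 1) / rowSums(D)
  dehmer_fV <- oracle_h_prob(fv / sum(fv))
  # dehmer fP: j-spheres with c_j = rho - j + 1
  fp <- numeric(n)
  for (v in seq_len(n)) {
    for (j in seq_len(rho)) {
      fp[v] <- fp[v] + (rho - j + 1) * sum(D[v, ] == j)
    }
  }
  dehmer_fP <- oracle_h_prob(fp / sum(fp))
  tic <- oracle_h(lengths(orb$blocks))
  # vertex complexity: per-vertex distance profile incl. j = 0
  vc <- mean(vapply(seq_len(n), function(v) {
    oracle_h(as.integer(table(D[v, ])))
  }, numeric(1)))
  idd <- oracle_h(as.integer(table(rowSums(D))))
  # edge equality by unordered endpoint-degree pair
  keys <- character(0)
  for (k in seq_len(graph_size(g))) {
    du <- deg[g$edges[k, 1]]; dv <- deg[g$edges[k, 2]]
    keys <- c(keys, paste(min(du, dv), max(du, dv)))
  }
  iee <- if (length(keys)) oracle_h(as.integer(table(keys))) else 0
  # distance-value distribution over unordered pairs
  dvals <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) dvals <- c(dvals, D[i, j])
  }
  b_id <- oracle_h(as.integer(table(dvals)))
  W <- sum(dvals)
  b_idw <- W * log2(W) - sum(vapply(unique(dvals), function(d) {
    sum(dvals == d) * (if (d > 0) d * log2(d) else 0)
  }, numeric(1)))
  # balaban J
  s <- rowSums(D)
  m <- graph_size(g)
  mu <- m - n + 1
  bj <- 0
  for (k in seq_len(m)) {
    bj <- bj + 1 / sqrt(s[g$edges[k, 1]] * s[g$edges[k, 2]])
  }
  bj <- m / (mu + 1) * bj
  sym <- log2(orb$group_order) +
    sum((lengths(orb$blocks) / n) * log2(lengths(orb$blocks)))
  c(dehmer_fV = unname(dehmer_fV), topological_info_content = tic,
    vertex_complexity = vc, info_distance_degree = idd,
    info_edge_equality = iee, balaban_J = unname(bj),
    symmetry_index = sym, bonchev_ID = b_id,
    dehmer_fP = unname(dehmer_fP), bonchev_IDW = b_idw)
}

oracle_h_prob <- function(p) -sum(p[p > 0] * log2(p[p > 0]))

# O(N^2) pairwise ndv
oracle_ndv <- function(values, tol) {
  n <- length(values)
  if (n < 2) return(0L)
  hit <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j &&
          abs(values[i] - values[j]) <=
            tol * max(abs(values[i]), abs(values[j]))) {
        hit[i] <- TRUE
      }
    }
  }
  sum(hit)
}

# binary confusion metrics, macro-averaged, written independently
oracle_macro_metrics <- function(tp1, fn1, fp1, tn1) {
  # class 1 positive
  s1 <- tp1 / (tp1 + fn1); s2 <- tn1 / (tn1 + fp1)
  p1 <- if (tp1 + fp1 > 0) tp1 / (tp1 + fp1) else 0
  p2 <- if (tn1 + fn1 > 0) tn1 / (tn1 + fn1) else 0
  f1 <- if (p1 + s1 > 0) 2 * p1 * s1 / (p1 + s1) else 0
  f2 <- if (p2 + s2 > 0) 2 * p2 * s2 / (p2 + s2) else 0
  c(sensitivity = (s1 + s2) / 2, specificity = (s2 + s1) / 2,
    precision = (p1 + p2) / 2, recall = (s1 + s2) / 2,
    accuracy = (tp1 + tn1) / (tp1 + fn1 + fp1 + tn1),
    f_score = (f1 + f2) / 2)
}

# all connected graphs with exactly n vertices, one per isomorphism class,
# by exhaustive bitmask enumeration + canonical-code dedupe (min over all
# vertex permutations of the edge-indicator integer)
enumerate_connected_graphs <- function(n) {
  pairs <- t(utils::combn(n, 2))
  np <- nrow(pairs)
  perms <- perm_all(n)
  # action of each permutation on edge-slot indices
  slot <- matrix(0L, n, n)
  slot[pairs] <- seq_len(np); slot[pairs[, c(2, 1)]] <- seq_len(np)
  permmap <- do.call(rbind, lapply(seq_len(nrow(perms)), function(r) {
    p <- perms[r, ]
    slot[cbind(p[pairs[, 1]], p[pairs[, 2]])]
  }))
  pow <- 2^(seq_len(np) - 1)
  codes <- 0:(2^np - 1)
  E <- matrix(0L, length(codes), np)
  for (b in seq_len(np)) E[, b] <- bitwAnd(codes, pow[b]) > 0
  # connectivity check via repeated neighbourhood expansion
  is_conn <- vapply(codes, function(code) {
    A <- matrix(0L, n, n)
    on <- bitwAnd(code, pow) > 0
    A[pairs[on, , drop = FALSE]] <- 1L
    A[pairs[on, c(2, 1), drop = FALSE]] <- 1L
    reach <- c(TRUE, rep(FALSE, n - 1))
    for (k in seq_len(n)) reach <- reach | (A %*% reach > 0)
    all(reach)
  }, logical(1))
  canon <- rep(NA_real_, length(codes))
  for (r in seq_len(nrow(permmap))) {
    v <- E[, permmap[r, ], drop = FALSE] %*% pow
    canon <- pmin(canon, v, na.rm = TRUE)
  }
  reps <- which(is_conn & !duplicated(canon) & codes == canon)
  lapply(reps, function(i) {
    on <- E[i, ] > 0
    labs <- letters[seq_len(n)]
    em <- cbind(labs[pairs[on, 1]], labs[pairs[on, 2]])
    smk_graph(if (nrow(em)) em else NULL, vertices = labs)
  })
}
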