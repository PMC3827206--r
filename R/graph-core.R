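#' Undirected labelled graph
#'
#' A minimal undirected simple graph with character vertex labels. Vertices
#' are kept in sorted (canonical) order so every matrix view, spectrum and
#' file output derived from the graph is byte-reproducible. Self-loops and
#' duplicate edges are rejected.
#'
#' @param edges two-column character matrix (or data.frame) of edges, or
#'   `NULL` for an edgeless graph.
#' @param vertices optional character vector of vertex labels; must contain
#'   every edge endpoint. Needed to represent isolated vertices.
#' @return An object of class `"smk_graph"`: a list with `vertices`
#'   (sorted character vector) and `edges` (two-column character matrix,
#'   each row sorted, rows in lexicographic order).
#' @examples
#' g <- smk_graph(rbind(c("a", "b"), c("b", "c")))
#' graph_order(g)
#' @export
smk_graph <- function(edges = NULL, vertices = NULL) {
  if (is.null(edges)) {
    em <- matrix(character(0), ncol = 2)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2) stop("edges must have two columns")
    storage.mode(em) <- "character"
  }
  if (nrow(em) > 0) {
    if (any(em[, 1] == em[, 2])) stop("self-loops are not allowed")
    swap <- em[, 1] > em[, 2]
    em[swap, ] <- em[swap, c(2, 1), drop = FALSE]
    key <- paste(em[, 1], em[, 2], sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
    em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  }
  # vertices may add isolated vertices; endpoints are always included, so
  # the "endpoints are members of the vertex set" invariant holds by
  # construction
  verts <- sort(unique(c(as.character(vertices), as.vector(em))))
  structure(list(vertices = verts, edges = em), class = "smk_graph")
}

#' @export
print.smk_graph <- function(x, ...) {
  cat(sprintf("smk_graph: %d vertices, %d edges\n",
              graph_order(x), graph_size(x)))
  invisible(x)
}

#' Number of vertices
#' @param g an `smk_graph`.
#' @export
graph_order <- function(g) length(g$vertices)

#' Number of edges
#' @param g an `smk_graph`.
#' @export
graph_size <- function(g) nrow(g$edges)

#' Vertex degrees in canonical vertex order
#' @param g an `smk_graph`.
#' @return named integer vector.
#' @export
graph_degrees <- function(g) {
  d <- stats::setNames(integer(graph_order(g)), g$vertices)
  if (graph_size(g) > 0) {
    tab <- table(factor(as.vector(g$edges), levels = g$vertices))
    d[] <- as.integer(tab)
  }
  d
}

#' Convert to an igraph object (canonical vertex order preserved)
#' @param g an `smk_graph`.
#' @export
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = 0, directed = FALSE)
  ig <- igraph::add_vertices(ig, graph_order(g), name = g$vertices)
  if (graph_size(g) > 0) {
    ig <- igraph::add_edges(ig, as.vector(t(g$edges)))
  }
  ig
}

#' Convert an igraph object to an `smk_graph`
#' @param ig an undirected igraph object; vertices must be named (unnamed
#'   vertices get their index as label).
#' @export
from_igraph <- function(ig) {
  if (igraph::is_directed(ig)) stop("directed graphs are not supported")
  nm <- igraph::vertex_attr(ig, "name")
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(ig)))
  el <- igraph::as_edgelist(ig, names = FALSE)
  em <- cbind(nm[el[, 1]], nm[el[, 2]])
  smk_graph(if (nrow(em)) em else NULL, vertices = nm)
}

#' Connected components
#' @param g an `smk_graph`.
#' @return list of character vectors of vertex labels, ordered by
#'   decreasing size, ties broken by smallest contained label.
#' @export
graph_components <- function(g) {
  if (graph_order(g) == 0) return(list())
  comp <- igraph::components(as_igraph(g))
  blocks <- split(g$vertices, comp$membership)
  firsts <- vapply(blocks, function(b) min(b), character(1))
  sizes <- lengths(blocks)
  blocks[order(-sizes, firsts)]
}

#' Vertex-induced subgraph
#' @param g an `smk_graph`.
#' @param vids character vector of vertex labels (labels absent from `g`
#'   are ignored).
#' @export
graph_induced <- function(g, vids) {
  keep <- intersect(g$vertices, vids)
  em <- g$edges
  em <- em[em[, 1] %in% keep & em[, 2] %in% keep, , drop = FALSE]
  smk_graph(if (nrow(em)) em else NULL, vertices = keep)
}

#' Largest connected component (ties by smallest vertex label)
#' @param g an `smk_graph` with at least one vertex.
#' @export
largest_component <- function(g) {
  comps <- graph_components(g)
  if (length(comps) == 0) stop("graph has no vertices")
  graph_induced(g, comps[[1]])
}

#' Adjacency, distance and Laplacian matrices of a graph
#'
#' Matrices are indexed by the canonical (sorted) vertex order. For a
#' disconnected graph the distance matrix is either computed on the largest
#' connected component (ties broken by smallest vertex label) or an error is
#' raised, depending on `distance_scope`; adjacency and Laplacian always
#' cover the full graph.
#'
#' @param g an `smk_graph` with at least 2 vertices.
#' @param distance_scope `"largest_component"` (default) or
#'   `"require_connected"`.
#' @return A list of class `"smk_graph_matrices"` with elements `adjacency`,
#'   `laplacian` (n x n), `distance` (possibly smaller, with dimnames giving
#'   the component's vertices), `distance_vertices`, and `graph`.
#' @export
build_matrices <- function(g,
                           distance_scope = c("largest_component",
                                              "require_connected")) {
  distance_scope <- match.arg(distance_scope)
  n <- graph_order(g)
  if (n < 2) stop("graph must have at least 2 vertices")
  A <- matrix(0, n, n, dimnames = list(g$vertices, g$vertices))
  if (graph_size(g) > 0) {
    A[g$edges] <- 1
    A[g$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  L <- diag(rowSums(A)) - A
  dimnames(L) <- dimnames(A)
  gc <- g
  if (length(graph_components(g)) > 1) {
    if (distance_scope == "require_connected") {
      stop("graph is disconnected (distance_scope = \"require_connected\")")
    }
    gc <- largest_component(g)
  }
  D <- igraph::distances(as_igraph(gc))
  D <- D[gc$vertices, gc$vertices, drop = FALSE]
  structure(list(adjacency = A, laplacian = L, distance = D,
                 distance_vertices = gc$vertices, graph = g),
            class = "smk_graph_matrices")
}

#' Exact graph isomorphism test
#'
#' Exact test (VF2 backtracking with pruning, via igraph), not a heuristic.
#'
#' @param g1,g2 `smk_graph` objects.
#' @return `TRUE` iff an edge-preserving vertex bijection exists.
#' @export
are_isomorphic <- function(g1, g2) {
  if (graph_order(g1) != graph_order(g2) ||
      graph_size(g1) != graph_size(g2)) {
    return(FALSE)
  }
  if (!identical(unname(sort(graph_degrees(g1))),
                 unname(sort(graph_degrees(g2))))) {
    return(FALSE)
  }
  igraph::isomorphic(as_igraph(g1), as_igraph(g2), method = "vf2")
}

#' Automorphism orbits and group order
#'
#' Vertex orbits of the automorphism group, computed exactly: BLISS
#' (canonical-labelling backtracking) supplies group generators and the
#' group order; orbits are the closure of the generator action (union-find).
#' 1-WL-style refinement is used internally by BLISS only for pruning, the
#' result is exact.
#'
#' @param g an `smk_graph`.
#' @param cap maximum number of vertices accepted (guard for the exact
#'   search); default 500.
#' @return list of class `"smk_orbits"`: `blocks` (list of character
#'   vectors partitioning the vertex set, ordered by smallest member) and
#'   `group_order` (double; order of the automorphism group).
#' @export
automorphism_orbits <- function(g, cap = 500) {
  n <- graph_order(g)
  if (n > cap) stop(sprintf("graph has %d vertices, exceeding cap %d", n, cap))
  if (n == 0) {
    return(structure(list(blocks = list(), group_order = 1),
                     class = "smk_orbits"))
  }
  ig <- as_igraph(g)
  gens <- igraph::automorphism_group(ig)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (perm in gens) {
    p <- as.integer(perm)
    for (i in seq_len(n)) {
      ri <- find(i); rj <- find(p[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  blocks <- split(g$vertices, roots)
  blocks <- blocks[order(vapply(blocks, min, character(1)))]
  names(blocks) <- NULL
  cnt <- igraph::count_automorphisms(ig)
  go <- if (is.list(cnt)) as.numeric(cnt$group_size) else as.numeric(cnt)
  structure(list(blocks = blocks, group_order = go), class = "smk_orbits")
}

#' @export
print.smk_orbits <- function(x, ...) {
  cat(sprintf("automorphism orbits: %d blocks, |Aut| = %s\n",
              length(x$blocks), format(x$group_order)))
  invisible(x)
}

## ---- I/O ------------------------------------------------------------------

#' Read / write a graph as a plain edge list
#'
#' Edge-list format: two whitespace-separated vertex labels per line.
#' Isolated vertices are carried by an optional sidecar file holding one
#' vertex label per line.
#'
#' @param path edge-list file path.
#' @param vertex_path optional sidecar file listing all vertices.
#' @return `read_edgelist` returns an `smk_graph`; `write_edgelist` returns
#'   `path` invisibly.
#' @export
read_edgelist <- function(path, vertex_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  em <- NULL
  if (length(lines) > 0) {
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    if (any(lengths(parts) != 2)) stop("each edge line must have two labels")
    em <- do.call(rbind, parts)
  }
  verts <- NULL
  if (!is.null(vertex_path) && file.exists(vertex_path)) {
    verts <- trimws(readLines(vertex_path))
    verts <- verts[nzchar(verts)]
  }
  smk_graph(em, vertices = verts)
}

#' @rdname read_edgelist
#' @param g an `smk_graph`.
#' @export
write_edgelist <- function(g, path, vertex_path = NULL) {
  writeLines(paste(g$edges[, 1], g$edges[, 2], sep = "\t"), path)
  if (!is.null(vertex_path)) writeLines(g$vertices, vertex_path)
  invisible(path)
}

#' Read / write GraphML
#' @param path file path.
#' @return `read_graphml` returns an `smk_graph`.
#' @export
read_graphml <- function(path) {
  from_igraph(igraph::read_graph(path, format = "graphml"))
}

#' @rdname read_graphml
#' @param g an `smk_graph`.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}
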