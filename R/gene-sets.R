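#' Named gene-set collection (GO-term surrogate)
#'
#' @param sets named list of character vectors (gene ids); names must be
#'   unique, lists non-empty and duplicate-free.
#' @param namespace annotation namespace tag.
#' @return object of class `"smk_gene_sets"`.
#' @export
gene_set_collection <- function(sets, namespace = "biological_process") {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must have unique names")
  }
  for (nm in names(sets)) {
    s <- sets[[nm]]
    if (length(s) == 0) stop(sprintf("gene set '%s' is empty", nm))
    if (anyDuplicated(s)) stop(sprintf("gene set '%s' has duplicates", nm))
  }
  structure(list(sets = lapply(sets, as.character), namespace = namespace),
            class = "smk_gene_sets")
}

#' @export
print.smk_gene_sets <- function(x, ...) {
  cat(sprintf("smk_gene_sets: %d sets (%s), sizes %d..%d\n",
              length(x$sets), x$namespace,
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, tab-separated `name`, `description`, genes.
#'
#' @param path GMT file path.
#' @param namespace namespace tag attached on read.
#' @return `read_gmt` returns an `smk_gene_sets`.
#' @export
read_gmt <- function(path, namespace = "biological_process") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) stop("GMT lines need name, description, genes")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  gene_set_collection(sets, namespace)
}

#' @rdname read_gmt
#' @param gs an `smk_gene_sets`.
#' @export
write_gmt <- function(gs, path) {
  lines <- vapply(names(gs$sets), function(nm) {
    paste(c(nm, gs$namespace, gs$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Extract gene-set-induced subgraphs from a network
#'
#' For each gene set, the vertex-induced subgraph of `g` on the genes of the
#' set that are present in `g`. Subgraphs with fewer than `min_genes`
#' vertices are dropped; output order follows the input set order. Induced
#' subgraphs may be disconnected — only the size filter is applied here
#' (connectivity is handled downstream by the distance-scope rule).
#'
#' @param g an `smk_graph`.
#' @param sets an `smk_gene_sets`.
#' @param min_genes minimum number of present genes (>= 2).
#' @return named list of `smk_graph` objects (possibly empty).
#' @export
extract_term_subgraphs <- function(g, sets, min_genes = 5) {
  stopifnot(min_genes >= 2)
  out <- list()
  for (nm in names(sets$sets)) {
    sub <- graph_induced(g, sets$sets[[nm]])
    if (graph_order(sub) >= min_genes) out[[nm]] <- sub
  }
  out
}

#' Write a list of subgraphs as edge-list files
#'
#' Files are named `<condition>__<term>.txt` (edges) with a matching
#' `.vertices` sidecar so isolated vertices survive the round trip.
#'
#' @param subgraphs named list of `smk_graph` objects.
#' @param dir output directory (created if needed).
#' @param condition condition label used in file names.
#' @return invisible character vector of edge-list paths.
#' @export
write_subgraph_dir <- function(subgraphs, dir, condition) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(subgraphs), function(nm) {
    base <- file.path(dir, paste0(condition, "__", nm))
    write_edgelist(subgraphs[[nm]], paste0(base, ".txt"),
                   vertex_path = paste0(base, ".vertices"))
    paste0(base, ".txt")
  }, character(1))
  invisible(paths)
}

#' Read a directory of edge-list subgraphs written by [write_subgraph_dir()]
#' @param dir directory path.
#' @return named list of `smk_graph`s with a `condition` attribute per
#'   element taken from the file-name prefix.
#' @export
read_subgraph_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  out <- list()
  for (f in files) {
    base <- sub("\\.txt$", "", basename(f))
    vp <- file.path(dir, paste0(base, ".vertices"))
    g <- read_edgelist(f, vertex_path = if (file.exists(vp)) vp else NULL)
    parts <- strsplit(base, "__", fixed = TRUE)[[1]]
    attr(g, "condition") <- parts[1]
    attr(g, "term") <- paste(parts[-1], collapse = "__")
    out[[base]] <- g
  }
  out
}
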