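#' Number of non-distinguishable values (ndv)
#'
#' Counts the entries of a descriptor-value vector that collide with at
#' least one other entry. Two values collide when they are equal within the
#' relative tolerance `tol`; equality groups are formed by single linkage
#' over the tolerance relation (sorted adjacent chaining), so the count is
#' the number of members of all groups of size >= 2. An ndv of 1 is
#' impossible by construction.
#'
#' @param values numeric vector of descriptor values.
#' @param tol relative tolerance (>= 0); two values `a`, `b` collide when
#'   `|a - b| <= tol * max(|a|, |b|)`. `tol = 0` is exact equality.
#' @return integer ndv.
#' @export
ndv <- function(values, tol = 1e-10) {
  stopifnot(tol >= 0)
  n <- length(values)
  if (n < 2) return(0L)
  ord <- order(values)
  v <- values[ord]
  linked <- abs(diff(v)) <= tol * pmax(abs(v[-n]), abs(v[-1]))
  grp <- cumsum(c(1, !linked))
  sizes <- tabulate(grp)
  sum(sizes[sizes >= 2])
}

#' Descriptor degeneracy report over network groups
#'
#' For every descriptor column and for the pooled set plus each group,
#' reports the absolute ndv, the relative ndv (ndv / group size) and the
#' Konstantinova sensitivity \eqn{S = (N - ndv)/N}.
#'
#' When the underlying graphs are supplied, each group is first verified to
#' be pairwise structurally non-equivalent (non-isomorphic); a duplicate is
#' an error, because degeneracy counts are only meaningful on
#' non-isomorphic networks.
#'
#' @param tables named list of `smk_feature_table`s (or plain numeric
#'   matrices with descriptor columns), one per group, sharing identical
#'   descriptor columns.
#' @param tol relative tolerance for [ndv()].
#' @param graphs optional named list (same names) of lists of `smk_graph`s
#'   used for the non-isomorphism pre-check.
#' @return data.frame of class `"smk_uniqueness_report"` with columns
#'   `descriptor`, `group`, `n`, `ndv_absolute`, `ndv_relative`,
#'   `sensitivity`.
#' @export
uniqueness_report <- function(tables, tol = 1e-10, graphs = NULL) {
  mats <- lapply(tables, function(t) {
    if (inherits(t, "smk_feature_table")) t$values else as.matrix(t)
  })
  feats <- colnames(mats[[1]])
  for (m in mats) {
    if (!identical(colnames(m), feats)) {
      stop("all groups must share identical descriptor columns")
    }
  }
  if (!is.null(graphs)) {
    for (gname in names(graphs)) {
      gs <- graphs[[gname]]
      if (length(gs) < 2) next
      for (i in seq_len(length(gs) - 1)) {
        for (j in (i + 1):length(gs)) {
          if (are_isomorphic(gs[[i]], gs[[j]])) {
            stop(sprintf(
              "group '%s' contains isomorphic networks (%d, %d)",
              gname, i, j))
          }
        }
      }
    }
  }
  groups <- c(list(all = do.call(rbind, mats)), mats)
  rows <- list()
  for (f in feats) {
    for (gname in names(groups)) {
      v <- groups[[gname]][, f]
      nd <- ndv(v, tol)
      rows[[length(rows) + 1]] <- data.frame(
        descriptor = f, group = gname, n = length(v),
        ndv_absolute = nd, ndv_relative = nd / length(v),
        sensitivity = (length(v) - nd) / length(v))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("smk_uniqueness_report", class(out))
  out
}

#' Write a uniqueness report as CSV (absolute/relative x group layout)
#' @param report output of [uniqueness_report()].
#' @param path CSV path.
#' @export
write_uniqueness_csv <- function(report, path) {
  wide <- stats::reshape(
    as.data.frame(report)[c("descriptor", "group", "ndv_absolute",
                            "ndv_relative")],
    idvar = "descriptor", timevar = "group", direction = "wide")
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Descriptor table for a population of graphs
#'
#' Computes the configured eigenvalue and/or entropy batteries for each
#' graph and assembles the networks x descriptors matrix (eigenvalue
#' columns first, entropy columns after, in their stable orders).
#'
#' @param graphs named list of `smk_graph`s.
#' @param battery `"spectral"`, `"entropy"` or `"both"`.
#' @param orbit_cap vertex cap passed to [automorphism_orbits()].
#' @return numeric matrix, one row per graph.
#' @export
descriptor_table <- function(graphs, battery = c("both", "spectral",
                                                 "entropy"),
                             orbit_cap = 500) {
  battery <- match.arg(battery)
  rows <- lapply(graphs, function(g) {
    mats <- build_matrices(g)
    out <- numeric(0)
    if (battery %in% c("both", "spectral")) {
      out <- c(out, spectral_descriptors(mats))
    }
    if (battery %in% c("both", "entropy")) {
      orbits <- automorphism_orbits(g, cap = orbit_cap)
      out <- c(out, entropy_descriptors(g, mats = mats, orbits = orbits))
    }
    out
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(graphs)
  mat
}

#' Write a descriptor table as CSV (stable column order)
#' @param mat matrix from [descriptor_table()].
#' @param path CSV path.
#' @export
write_descriptor_csv <- function(mat, path) {
  df <- data.frame(network = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
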