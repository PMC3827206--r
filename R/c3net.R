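#' Expression matrix container
#'
#' Genes x samples real matrix with a condition label per sample.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param condition character/factor vector of length `ncol(values)`, or a
#'   single label recycled to all samples.
#' @return object of class `"smk_expression"`.
#' @export
expression_matrix <- function(values, condition) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene rownames")
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  condition <- as.character(condition)
  if (length(condition) == 1) condition <- rep(condition, ncol(values))
  if (length(condition) != ncol(values)) {
    stop("condition must have one label per sample")
  }
  structure(list(values = values, condition = condition),
            class = "smk_expression")
}

#' @export
print.smk_expression <- function(x, ...) {
  cat(sprintf("smk_expression: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$condition), collapse = "/")))
  invisible(x)
}

#' Read / write an expression matrix as TSV
#'
#' Layout: header row of sample ids, first column of gene ids. The
#' condition labels are stored in a `# condition:` comment line on write
#' and recovered on read (or supplied explicitly).
#'
#' @param path TSV file path.
#' @param condition optional condition labels overriding the file comment.
#' @return `read_expression_tsv` returns an `smk_expression`.
#' @export
read_expression_tsv <- function(path, condition = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(condition) && startsWith(first, "# condition:")) {
    condition <- strsplit(trimws(sub("# condition:", "", first)),
                          "\t")[[1]]
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df[[1]])
  if (is.null(condition)) condition <- "unknown"
  expression_matrix(values, condition)
}

#' @rdname read_expression_tsv
#' @param x an `smk_expression`.
#' @export
write_expression_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# condition:\t", paste(x$condition, collapse = "\t")),
             con)
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mutual information between two vectors
#'
#' Two estimators: `"gaussian"` gives \eqn{-\frac12 \ln(1 - r^2)} (nats)
#' with \eqn{r} the sample correlation clipped to \eqn{|r| \le 1 - 10^{-12}};
#' `"binned"` is the plug-in estimate on equal-width bins.
#'
#' @param x,y numeric vectors of equal length (at least 8).
#' @param estimator `"gaussian"` or `"binned"`.
#' @param bins number of equal-width bins for the binned estimator.
#' @return mutual information in nats.
#' @export
mutual_information <- function(x, y, estimator = c("gaussian", "binned"),
                               bins = 10) {
  estimator <- match.arg(estimator)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 8) stop("need at least 8 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input")
  }
  if (estimator == "gaussian") {
    r <- stats::cor(x, y)
    r <- max(min(r, 1 - 1e-12), -(1 - 1e-12))
    -0.5 * log(1 - r^2)
  } else {
    bx <- cut(x, breaks = bins, labels = FALSE, include.lowest = TRUE)
    by <- cut(y, breaks = bins, labels = FALSE, include.lowest = TRUE)
    pxy <- table(bx, by) / length(x)
    px <- rowSums(pxy); py <- colSums(pxy)
    pp <- as.vector(pxy)
    e <- outer(px, py)
    idx <- pp > 0
    sum(pp[idx] * log(pp[idx] / as.vector(e)[idx]))
  }
}

# all pairwise gaussian MIs of a genes-x-samples matrix (vectorised)
gaussian_mi_matrix <- function(values) {
  r <- stats::cor(t(values))
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  mi <- -0.5 * log(1 - r^2)
  diag(mi) <- 0
  mi
}

mi_matrix_of <- function(values, estimator, bins) {
  if (estimator == "gaussian") return(gaussian_mi_matrix(values))
  p <- nrow(values)
  mi <- matrix(0, p, p, dimnames = list(rownames(values), rownames(values)))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      mi[i, j] <- mi[j, i] <- mutual_information(values[i, ], values[j, ],
                                                 "binned", bins)
    }
  }
  mi
}

#' Conservative causal core (C3NET) network inference
#'
#' Estimates all pairwise mutual information values, determines a
#' significance threshold from a permutation null, and keeps for each gene
#' at most one edge: the one to its maximum-MI partner, retained iff that
#' MI is significant. The union over genes (undirected, de-duplicated) is
#' returned, so the output never has more edges than genes.
#'
#' Two permutation nulls are available. `"max"` (default) records, for each
#' of `n_permutations` sample-label permutations, the maximum MI over all
#' gene pairs; the threshold is the \eqn{(1-\alpha)} empirical quantile of
#' these maxima, which controls the family-wise error of the edge set.
#' `"pooled"` pools individual permuted pairwise MI values and thresholds
#' at their \eqn{(1-\alpha)} quantile (per-pair control only; liberal).
#'
#' @param x an `smk_expression`, or a genes x samples numeric matrix with
#'   rownames.
#' @param estimator MI estimator, see [mutual_information()].
#' @param alpha significance level in (0, 1).
#' @param n_permutations number of permutations for the null.
#' @param seed integer seed; the run is deterministic given the seed.
#' @param null `"max"` or `"pooled"`.
#' @param bins bins for the binned estimator.
#' @return an `smk_graph` whose vertices are all genes; the MI matrix,
#'   threshold and significance mask are attached as attributes
#'   `"mi"`, `"threshold"`, `"significant"`.
#' @export
infer_c3net <- function(x, estimator = c("gaussian", "binned"),
                        alpha = 0.05, n_permutations = 100, seed = 1,
                        null = c("max", "pooled"), bins = 10) {
  estimator <- match.arg(estimator)
  null <- match.arg(null)
  values <- if (inherits(x, "smk_expression")) x$values else as.matrix(x)
  if (is.null(rownames(values))) stop("gene rownames required")
  p <- nrow(values); n <- ncol(values)
  if (p < 2) stop("need at least 2 genes")
  if (n < 8) stop("need at least 8 samples")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  genes <- rownames(values)

  mi <- mi_matrix_of(values, estimator, bins)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  if (null == "max") {
    null_stat <- vapply(seq_len(n_permutations), function(b) {
      perm <- values
      for (i in seq_len(p)) perm[i, ] <- perm[i, sample.int(n)]
      max(mi_matrix_of(perm, estimator, bins))
    }, numeric(1))
  } else {
    null_stat <- vapply(seq_len(n_permutations), function(b) {
      ij <- sample.int(p, 2)
      mutual_information(values[ij[1], ],
                         values[ij[2], sample.int(n)], estimator, bins)
    }, numeric(1))
  }
  threshold <- stats::quantile(null_stat, 1 - alpha, names = FALSE)
  sig <- mi > threshold
  diag(sig) <- FALSE

  edges <- NULL
  for (i in seq_len(p)) {
    best <- max(mi[i, -i])
    # argmax partner, ties broken by lexicographically smallest gene id
    cand <- setdiff(genes[abs(mi[i, ] - best) == 0], genes[i])
    partner <- min(cand)
    if (sig[i, match(partner, genes)]) {
      edges <- rbind(edges, sort(c(genes[i], partner)))
    }
  }
  if (!is.null(edges)) edges <- unique(edges)
  g <- smk_graph(edges, vertices = genes)
  attr(g, "mi") <- mi
  attr(g, "threshold") <- threshold
  attr(g, "significant") <- sig
  g
}

# save/restore .Random.seed so seeded helpers do not disturb the caller
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
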