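#' Feature table with binary class labels
#'
#' Rows are instances (networks or samples), columns are features
#' (descriptors or genes). Rows containing non-finite values are dropped
#' with a message; both classes must remain non-empty.
#'
#' @param values numeric matrix; colnames are feature names.
#' @param labels binary class label per row.
#' @param row_ids optional row identifiers (default rownames or indices).
#' @return object of class `"smk_feature_table"`.
#' @export
feature_table <- function(values, labels, row_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  if (is.null(row_ids)) {
    row_ids <- if (!is.null(rownames(values))) rownames(values)
               else as.character(seq_len(nrow(values)))
  }
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  if (length(labels) != nrow(values)) stop("one label per row required")
  ok <- apply(values, 1, function(r) all(is.finite(r)))
  if (!all(ok)) {
    message(sprintf("dropping %d row(s) with undefined feature values: %s",
                    sum(!ok), paste(row_ids[!ok], collapse = ", ")))
    values <- values[ok, , drop = FALSE]
    labels <- droplevels(labels[ok])
    row_ids <- row_ids[ok]
    if (nlevels(labels) != 2) stop("a class became empty after dropping rows")
  }
  structure(list(values = values, labels = labels, row_ids = row_ids,
                 feature_names = colnames(values)),
            class = "smk_feature_table")
}

#' @export
print.smk_feature_table <- function(x, ...) {
  cat(sprintf("smk_feature_table: %d rows x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", levels(x$labels),
                            table(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Information gain of a feature about binary labels
#'
#' \eqn{H(\text{labels}) - H(\text{labels} \mid \text{feature})} in bits,
#' after discretising the feature into `n_bins` equal-frequency bins
#' (duplicate quantiles are collapsed, so fewer effective bins can result).
#'
#' @param feature numeric vector.
#' @param labels binary labels (same length).
#' @param n_bins number of equal-frequency bins (>= 2).
#' @return information gain in bits.
#' @export
information_gain <- function(feature, labels, n_bins = 10) {
  stopifnot(n_bins >= 2)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("labels are constant")
  br <- unique(stats::quantile(feature, probs = seq(0, 1, length.out =
                                                      n_bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) return(0)  # constant feature
  bins <- cut(feature, breaks = br, labels = FALSE, include.lowest = TRUE)
  h <- function(x) {
    p <- table(x) / length(x)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  hy <- h(labels)
  cond <- 0
  for (b in unique(bins)) {
    idx <- bins == b
    cond <- cond + mean(idx) * h(labels[idx])
  }
  hy - cond
}

#' Select the k most informative features
#'
#' Ranks features by [information_gain()] (ties broken by lexicographic
#' feature name) and keeps the top `k`. When used inside cross-validation,
#' call this on the training rows only — [cross_validated_svm()] does so
#' automatically via its `k_features` argument.
#'
#' @param table an `smk_feature_table`.
#' @param k number of features to keep (<= feature count).
#' @param n_bins bins for [information_gain()].
#' @return an `smk_feature_table` restricted to the selected features, in
#'   rank order; the gains are attached as attribute `"information_gain"`.
#' @export
select_top_k <- function(table, k, n_bins = 10) {
  stopifnot(k <= ncol(table$values))
  ig <- vapply(seq_len(ncol(table$values)), function(j) {
    information_gain(table$values[, j], table$labels, n_bins)
  }, numeric(1))
  names(ig) <- table$feature_names
  ord <- order(-ig, table$feature_names)
  keep <- ord[seq_len(k)]
  out <- feature_table(table$values[, keep, drop = FALSE], table$labels,
                       table$row_ids)
  attr(out, "information_gain") <- ig[keep]
  out
}

# macro-averaged binary classification metrics from predictions
confusion_metrics <- function(pred, truth) {
  lv <- levels(truth)
  per_class <- function(pos) {
    tp <- sum(pred == pos & truth == pos)
    fn <- sum(pred != pos & truth == pos)
    fp <- sum(pred == pos & truth != pos)
    tn <- sum(pred != pos & truth != pos)
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
    c(sensitivity = sens, specificity = spec, precision = prec,
      recall = sens, f_score = f1)
  }
  m <- (per_class(lv[1]) + per_class(lv[2])) / 2
  c(m[c("sensitivity", "specificity", "precision", "recall")],
    accuracy = mean(pred == truth), f_score = m[["f_score"]])
}

# stratified fold assignment (uses current RNG state)
stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Default hyperparameter grid for the polynomial-kernel SVM
#'
#' @param degree,cost,gamma,coef0 candidate values; the full cross product
#'   is searched, ties in inner accuracy resolved by grid order.
#' @return data.frame with one row per combination.
#' @export
svm_grid <- function(degree = c(1, 2, 3, 4), cost = c(0.1, 1, 10, 100),
                     gamma = c(0.001, 0.01, 0.1, 1), coef0 = 1) {
  expand.grid(degree = degree, cost = cost, gamma = gamma, coef0 = coef0,
              KEEP.OUT.ATTRS = FALSE)
}

#' Cross-validated polynomial-kernel SVM classification
#'
#' Stratified k-fold cross-validation. Inside each training fold: optional
#' information-gain selection of the top `k_features`, z-scoring on training
#' statistics, and exhaustive grid search scored by inner `inner_folds`-fold
#' accuracy. Nothing is fit on held-out rows, so there is no selection or
#' scaling leakage. Metrics are macro-averaged over the two classes, which
#' makes sensitivity, specificity and recall coincide by construction.
#'
#' @param table an `smk_feature_table`; each class must have at least
#'   `folds` rows.
#' @param grid data.frame from [svm_grid()].
#' @param folds number of outer folds (>= 2).
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @param k_features optional number of features to select per training
#'   fold (`NULL` = use all).
#' @param inner_folds folds for hyperparameter selection.
#' @param ig_bins bins for information gain.
#' @return object of class `"smk_cv_report"`: `per_fold` (data.frame of the
#'   six metrics plus chosen hyperparameters), `mean`, `se` (standard error
#'   = sd over folds / sqrt(folds)), `best` (modal hyperparameters), and
#'   call metadata.
#' @export
cross_validated_svm <- function(table, grid = svm_grid(), folds = 10,
                                seed = 1, k_features = NULL,
                                inner_folds = 3, ig_bins = 10) {
  stopifnot(folds >= 2)
  y <- table$labels
  if (any(table(y) < folds)) stop("each class needs at least `folds` rows")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  fold <- stratified_folds(y, folds)

  fit_eval <- function(xtr, ytr, xte, par) {
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
    xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    fit <- svm_train(xtr, ytr, cost = par$cost, gamma = par$gamma,
                     degree = par$degree, coef0 = par$coef0)
    predict(fit, xte)
  }

  metric_names <- c("sensitivity", "specificity", "precision", "recall",
                    "accuracy", "f_score")
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    xtr <- table$values[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    xte <- table$values[!tr, , drop = FALSE]; yte <- y[!tr]
    if (nlevels(ytr) < 2) stop("degenerate training fold (single class)")
    sel <- seq_len(ncol(xtr))
    if (!is.null(k_features) && k_features < ncol(xtr)) {
      sub <- select_top_k(feature_table(xtr, ytr), k_features, ig_bins)
      sel <- match(sub$feature_names, table$feature_names)
    }
    xtr_s <- xtr[, sel, drop = FALSE]
    xte_s <- xte[, sel, drop = FALSE]
    # inner grid search on the training fold only
    best_i <- 1
    if (nrow(grid) > 1) {
      infold <- stratified_folds(ytr, min(inner_folds, min(table(ytr))))
      acc <- vapply(seq_len(nrow(grid)), function(gi) {
        mean(vapply(unique(infold), function(g2) {
          itr <- infold != g2
          if (nlevels(droplevels(ytr[itr])) < 2) return(NA_real_)
          p <- fit_eval(xtr_s[itr, , drop = FALSE], ytr[itr],
                        xtr_s[!itr, , drop = FALSE], grid[gi, ])
          mean(p == ytr[!itr])
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1))
      best_i <- which.max(acc)
    }
    pred <- fit_eval(xtr_s, ytr, xte_s, grid[best_i, ])
    per_fold[[f]] <- c(confusion_metrics(pred, yte),
                       degree = grid$degree[best_i],
                       cost = grid$cost[best_i],
                       gamma = grid$gamma[best_i])
  }
  pf <- as.data.frame(do.call(rbind, per_fold))
  mu <- colMeans(pf[metric_names])
  se <- apply(pf[metric_names], 2, stats::sd) / sqrt(folds)
  best <- vapply(c("degree", "cost", "gamma"), function(p) {
    as.numeric(names(sort(-table(pf[[p]])))[1])
  }, numeric(1))
  structure(list(per_fold = pf, mean = mu, se = se, best = best,
                 folds = folds, seed = seed, k_features = k_features),
            class = "smk_cv_report")
}

#' @export
print.smk_cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$folds, x$seed))
  out <- data.frame(mean = round(x$mean, 3), sd_error = round(x$se, 3))
  print(out)
  invisible(x)
}

#' Serialise a CV report to JSON (metric x \{mean, sd_error\} layout)
#' @param report an `smk_cv_report`.
#' @param path output path.
#' @export
write_cv_report <- function(report, path) {
  obj <- list(
    metrics = lapply(stats::setNames(names(report$mean),
                                     names(report$mean)), function(m) {
      list(mean = report$mean[[m]], sd_error = report$se[[m]])
    }),
    best_parameters = as.list(report$best),
    folds = report$folds, seed = report$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
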