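# Soft-margin binary SVM with polynomial kernel, trained by sequential
# minimal optimisation (SMO). Self-contained because no SVM library is a
# declared dependency; sized for the small feature tables this package
# produces (hundreds of rows). Deterministic: the second working variable
# is chosen by the maximal-|E_i - E_j| heuristic with an ordered fallback
# scan, never randomly.

poly_kernel <- function(X1, X2, gamma, degree, coef0 = 1) {
  (gamma * tcrossprod(X1, X2) + coef0)^degree
}

#' Train a polynomial-kernel support vector machine
#'
#' Maximum-margin binary classifier with kernel
#' \eqn{K(x, y) = (\gamma x^\top y + c_0)^d}, solved by SMO.
#'
#' @param x numeric matrix, rows = instances.
#' @param y labels: factor with two levels, or a vector coercible to one.
#'   The first level is encoded as -1, the second as +1.
#' @param cost soft-margin cost C.
#' @param gamma kernel coefficient.
#' @param degree polynomial degree.
#' @param coef0 kernel offset.
#' @param tol KKT violation tolerance.
#' @param max_passes full no-change passes before convergence is declared.
#' @param max_iter hard cap on optimisation sweeps.
#' @return object of class `"smk_svm"`.
#' @export
svm_train <- function(x, y, cost = 1, gamma = 0.1, degree = 2, coef0 = 1,
                      tol = 1e-3, max_passes = 3, max_iter = 50) {
  x <- as.matrix(x)
  yf <- as.factor(y)
  if (nlevels(yf) != 2) stop("y must have exactly two classes")
  yy <- ifelse(as.integer(yf) == 1, -1, 1)
  n <- nrow(x)
  K <- poly_kernel(x, x, gamma, degree, coef0)
  alpha <- numeric(n)
  b <- 0
  E <- -yy  # f = 0 initially
  take_step <- function(i, j) {
    if (i == j) return(FALSE)
    ai <- alpha[i]; aj <- alpha[j]
    yi <- yy[i]; yj <- yy[j]
    if (yi != yj) {
      L <- max(0, aj - ai); H <- min(cost, cost + aj - ai)
    } else {
      L <- max(0, ai + aj - cost); H <- min(cost, ai + aj)
    }
    if (L >= H) return(FALSE)
    eta <- 2 * K[i, j] - K[i, i] - K[j, j]
    if (eta >= 0) return(FALSE)
    ajn <- aj - yj * (E[i] - E[j]) / eta
    ajn <- min(max(ajn, L), H)
    if (abs(ajn - aj) < 1e-8 * (ajn + aj + 1e-8)) return(FALSE)
    ain <- ai + yi * yj * (aj - ajn)
    b1 <- b - E[i] - yi * (ain - ai) * K[i, i] - yj * (ajn - aj) * K[i, j]
    b2 <- b - E[j] - yi * (ain - ai) * K[i, j] - yj * (ajn - aj) * K[j, j]
    bn <- if (ain > 0 && ain < cost) b1
          else if (ajn > 0 && ajn < cost) b2
          else (b1 + b2) / 2
    E <<- E + yi * (ain - ai) * K[, i] + yj * (ajn - aj) * K[, j] +
      (bn - b)
    alpha[i] <<- ain; alpha[j] <<- ajn; b <<- bn
    TRUE
  }
  passes <- 0; iter <- 0
  while (passes < max_passes && iter < max_iter) {
    iter <- iter + 1
    changed <- 0
    for (i in seq_len(n)) {
      r <- E[i] * yy[i]
      if ((r < -tol && alpha[i] < cost) || (r > tol && alpha[i] > 0)) {
        # second-choice heuristic: best |E_i - E_j| first, then a bounded
        # deterministic fallback scan
        j <- utils::head(order(-abs(E - E[i])), 12)
        ok <- FALSE
        for (jj in j) {
          if (take_step(i, jj)) { ok <- TRUE; break }
        }
        if (ok) changed <- changed + 1
      }
    }
    if (changed == 0) passes <- passes + 1 else passes <- 0
  }
  sv <- alpha > 1e-10
  structure(list(x_sv = x[sv, , drop = FALSE],
                 coef = (alpha * yy)[sv], b = b,
                 levels = levels(yf), gamma = gamma, degree = degree,
                 coef0 = coef0, cost = cost,
                 converged = passes >= max_passes),
            class = "smk_svm")
}

#' Predict with a trained SVM
#' @param object an `smk_svm`.
#' @param newdata numeric matrix of instances.
#' @param ... unused.
#' @return factor of predicted labels (decision values in attribute
#'   `"decision"`).
#' @export
predict.smk_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  f <- if (nrow(object$x_sv) == 0) rep(0, nrow(newdata)) else {
    as.vector(poly_kernel(newdata, object$x_sv, object$gamma,
                          object$degree, object$coef0) %*% object$coef)
  }
  f <- f + object$b
  lab <- factor(ifelse(f >= 0, object$levels[2], object$levels[1]),
                levels = object$levels)
  attr(lab, "decision") <- f
  lab
}
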