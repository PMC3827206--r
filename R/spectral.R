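#' Eigenvalue spectrum of a graph matrix
#'
#' Full real spectrum of the adjacency, distance or Laplacian matrix,
#' computed with a symmetric eigensolver (never via characteristic-polynomial
#' root finding, which is numerically unstable) and sorted non-increasing.
#'
#' @param mats an `smk_graph_matrices` object from [build_matrices()].
#' @param kind `"adjacency"`, `"distance"` or `"laplacian"`.
#' @return list of class `"smk_spectrum"` with `matrix_kind` and
#'   `eigenvalues` (non-increasing).
#' @export
graph_spectrum <- function(mats,
                           kind = c("adjacency", "distance", "laplacian")) {
  kind <- match.arg(kind)
  M <- mats[[kind]]
  if (max(abs(M - t(M))) > 1e-12) stop("matrix is not symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  structure(list(matrix_kind = kind,
                 eigenvalues = sort(ev, decreasing = TRUE)),
            class = "smk_spectrum")
}

# Estrada-type index sum(exp(ev)) in log-sum-exp form; beyond exp(700) the
# natural value would overflow, so the log-domain value is returned with a
# flag attribute.
estrada_sum <- function(ev) {
  m <- max(ev)
  lse <- m + log(sum(exp(ev - m)))
  if (lse > 700) {
    structure(lse, log_scale = TRUE)
  } else {
    structure(exp(lse), log_scale = FALSE)
  }
}

#' Names of the default eigenvalue-based descriptor battery
#'
#' Four adjacency-based, four distance-based and three Laplacian-based
#' measures (11 in total). The battery is configuration-driven: pass a
#' subset of these names to [spectral_descriptors()].
#' @return character vector of 11 measure names.
#' @export
spectral_battery <- function() {
  c("energy_adjacency", "estrada_adjacency", "spectral_radius_adjacency",
    "spectral_gap_adjacency",
    "energy_distance", "estrada_distance", "spectral_radius_distance",
    "min_eigenvalue_distance",
    "energy_laplacian", "estrada_laplacian", "algebraic_connectivity")
}

#' Eigenvalue-based structural descriptors
#'
#' The default battery:
#' adjacency spectrum \eqn{\lambda_i}: graph energy \eqn{\sum |\lambda_i|},
#' Estrada index \eqn{\sum e^{\lambda_i}}, spectral radius
#' \eqn{\lambda_1}, spectral gap \eqn{\lambda_1 - \lambda_2};
#' distance spectrum: distance energy, distance Estrada index, distance
#' spectral radius, smallest distance eigenvalue;
#' Laplacian spectrum \eqn{\mu_i}: Laplacian energy
#' \eqn{\sum |\mu_i - 2m/n|}, Laplacian Estrada index, algebraic
#' connectivity (second-smallest \eqn{\mu}).
#' Distance-based values follow the largest-component rule encoded in
#' `mats`.
#'
#' @param mats an `smk_graph_matrices` object.
#' @param battery character vector of measure names (subset of
#'   [spectral_battery()]); order is preserved in the output.
#' @return named numeric vector (one finite value per measure; Estrada
#'   indices switch to log-domain with an `"estrada_log_scale"` attribute
#'   when \eqn{\lambda_1 > 700}).
#' @export
spectral_descriptors <- function(mats, battery = spectral_battery()) {
  stopifnot(all(battery %in% spectral_battery()))
  evA <- graph_spectrum(mats, "adjacency")$eigenvalues
  evD <- graph_spectrum(mats, "distance")$eigenvalues
  evL <- graph_spectrum(mats, "laplacian")$eigenvalues
  n <- length(evA)
  m <- graph_size(mats$graph)
  eA <- estrada_sum(evA); eD <- estrada_sum(evD); eL <- estrada_sum(evL)
  vals <- c(
    energy_adjacency = sum(abs(evA)),
    estrada_adjacency = as.numeric(eA),
    spectral_radius_adjacency = evA[1],
    spectral_gap_adjacency = if (n >= 2) evA[1] - evA[2] else 0,
    energy_distance = sum(abs(evD)),
    estrada_distance = as.numeric(eD),
    spectral_radius_distance = evD[1],
    min_eigenvalue_distance = evD[length(evD)],
    energy_laplacian = sum(abs(evL - 2 * m / n)),
    estrada_laplacian = as.numeric(eL),
    algebraic_connectivity = sort(evL)[min(2, n)]
  )
  out <- vals[battery]
  flags <- c(estrada_adjacency = attr(eA, "log_scale"),
             estrada_distance = attr(eD, "log_scale"),
             estrada_laplacian = attr(eL, "log_scale"))
  if (any(flags)) attr(out, "estrada_log_scale") <- names(flags)[flags]
  out
}

#' Sign distribution of a spectrum
#'
#' Fractions of negative and positive eigenvalues among those whose modulus
#' exceeds `zero_tol` (near-zero eigenvalues are excluded from the
#' denominator).
#'
#' @param spec an `smk_spectrum`, or a numeric vector of eigenvalues.
#' @param zero_tol non-negative tolerance below which an eigenvalue counts
#'   as zero.
#' @return named numeric vector `c(fraction_negative, fraction_positive)`.
#' @export
sign_ratio <- function(spec, zero_tol = 1e-9) {
  stopifnot(zero_tol >= 0)
  ev <- if (inherits(spec, "smk_spectrum")) spec$eigenvalues else spec
  ev <- ev[abs(ev) > zero_tol]
  if (length(ev) == 0) stop("all eigenvalues are within zero_tol of zero")
  c(fraction_negative = mean(ev < 0), fraction_positive = mean(ev > 0))
}
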