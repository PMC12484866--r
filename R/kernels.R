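#' Multi-component Gaussian space kernel
#'
#' A spatial reproducing kernel \eqn{K_\sigma(x,y) = \sum_c c_w \exp(-\|x-y\|^2
#' / (2\sigma_c^2))}.  Several components may be mixed, e.g. a sum of two
#' Gaussians at 0.15 and 0.75 mm bandwidth for brain-scale matching.  All
#' bandwidths are in millimeters, the package's internal length unit.
#'
#' @param sigma numeric vector of bandwidths in mm, all > 0.
#' @param weight numeric vector of nonnegative component weights, recycled to
#'   `length(sigma)`.  The kernel value at zero distance is `sum(weight)`.
#' @return an object of class `space_kernel`.
#' @examples
#' ks <- space_kernel(c(0.15, 0.75))
#' space_kernel_eval(ks, c(0, 0, 0), c(0, 0, 0))  # = 2
#' @export
space_kernel <- function(sigma, weight = 1) {
  sigma <- as.numeric(sigma)
  weight <- rep_len(as.numeric(weight), length(sigma))
  if (length(sigma) < 1L) stop("space_kernel needs at least one component")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("all kernel bandwidths must be finite and > 0")
  }
  if (any(!is.finite(weight)) || any(weight < 0)) {
    stop("kernel component weights must be finite and >= 0")
  }
  structure(list(sigma = sigma, weight = weight), class = "space_kernel")
}

#' @export
print.space_kernel <- function(x, ...) {
  cat("Gaussian space kernel:",
      paste(sprintf("%g mm (w=%g)", x$sigma, x$weight), collapse = " + "),
      "\n")
  invisible(x)
}

#' Feature kernel on the feature space
#'
#' For discrete labels the identity (indicator) kernel is used:
#' \eqn{K_F(f,g) = 1} iff \eqn{f = g}.  For real-valued feature vectors the
#' plain Euclidean inner product is used.  In both cases the double sum
#' \eqn{\sum_{f,g} K_F(f,g) p_i(f) p_j(g)} reduces to the dot product of the
#' per-particle feature vectors, which is how it is evaluated.
#'
#' @param kind `"identity"` (discrete labels) or `"euclidean"` (real-valued
#'   feature vectors).
#' @return an object of class `feature_kernel`.
#' @export
feature_kernel <- function(kind = c("identity", "euclidean")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "feature_kernel")
}

#' @export
print.feature_kernel <- function(x, ...) {
  cat("Feature kernel:", x$kind, "\n")
  invisible(x)
}

#' Evaluate the space kernel between two points
#'
#' @param kernel a [space_kernel()].
#' @param x,y numeric 3-vectors (mm).
#' @return scalar kernel value; symmetric in `x`, `y`.
#' @export
space_kernel_eval <- function(kernel, x, y) {
  stopifnot(inherits(kernel, "space_kernel"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have the same dimension")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite coordinates are not allowed")
  }
  r2 <- sum((x - y)^2)
  sum(kernel$weight * exp(-r2 / (2 * kernel$sigma^2)))
}

#' Space-kernel Gram matrix between two point sets
#'
#' Computes \eqn{K[i,j] = K_\sigma(X_i, Y_j)}.  With a finite `truncate`
#' radius, entries between points farther apart than the radius are set to
#' zero without evaluation; the exact (untruncated) form is the default.
#'
#' @param kernel a [space_kernel()].
#' @param X,Y numeric matrices (n x d), rows are points.
#' @param truncate truncation radius in mm (`Inf` for exact evaluation).
#' @return an n x m numeric matrix.
#' @export
kernel_matrix <- function(kernel, X, Y = X, truncate = Inf) {
  stopifnot(inherits(kernel, "space_kernel"))
  X <- as_point_matrix(X); Y <- as_point_matrix(Y)
  D2 <- pairwise_sq_dist(X, Y)
  K <- matrix(0, nrow(X), nrow(Y))
  for (c in seq_along(kernel$sigma)) {
    K <- K + kernel$weight[c] * exp(-D2 / (2 * kernel$sigma[c]^2))
  }
  if (is.finite(truncate)) K[D2 > truncate^2] <- 0
  K
}

## squared Euclidean distances between rows of X and rows of Y
pairwise_sq_dist <- function(X, Y) {
  nx <- rowSums(X^2)
  ny <- rowSums(Y^2)
  D2 <- outer(nx, ny, "+") - 2 * tcrossprod(X, Y)
  D2[D2 < 0] <- 0  # numerical guard
  D2
}

as_point_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}
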