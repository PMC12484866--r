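#' Particle measure (image varifold)
#'
#' A finite measure on position x feature space,
#' \eqn{\mu = \sum_i w_i \delta_{x_i} \otimes p_i}: each particle carries a
#' nonnegative mass `w_i` at a 3D position `x_i` (mm) and a feature
#' distribution `p_i` over a shared, ordered feature space.  Feature rows may
#' be stored normalized (each summing to 1) or unnormalized (weighted laws
#' `w_i p_i` stored directly); the flag is recorded and no silent
#' renormalization is ever performed.
#'
#' @param positions n x 3 numeric matrix of positions in mm (a 2-column
#'   matrix is padded with z = 0).
#' @param weights numeric vector of nonnegative particle masses.
#' @param features either an n x F numeric matrix of feature distributions
#'   (column names are the feature labels) or a character/factor vector of
#'   length n of discrete labels, expanded to one-hot rows.
#' @param labels optional character vector of feature labels overriding
#'   column names.
#' @param normalized logical flag: are the feature rows probability
#'   distributions?  Default `NA` auto-detects (TRUE when every row sums to 1
#'   within 1e-9).
#' @param kind feature-space kind, `"discrete"` or `"real"`.
#' @return an object of class `particle_measure` with fields `positions`,
#'   `weights`, `features`, `labels`, `normalized`, `kind`.
#' @examples
#' mu <- particle_measure(matrix(rnorm(9), 3, 3), rep(1, 3),
#'                        c("Gfap", "Wipf3", "Gfap"))
#' total_mass(mu)
#' @export
particle_measure <- function(positions, weights, features,
                             labels = NULL, normalized = NA,
                             kind = c("discrete", "real")) {
  kind <- match.arg(kind)
  positions <- as_point_matrix(positions)
  if (ncol(positions) == 2L) positions <- cbind(positions, 0)
  if (ncol(positions) != 3L) stop("positions must have 2 or 3 columns")
  if (any(!is.finite(positions))) stop("non-finite particle positions")
  n <- nrow(positions)
  weights <- as.numeric(weights)
  if (length(weights) == 1L) weights <- rep(weights, n)
  if (length(weights) != n) stop("weights length must match particle count")
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("particle weights must be finite and >= 0")
  }
  if (is.character(features) || is.factor(features)) {
    features <- one_hot(as.character(features), labels)
  } else {
    features <- as.matrix(features)
    storage.mode(features) <- "double"
    if (!is.null(labels)) colnames(features) <- labels
    if (is.null(colnames(features))) {
      colnames(features) <- paste0("f", seq_len(ncol(features)))
    }
  }
  if (nrow(features) != n) stop("feature rows must match particle count")
  if (anyDuplicated(colnames(features))) stop("feature labels must be unique")
  if (ncol(features) < 1L) stop("feature space must be non-empty")
  if (is.na(normalized)) {
    normalized <- all(abs(rowSums(features) - 1) < 1e-9)
  }
  if (isTRUE(normalized) && any(abs(rowSums(features) - 1) > 1e-9)) {
    stop("normalized = TRUE but feature rows do not sum to 1 within 1e-9")
  }
  structure(
    list(positions = positions, weights = weights, features = features,
         labels = colnames(features), normalized = normalized, kind = kind),
    class = "particle_measure"
  )
}

one_hot <- function(x, labels = NULL) {
  if (is.null(labels)) labels <- sort(unique(x))
  if (!all(x %in% labels)) stop("labels do not cover all observed features")
  m <- matrix(0, length(x), length(labels),
              dimnames = list(NULL, labels))
  m[cbind(seq_along(x), match(x, labels))] <- 1
  m
}

#' @export
print.particle_measure <- function(x, ...) {
  cat(sprintf(
    "particle_measure: %d particles, %d features (%s, %s), total mass %g\n",
    n_particles(x), length(x$labels), x$kind,
    if (x$normalized) "normalized" else "unnormalized", total_mass(x)))
  invisible(x)
}

#' @rdname particle_measure
#' @param mu a `particle_measure`.
#' @export
n_particles <- function(mu) nrow(mu$positions)

#' @rdname particle_measure
#' @export
total_mass <- function(mu) sum(mu$weights)

#' Weighted feature laws of a measure
#'
#' Returns the n x F matrix of `w_i p_i` rows, the representation the
#' varifold inner product, resampling and atlas laws all operate on.
#' @param mu a [particle_measure()].
#' @keywords internal
weighted_features <- function(mu) mu$features * mu$weights

same_feature_space <- function(mu, nu) {
  identical(mu$labels, nu$labels)
}

#' Sampled diffeomorphism
#'
#' The action of a diffeomorphism on a particle measure only needs the mapped
#' positions \eqn{\varphi(x_i)} and Jacobian determinants
#' \eqn{|D\varphi|_{x_i}} at the particles.
#'
#' @param positions n x 3 matrix of mapped positions \eqn{\varphi(x_i)}.
#' @param jacobians length-n vector of Jacobian determinants, all > 0.
#' @return an object of class `diffeo_sample`.
#' @export
diffeo_sample <- function(positions, jacobians) {
  positions <- as_point_matrix(positions)
  if (ncol(positions) == 2L) positions <- cbind(positions, 0)
  jacobians <- as.numeric(jacobians)
  if (length(jacobians) == 1L) jacobians <- rep(jacobians, nrow(positions))
  if (length(jacobians) != nrow(positions)) {
    stop("jacobians length must match mapped positions")
  }
  if (any(!is.finite(jacobians)) || any(jacobians <= 0)) {
    stop("Jacobian determinants must be finite and > 0 (orientation-preserving)")
  }
  structure(list(positions = positions, jacobians = jacobians),
            class = "diffeo_sample")
}

#' Varifold inner product between two particle measures
#'
#' \deqn{\langle\mu,\nu\rangle_M = \sum_{i,j} w_i w_j K_\sigma(x_i, x_j)
#'   \sum_{f,g} K_F(f,g) p_i(f) p_j(g).}
#' Feature distributions are used as stored (normalized or not).
#'
#' @param mu,nu [particle_measure()] objects over the same feature space.
#' @param ks a [space_kernel()].
#' @param kf a [feature_kernel()]; both kinds reduce to the dot product of
#'   feature rows.
#' @param truncate optional kernel truncation radius in mm (default exact).
#' @return scalar inner product.
#' @export
varifold_inner_product <- function(mu, nu, ks, kf = feature_kernel(),
                                   truncate = Inf) {
  stopifnot(inherits(mu, "particle_measure"), inherits(nu, "particle_measure"))
  if (!same_feature_space(mu, nu)) {
    stop("measures do not share a feature space")
  }
  K <- kernel_matrix(ks, mu$positions, nu$positions, truncate = truncate)
  P <- tcrossprod(mu$features, nu$features)
  as.numeric(mu$weights %*% (K * P) %*% nu$weights)
}

#' Squared varifold norm distance
#'
#' \deqn{\|\mu-\nu\|_M^2 = \langle\mu,\mu\rangle - 2\langle\mu,\nu\rangle +
#'   \langle\nu,\nu\rangle \ge 0.}
#' @inheritParams varifold_inner_product
#' @return nonnegative scalar (up to ~1e-9 numerical slack).
#' @export
varifold_norm_dist2 <- function(mu, nu, ks, kf = feature_kernel(),
                                truncate = Inf) {
  varifold_inner_product(mu, mu, ks, kf, truncate) -
    2 * varifold_inner_product(mu, nu, ks, kf, truncate) +
    varifold_inner_product(nu, nu, ks, kf, truncate)
}

#' Varifold action of a diffeomorphism on a measure
#'
#' \deqn{\varphi\cdot\mu = \sum_i |D\varphi|_{x_i} w_i
#'   \delta_{\varphi(x_i)} \otimes p_i:}
#' positions are mapped, masses are multiplied by the local volume change,
#' feature distributions are transported unchanged.
#'
#' @param mu a [particle_measure()].
#' @param phi a [diffeo_sample()] with one row per particle of `mu`.
#' @return the transported `particle_measure`.
#' @export
apply_varifold_action <- function(mu, phi) {
  stopifnot(inherits(mu, "particle_measure"), inherits(phi, "diffeo_sample"))
  if (nrow(phi$positions) != n_particles(mu)) {
    stop("diffeo sample length does not match the measure")
  }
  particle_measure(phi$positions, phi$jacobians * mu$weights, mu$features,
                   normalized = mu$normalized, kind = mu$kind)
}

## restrict a measure to a subset of particles
subset_measure <- function(mu, idx) {
  particle_measure(mu$positions[idx, , drop = FALSE], mu$weights[idx],
                   mu$features[idx, , drop = FALSE],
                   normalized = mu$normalized, kind = mu$kind)
}
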