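#' Section stack for rigid alignment
#'
#' An ordered stack of 2D particle measures (sections), each centered at its
#' own origin on load, with a fixed inter-section spacing.
#'
#' @param sections list of [particle_measure()] objects with z ignored
#'   (2D positions).
#' @param spacing inter-section spacing in mm (bookkeeping).
#' @param center if `TRUE` (default) each section is recentered at its
#'   mass-weighted centroid.
#' @return object of class `section_stack`.
#' @export
section_stack <- function(sections, spacing = 0.2, center = TRUE) {
  if (length(sections) < 2L) stop("a stack needs at least two sections")
  lab <- sections[[1]]$labels
  sections <- lapply(sections, function(s) {
    stopifnot(inherits(s, "particle_measure"))
    if (!identical(s$labels, lab)) stop("sections must share a feature space")
    if (center) {
      ctr <- colSums(s$positions[, 1:2, drop = FALSE] * s$weights) /
        sum(s$weights)
      s$positions[, 1] <- s$positions[, 1] - ctr[1]
      s$positions[, 2] <- s$positions[, 2] - ctr[2]
    }
    s$positions[, 3] <- 0
    s
  })
  structure(list(sections = sections, spacing = spacing),
            class = "section_stack")
}

#' Apply an in-plane rigid motion to a section
#'
#' Positions are rotated by \eqn{R_\theta} then translated by \eqn{\tau};
#' weights and feature laws are untouched.
#'
#' @param section a [particle_measure()] (z ignored).
#' @param theta rotation angle in radians.
#' @param tau 2D translation (mm).
#' @return the moved [particle_measure()].
#' @export
apply_rigid <- function(section, theta, tau = c(0, 0)) {
  xy <- section$positions[, 1:2, drop = FALSE]
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  xy <- xy %*% t(R)
  xy[, 1] <- xy[, 1] + tau[1]
  xy[, 2] <- xy[, 2] + tau[2]
  particle_measure(cbind(xy, section$positions[, 3]), section$weights,
                   section$features, normalized = section$normalized,
                   kind = section$kind)
}

#' Rigid alignment of a section stack
#'
#' Estimates per-section rotations and in-plane translations for the
#' interior sections (the first and last are fixed at identity), jointly
#' minimizing the sum of adjacent-pair squared varifold distances by
#' L-BFGS-B.  Discrete labels use the identity feature kernel.
#'
#' @param stack a [section_stack()] with at least 3 sections.
#' @param ks a [space_kernel()]; default a single Gaussian at twice the
#'   median nearest-neighbor distance of the first section.
#' @param max_iter optimizer budget (default 200).
#' @return object of class `rigid_params`: data.frame with per-section
#'   `theta` (radians, in `(-pi, pi]`) and `tau_x`, `tau_y`; the aligned
#'   stack is attached as `attr(, "aligned")` and the objective values at
#'   identity and optimum as attributes.
#' @export
align_stack <- function(stack, ks = NULL, max_iter = 200L) {
  stopifnot(inherits(stack, "section_stack"))
  N <- length(stack$sections)
  if (N < 3L) stop("alignment needs at least 3 sections (ends are fixed)")
  if (is.null(ks)) {
    ks <- space_kernel(2 * median_nn_dist(stack$sections[[1]]$positions))
  }
  free <- 2:(N - 1)
  par_of <- function(par) {
    m <- matrix(par, ncol = 3)  # theta, tau_x, tau_y per free section
    m
  }
  moved <- function(par) {
    m <- par_of(par)
    secs <- stack$sections
    for (k in seq_along(free)) {
      secs[[free[k]]] <- apply_rigid(secs[[free[k]]], m[k, 1], m[k, 2:3])
    }
    secs
  }
  objective <- function(par) {
    secs <- moved(par)
    s <- 0
    for (n in seq_len(N - 1)) {
      s <- s + varifold_norm_dist2(secs[[n]], secs[[n + 1]], ks)
    }
    s
  }
  obj0 <- objective(rep(0, 3 * length(free)))
  fit <- stats::optim(rep(0, 3 * length(free)), objective,
                      method = "L-BFGS-B",
                      control = list(maxit = max_iter))
  if (!is.finite(fit$value)) {
    stop("stack alignment diverged; identity objective was ", obj0)
  }
  m <- par_of(fit$par)
  theta <- numeric(N); taux <- numeric(N); tauy <- numeric(N)
  theta[free] <- wrap_angle(m[, 1])
  taux[free] <- m[, 2]; tauy[free] <- m[, 3]
  out <- data.frame(section = seq_len(N), theta = theta,
                    tau_x = taux, tau_y = tauy)
  class(out) <- c("rigid_params", class(out))
  attr(out, "aligned") <- section_stack(moved(fit$par),
                                        spacing = stack$spacing,
                                        center = FALSE)
  attr(out, "objective") <- fit$value
  attr(out, "objective_identity") <- obj0
  out
}

wrap_angle <- function(th) {
  out <- (th + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

median_nn_dist <- function(X) {
  D2 <- pairwise_sq_dist(X, X)
  diag(D2) <- Inf
  stats::median(sqrt(apply(D2, 1, min)))
}
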