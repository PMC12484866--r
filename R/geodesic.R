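#' Flow kernel controlling deformation smoothness
#'
#' Single-component Gaussian kernel \eqn{k_\sigma(x,y) = c\,\exp(-\|x-y\|^2 /
#' (2\sigma_V^2))} generating the velocity fields of the diffeomorphism flow.
#' The bandwidth \eqn{\sigma_V} (mm) sets the spatial scale of deformation.
#'
#' @param sigma bandwidth in mm, > 0.
#' @param weight kernel amplitude (default 1).
#' @return object of class `flow_kernel`.
#' @export
flow_kernel <- function(sigma, weight = 1) {
  sigma <- as.numeric(sigma)[1]
  if (!is.finite(sigma) || sigma <= 0) stop("flow kernel bandwidth must be > 0")
  structure(list(sigma = sigma, weight = as.numeric(weight)[1]),
            class = "flow_kernel")
}

#' Geodesic state of the particle system
#'
#' The state carries particle positions and weights \eqn{q = (x_i, w_i)}
#' together with the conjugate space momenta \eqn{\rho^x_i} (3-vectors) and
#' mass momenta \eqn{\rho^w_i} (scalars) that drive the Hamiltonian dynamics
#' of geodesic shooting.
#'
#' @param positions n x 3 matrix (mm).
#' @param weights length-n nonnegative masses.
#' @param rho_x n x 3 matrix of space momenta (default zero).
#' @param rho_w length-n vector of mass momenta (default zero).
#' @param time scalar time in `[0, 1]` (bookkeeping only).
#' @return object of class `geodesic_state`.
#' @export
geodesic_state <- function(positions, weights, rho_x = NULL, rho_w = NULL,
                           time = 0) {
  positions <- as_point_matrix(positions)
  if (ncol(positions) == 2L) positions <- cbind(positions, 0)
  n <- nrow(positions)
  weights <- as.numeric(weights)
  if (length(weights) == 1L) weights <- rep(weights, n)
  if (is.null(rho_x)) rho_x <- matrix(0, n, 3)
  if (is.null(rho_w)) rho_w <- rep(0, n)
  rho_x <- as_point_matrix(rho_x)
  rho_w <- as.numeric(rho_w)
  if (nrow(rho_x) != n || length(rho_w) != n || length(weights) != n) {
    stop("state arrays must share the particle count")
  }
  if (any(weights < 0)) stop("weights must be >= 0 along the flow")
  structure(list(positions = positions, weights = weights,
                 rho_x = rho_x, rho_w = rho_w, time = time),
            class = "geodesic_state")
}

## Gaussian kernel matrix and squared distances for the flow kernel
flow_K <- function(fk, X, Y = X) {
  D2 <- pairwise_sq_dist(as_point_matrix(X), as_point_matrix(Y))
  list(K = fk$weight * exp(-D2 / (2 * fk$sigma^2)), D2 = D2)
}

#' Velocity field of the momentum-parameterized flow
#'
#' \deqn{v(x) = \sum_i k_\sigma(x, x_i)\,\rho^x_i +
#'   \frac{x - x_i}{\sigma^2} w_i \rho^w_i k_\sigma(x, x_i).}
#'
#' @param state a [geodesic_state()].
#' @param fk a [flow_kernel()].
#' @param query m x 3 matrix of evaluation points (default: the particles).
#' @return m x 3 matrix of velocities.
#' @export
velocity_field <- function(state, fk, query = state$positions) {
  Q <- as_point_matrix(query)
  if (ncol(Q) == 2L) Q <- cbind(Q, 0)
  X <- state$positions
  a <- state$rho_x
  b <- state$weights * state$rho_w
  s2 <- fk$sigma^2
  K <- flow_K(fk, Q, X)$K
  Kb <- drop(K %*% b)
  K %*% a + (Q * Kb - K %*% (X * b)) / s2
}

#' Divergence of the velocity field
#'
#' Analytic divergence of the Gaussian-kernel velocity field:
#' \deqn{\mathrm{div}\,v(x) = \sum_i k(x,x_i)\Big[-\frac{(x-x_i)\cdot\rho^x_i}
#'   {\sigma^2} + \frac{w_i\rho^w_i}{\sigma^2}\Big(3 -
#'   \frac{\|x-x_i\|^2}{\sigma^2}\Big)\Big].}
#'
#' @inheritParams velocity_field
#' @return length-m vector of divergences.
#' @export
velocity_divergence <- function(state, fk, query = state$positions) {
  Q <- as_point_matrix(query)
  if (ncol(Q) == 2L) Q <- cbind(Q, 0)
  X <- state$positions
  a <- state$rho_x
  b <- state$weights * state$rho_w
  s2 <- fk$sigma^2
  kk <- flow_K(fk, Q, X)
  K <- kk$K
  ## -(x - x_i).a_i / s2 summed against K
  t1 <- -(rowSums(Q * (K %*% a)) - drop(K %*% rowSums(X * a))) / s2
  t2 <- (3 * drop(K %*% b) - drop((K * kk$D2) %*% b) / s2) / s2
  t1 + t2
}

#' Hamiltonian of the geodesic particle system
#'
#' For the optimal velocity (the kernel field of [velocity_field()]) the
#' Hamiltonian reduces to
#' \eqn{H(q,\rho) = \tfrac12\sum_i \rho^x_i\cdot v(x_i) +
#'   \rho^w_i\,\mathrm{div}\,v(x_i)\,w_i = \tfrac12\|v\|_V^2},
#' conserved along geodesics.
#'
#' @inheritParams velocity_field
#' @return scalar Hamiltonian value.
#' @export
hamiltonian <- function(state, fk) {
  v <- velocity_field(state, fk)
  dv <- velocity_divergence(state, fk)
  0.5 * (sum(state$rho_x * v) + sum(state$weights * state$rho_w * dv))
}

## analytic position-gradient of the reduced Hamiltonian (n x 3),
## verified against central finite differences in the test suite
grad_x_hamiltonian <- function(state, fk) {
  X <- state$positions
  a <- state$rho_x
  b <- state$weights * state$rho_w
  s2 <- fk$sigma^2
  kk <- flow_K(fk, X, X)
  K <- kk$K; D2 <- kk$D2
  AAt <- tcrossprod(a)                # a_m . a_j
  XA <- tcrossprod(X, a)              # X_m . a_j
  s <- rowSums(X * a)                 # X_j . a_j
  ## coefficient of d_mj = X_m - X_j in grad_{x_m} H
  Cd <- K * (-AAt / s2 +
               (outer(b, -s, "*") + b * XA -
                  tcrossprod(rep(1, nrow(X)), b) * (s - t(XA))) / s2^2 -
               outer(b, b) * (5 - D2 / s2) / s2^2)
  gd <- X * rowSums(Cd) - Cd %*% X
  gv <- (a * drop(K %*% b) - b * (K %*% a)) / s2
  gd + gv
}

## time derivative of the full augmented state (positions, weights, momenta,
## passive points and their log-Jacobian surrogate); kernel pieces are
## computed once and shared between v, div v and grad_x H
geodesic_rhs <- function(state, fk, passive = NULL) {
  X <- state$positions
  a <- state$rho_x
  b <- state$weights * state$rho_w
  s2 <- fk$sigma^2
  kk <- flow_K(fk, X, X)
  K <- kk$K; D2 <- kk$D2
  Kb <- drop(K %*% b)
  Ka <- K %*% a
  KXb <- K %*% (X * b)
  v <- Ka + (X * Kb - KXb) / s2
  sXa <- rowSums(X * a)
  dv <- -(rowSums(X * Ka) - drop(K %*% sXa)) / s2 +
    (3 * Kb - drop((K * D2) %*% b) / s2) / s2
  AAt <- tcrossprod(a)
  XA <- tcrossprod(X, a)
  Cd <- K * (-AAt / s2 +
               (outer(b, -sXa, "*") + b * XA -
                  tcrossprod(rep(1, nrow(X)), b) * (sXa - t(XA))) / s2^2 -
               outer(b, b) * (5 - D2 / s2) / s2^2)
  gx <- (X * rowSums(Cd) - Cd %*% X) + (a * Kb - b * Ka) / s2
  out <- list(
    dx = v,
    dw = dv * state$weights,
    drho_x = -gx,
    drho_w = -state$rho_w * dv,
    djac = dv  # d/dt log|Dphi| at the particles
  )
  if (!is.null(passive)) {
    out$dpassive <- velocity_field(state, fk, passive)
    out$dpass_jac <- velocity_divergence(state, fk, passive)
  }
  out
}

#' Geodesic shooting of the Hamiltonian particle system
#'
#' Integrates the geodesic equations
#' \eqn{\dot x_i = v(x_i)}, \eqn{\dot w_i = \mathrm{div}(v(x_i)) w_i},
#' \eqn{\dot\rho_i = -\nabla_{q_i} H} from `t = 0` to `t = 1` with fixed-step
#' RK4.  Jacobian determinants at the particle positions are integrated
#' alongside via \eqn{d\log|D\varphi|/dt = \mathrm{div}\,v}.
#'
#' @param initial a [geodesic_state()] at `t = 0`.
#' @param fk a [flow_kernel()].
#' @param n_steps number of RK4 steps (>= 1).
#' @param passive optional m x 3 matrix of extra points advected by the flow
#'   (without momenta of their own).
#' @param keep_trajectory if `TRUE`, return the state at every step.
#' @return a list with `final` ([geodesic_state()] at t = 1), `phi` (a
#'   [diffeo_sample()] at the control particles), `passive` and
#'   `passive_jacobians` (if requested), `hamiltonian` (value at t = 0) and
#'   optionally `trajectory`.
#' @export
shoot <- function(initial, fk, n_steps = 10L, passive = NULL,
                  keep_trajectory = FALSE) {
  stopifnot(inherits(initial, "geodesic_state"), inherits(fk, "flow_kernel"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  h <- 1 / n_steps
  st <- initial
  logjac <- rep(0, n_particles_state(st))
  if (!is.null(passive)) {
    passive <- as_point_matrix(passive)
    if (ncol(passive) == 2L) passive <- cbind(passive, 0)
    pass_logjac <- rep(0, nrow(passive))
  }
  H0 <- hamiltonian(initial, fk)
  traj <- if (keep_trajectory) vector("list", n_steps + 1L) else NULL
  if (keep_trajectory) traj[[1L]] <- st

  pack <- function(st, lj, pv, plj) list(st = st, lj = lj, pv = pv, plj = plj)
  rhs_of <- function(z) {
    r <- geodesic_rhs(z$st, fk, passive = z$pv)
    r
  }
  step_state <- function(z, r, fac) {
    st2 <- z$st
    st2$positions <- z$st$positions + fac * r$dx
    st2$weights <- pmax(z$st$weights + fac * r$dw, 0)
    st2$rho_x <- z$st$rho_x + fac * r$drho_x
    st2$rho_w <- z$st$rho_w + fac * r$drho_w
    lj <- z$lj + fac * r$djac
    pv <- if (is.null(z$pv)) NULL else z$pv + fac * r$dpassive
    plj <- if (is.null(z$pv)) NULL else z$plj + fac * r$dpass_jac
    pack(st2, lj, pv, plj)
  }
  z <- pack(st, logjac, passive, if (is.null(passive)) NULL else pass_logjac)
  for (step in seq_len(n_steps)) {
    k1 <- rhs_of(z)
    k2 <- rhs_of(step_state(z, k1, h / 2))
    k3 <- rhs_of(step_state(z, k2, h / 2))
    k4 <- rhs_of(step_state(z, k3, h))
    comb <- function(f) {
      a1 <- k1[[f]]
      if (is.null(a1)) return(NULL)
      (a1 + 2 * k2[[f]] + 2 * k3[[f]] + k4[[f]]) * (h / 6)
    }
    z$st$positions <- z$st$positions + comb("dx")
    z$st$weights <- pmax(z$st$weights + comb("dw"), 0)
    z$st$rho_x <- z$st$rho_x + comb("drho_x")
    z$st$rho_w <- z$st$rho_w + comb("drho_w")
    z$lj <- z$lj + comb("djac")
    if (!is.null(z$pv)) {
      z$pv <- z$pv + comb("dpassive")
      z$plj <- z$plj + comb("dpass_jac")
    }
    z$st$time <- step * h
    if (any(!is.finite(z$st$positions)) || any(!is.finite(z$st$rho_x))) {
      stop(sprintf("geodesic integration blew up at step %d/%d",
                   step, n_steps))
    }
    if (keep_trajectory) traj[[step + 1L]] <- z$st
  }
  out <- list(
    final = z$st,
    phi = diffeo_sample(z$st$positions, exp(z$lj)),
    hamiltonian = H0
  )
  if (!is.null(passive)) {
    out$passive <- z$pv
    out$passive_jacobians <- exp(z$plj)
  }
  if (keep_trajectory) out$trajectory <- traj
  out
}

n_particles_state <- function(state) nrow(state$positions)
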