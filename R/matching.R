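#' Atlas measure with region memberships and latent feature laws
#'
#' A tissue-scale atlas represented as a particle measure over the region
#' ontology: each particle carries a membership distribution
#' \eqn{\pi_i(\ell)} over region labels, and each region \eqn{\ell} carries
#' an (unnormalized) latent law \eqn{p_\ell} over the target feature space,
#' to be estimated jointly with the deformation.  The induced measure is
#' \eqn{\mu_A^p = \sum_i w_i \delta_{x_i} \otimes \sum_\ell
#' \pi_i(\ell) p_\ell}.
#'
#' @param positions n x 3 matrix (mm).
#' @param weights length-n nonnegative masses.
#' @param region_probs n x L matrix of region memberships; rows must sum
#'   to 1 (one-hot for interior particles).  Column names are region labels.
#' @param feature_labels character vector: target feature space the laws
#'   live on.
#' @param feature_laws optional L x F matrix of nonnegative laws (default
#'   uniform `1/F`).
#' @return object of class `atlas_measure`.
#' @export
atlas_measure <- function(positions, weights, region_probs,
                          feature_labels, feature_laws = NULL) {
  positions <- as_point_matrix(positions)
  if (ncol(positions) == 2L) positions <- cbind(positions, 0)
  n <- nrow(positions)
  weights <- as.numeric(weights)
  if (length(weights) == 1L) weights <- rep(weights, n)
  region_probs <- as.matrix(region_probs)
  if (is.null(colnames(region_probs))) {
    colnames(region_probs) <- paste0("region", seq_len(ncol(region_probs)))
  }
  if (nrow(region_probs) != n) stop("region_probs rows must match particles")
  if (any(abs(rowSums(region_probs) - 1) > 1e-9)) {
    stop("region membership rows must sum to 1")
  }
  feature_labels <- as.character(feature_labels)
  L <- ncol(region_probs); F <- length(feature_labels)
  if (is.null(feature_laws)) {
    feature_laws <- matrix(1 / F, L, F)
  }
  feature_laws <- as.matrix(feature_laws)
  if (any(feature_laws < 0)) stop("feature laws must be >= 0")
  dimnames(feature_laws) <- list(colnames(region_probs), feature_labels)
  structure(list(positions = positions, weights = weights,
                 region_probs = region_probs, feature_laws = feature_laws,
                 region_labels = colnames(region_probs),
                 feature_labels = feature_labels),
            class = "atlas_measure")
}

#' @export
print.atlas_measure <- function(x, ...) {
  cat(sprintf("atlas_measure: %d particles, %d regions -> %d target features\n",
              nrow(x$positions), length(x$region_labels),
              length(x$feature_labels)))
  invisible(x)
}

#' Realize the atlas as a particle measure over its target feature space
#'
#' Applies the mixture \eqn{p_i = \sum_\ell \pi_i(\ell) p_\ell} with the
#' atlas's current (or supplied) laws.
#'
#' @param atlas an [atlas_measure()].
#' @param laws optional L x F law matrix overriding the stored one.
#' @return a [particle_measure()] over the target feature space
#'   (unnormalized feature rows).
#' @export
atlas_as_measure <- function(atlas, laws = atlas$feature_laws) {
  particle_measure(atlas$positions, atlas$weights,
                   atlas$region_probs %*% laws,
                   labels = atlas$feature_labels, normalized = FALSE)
}

#' KL prior on latent feature laws
#'
#' \deqn{J_{KL}(p) = \sum_\ell \frac{M^A_\ell}{\sum_f M^T_f} \sum_f
#'   p_\ell(f)\,\log\!\big(\bar p_\ell(f)\,|\mathcal F|\big)}
#' with \eqn{\bar p_\ell} the normalized law, \eqn{M^A_\ell} the deformed
#' atlas mass of region \eqn{\ell} and \eqn{M^T_f} the target mass of
#' feature \eqn{f}.  Nonnegative; zero exactly when every law is uniform.
#' The convention \eqn{0\log 0 = 0} applies.
#'
#' @param laws L x F matrix of nonnegative unnormalized laws.
#' @param region_masses length-L vector \eqn{M^A_\ell \ge 0}.
#' @param target_feature_masses length-F vector \eqn{M^T_f} (or its sum),
#'   with positive total.
#' @return scalar penalty.
#' @export
kl_prior <- function(laws, region_masses, target_feature_masses) {
  laws <- as.matrix(laws)
  Fn <- ncol(laws)
  MT <- sum(target_feature_masses)
  if (!is.finite(MT) || MT <= 0) stop("total target feature mass must be > 0")
  if (any(region_masses < 0)) stop("region masses must be >= 0")
  S <- rowSums(laws)
  per <- vapply(seq_len(nrow(laws)), function(l) {
    p <- laws[l, ]
    if (S[l] <= 0) return(0)
    pb <- p / S[l]
    terms <- ifelse(p > 0, p * log(pb * Fn), 0)
    sum(terms)
  }, numeric(1))
  sum(region_masses / MT * per)
}

#' Configuration for diffeomorphic matching
#'
#' Collects the hyperparameters of the matching problems: flow-kernel scale,
#' varifold kernel, loss weights, integrator steps, optimizer budget and
#' seed.
#'
#' @param flow_sigma flow-kernel bandwidth \eqn{\sigma_V} in mm.
#' @param varifold_kernel a [space_kernel()] for the data term.
#' @param feature_kernel a [feature_kernel()].
#' @param reg_weight weight of the Hamiltonian regularization (default 1).
#' @param data_weight weight of the varifold data term (default 1).
#' @param n_steps RK4 integration steps (default 10).
#' @param max_iter optimizer iteration budget (default 150).
#' @param seed integer seed for any stochastic initialization.
#' @param truncate kernel truncation radius for the data term (default
#'   exact).
#' @return object of class `mapping_config`.
#' @export
mapping_config <- function(flow_sigma, varifold_kernel,
                           feature_kernel = ivmatch::feature_kernel(),
                           reg_weight = 1, data_weight = 1,
                           n_steps = 10L, max_iter = 150L, seed = 1L,
                           truncate = Inf) {
  stopifnot(inherits(varifold_kernel, "space_kernel"))
  n_steps <- as.integer(n_steps); max_iter <- as.integer(max_iter)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (max_iter < 1L) stop("iteration budget must be > 0")
  structure(list(fk = flow_kernel(flow_sigma),
                 ks = varifold_kernel, kf = feature_kernel,
                 reg_weight = reg_weight, data_weight = data_weight,
                 n_steps = n_steps, max_iter = max_iter,
                 seed = as.integer(seed), truncate = truncate),
            class = "mapping_config")
}

## guard an objective against integrator blow-up during line-search probes:
## a degenerate trial step scores a large finite penalty instead of erroring
guarded <- function(f, penalty = 1e10) {
  function(par) {
    v <- tryCatch(f(par), error = function(e) penalty)
    if (!is.finite(v)) penalty else v
  }
}

## forward-difference gradient of f over the indices sel of par
fd_gradient <- function(f, par, f0 = f(par), sel = seq_along(par),
                        eps = 1e-6) {
  g <- numeric(length(sel))
  for (k in seq_along(sel)) {
    i <- sel[k]
    h <- eps * max(1, abs(par[i]))
    p2 <- par
    p2[i] <- p2[i] + h
    g[k] <- (f(p2) - f0) / h
  }
  g
}

#' Single-modality diffeomorphic matching by geodesic shooting
#'
#' Minimizes the Hamiltonian regularization plus the squared varifold
#' distance \eqn{H(q_0,\rho_0) + \|\varphi_1\cdot\mu - \mu'\|_M^2} over the
#' initial space and mass momenta, by L-BFGS-B descent through the RK4
#' geodesic integrator.
#'
#' @param mu source [particle_measure()] (the deforming template).
#' @param target target [particle_measure()] over the same feature space.
#' @param cfg a [mapping_config()].
#' @param init optional list with `rho_x`, `rho_w` warm start.
#' @return a `mapping_result` list: `rho_x`, `rho_w` (optimized initial
#'   momenta), `deformed` (the transported measure), `phi`
#'   ([diffeo_sample()]), `objective`, `objective_zero` (value at zero
#'   momenta), `trajectory` (objective values over evaluations),
#'   `convergence` (optim code).
#' @export
match_single_modality <- function(mu, target, cfg, init = NULL) {
  stopifnot(inherits(mu, "particle_measure"),
            inherits(target, "particle_measure"),
            inherits(cfg, "mapping_config"))
  if (!same_feature_space(mu, target)) stop("measures do not share a feature space")
  n <- n_particles(mu)
  wpT <- weighted_features(target)
  Tself <- varifold_inner_product(target, target, cfg$ks, cfg$kf, cfg$truncate)
  wpM <- weighted_features(mu)  # feature rows fixed; only w scales by jac
  trace_env <- new.env(); trace_env$vals <- numeric(0)

  objective_raw <- function(par) {
    rho_x <- matrix(par[seq_len(3 * n)], n, 3)
    rho_w <- par[3 * n + seq_len(n)]
    st <- geodesic_state(mu$positions, mu$weights, rho_x, rho_w)
    sh <- shoot(st, cfg$fk, cfg$n_steps)
    y <- sh$final$positions
    wdef <- sh$phi$jacobians * mu$weights
    Kyy <- kernel_matrix(cfg$ks, y, y, truncate = cfg$truncate)
    Kyt <- kernel_matrix(cfg$ks, y, target$positions, truncate = cfg$truncate)
    PP <- tcrossprod(mu$features)
    jfac <- sh$phi$jacobians
    self <- as.numeric((jfac * mu$weights) %*% (Kyy * PP) %*% (jfac * mu$weights))
    cross <- sum((Kyt %*% wpT) * (jfac * wpM))
    data <- self - 2 * cross + Tself
    cfg$reg_weight * sh$hamiltonian + cfg$data_weight * data
  }
  objective <- guarded(objective_raw)
  obj_traced <- function(par) {
    v <- objective(par)
    trace_env$vals <- c(trace_env$vals, v)
    v
  }
  par0 <- rep(0, 4 * n)
  if (!is.null(init)) {
    par0 <- c(as.numeric(init$rho_x), as.numeric(init$rho_w))
  }
  obj0 <- objective(rep(0, 4 * n))
  grad <- function(par) {
    if (objective(par) >= 1e10) return(numeric(length(par)))
    fd_gradient(objective, par)
  }
  fit <- stats::optim(par0, obj_traced, gr = grad, method = "L-BFGS-B",
                      control = list(maxit = cfg$max_iter, factr = 1e7))
  if (!is.finite(fit$value)) {
    stop("optimizer diverged; last finite objective ",
         max(trace_env$vals[is.finite(trace_env$vals)]))
  }
  rho_x <- matrix(fit$par[seq_len(3 * n)], n, 3)
  rho_w <- fit$par[3 * n + seq_len(n)]
  sh <- shoot(geodesic_state(mu$positions, mu$weights, rho_x, rho_w),
              cfg$fk, cfg$n_steps)
  structure(list(rho_x = rho_x, rho_w = rho_w,
                 deformed = apply_varifold_action(mu, sh$phi),
                 phi = sh$phi, objective = fit$value,
                 objective_zero = obj0,
                 trajectory = trace_env$vals,
                 convergence = fit$convergence),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("mapping_result: objective %g (zero-momenta %g), %d evaluations\n",
              x$objective, x$objective_zero, length(x$trajectory)))
  invisible(x)
}

#' Cross-modality matching with latent feature laws (and optional censoring)
#'
#' Jointly optimizes the initial momenta, the per-region feature laws
#' \eqn{p_\ell} (positivity enforced by exponential parameterization) and,
#' when a censor is supplied, its bandwidth \eqn{\lambda}, minimizing
#' \deqn{H(q_0,\rho_0) + \sum_\ell J_{KL}(p_\ell) +
#'   \|\varphi_1\cdot\mu_A^{p,\lambda} - \mu_T\|_M^2 \;(+ J_s(\lambda)).}
#' The deformed atlas carries weights
#' \eqn{\alpha^\lambda(\varphi(x_i))\,|D\varphi|_{x_i} w_i} and feature rows
#' \eqn{\sum_\ell \pi_i(\ell) p_\ell}.
#'
#' @param atlas an [atlas_measure()].
#' @param target target [particle_measure()] over the atlas's target feature
#'   space.
#' @param cfg a [mapping_config()].
#' @param censor optional [planar_censor()] or [learned_censor()]; its
#'   `lambda` is optimized jointly (with the [lambda_penalty()]
#'   regularization) unless `optimize_lambda = FALSE`.
#' @param optimize_lambda should the censor bandwidth be estimated?
#' @param kl_weight weight of the KL prior (default 1).
#' @return a `mapping_result` with additionally `laws` (estimated
#'   unnormalized laws), `laws_normalized`, `lambda` and `deformed` the
#'   censored deformed atlas measure.
#' @export
match_cross_modality <- function(atlas, target, cfg, censor = NULL,
                                 optimize_lambda = !is.null(censor),
                                 kl_weight = 1) {
  pb <- cross_modality_problem(atlas, target, cfg, censor, optimize_lambda,
                               kl_weight)
  trace_env <- new.env(); trace_env$vals <- numeric(0)
  obj_traced <- function(par) {
    v <- pb$objective(par)
    trace_env$vals <- c(trace_env$vals, v)
    v
  }
  obj0 <- pb$objective(pb$par0)
  ## warm-start the laws by solving the convex law subproblem at the
  ## initial (identity) deformation, then descend jointly
  par_start <- pb$par0
  if (length(pb$idx_theta) > 0) {
    par_start[pb$idx_theta] <- pb$law_warmstart(par_start)
  }
  fit <- stats::optim(par_start, obj_traced, gr = pb$gradient,
                      method = "L-BFGS-B",
                      control = list(maxit = cfg$max_iter, factr = 1e3,
                                     lmm = 20))
  if (!is.finite(fit$value)) {
    stop("optimizer diverged; last finite objective ",
         max(trace_env$vals[is.finite(trace_env$vals)]))
  }
  out <- pb$unpack(fit$par)
  out$objective <- fit$value
  out$objective_zero <- obj0
  out$trajectory <- trace_env$vals
  out$convergence <- fit$convergence
  structure(out, class = "mapping_result")
}

## builds the joint objective/gradient of the cross-modality problem;
## internal, exposed for gradient-consistency tests
cross_modality_problem <- function(atlas, target, cfg, censor = NULL,
                                   optimize_lambda = !is.null(censor),
                                   kl_weight = 1) {
  stopifnot(inherits(atlas, "atlas_measure"),
            inherits(target, "particle_measure"),
            inherits(cfg, "mapping_config"))
  if (!identical(atlas$feature_labels, target$labels)) {
    stop("atlas target-feature space must match the target measure")
  }
  n <- nrow(atlas$positions)
  L <- length(atlas$region_labels)
  Fn <- length(atlas$feature_labels)
  Pi <- atlas$region_probs
  wpT <- weighted_features(target)
  MTtot <- sum(wpT)
  Tself <- varifold_inner_product(target, target, cfg$ks, cfg$kf, cfg$truncate)

  ## regions with no membership mass are pinned to the uniform law
  empty <- colSums(Pi * atlas$weights) <= 0
  if (any(empty)) {
    warning("atlas region(s) with zero mass pinned to uniform law: ",
            paste(atlas$region_labels[empty], collapse = ", "))
  }
  free_l <- which(!empty)

  n_rho <- 4 * n
  n_theta <- length(free_l) * Fn
  has_lam <- !is.null(censor) && optimize_lambda
  idx_rho <- seq_len(n_rho)
  idx_theta <- n_rho + seq_len(n_theta)
  idx_lam <- if (has_lam) n_rho + n_theta + 1L else integer(0)

  laws_of <- function(theta) {
    P <- matrix(1 / Fn, L, Fn,
                dimnames = list(atlas$region_labels, atlas$feature_labels))
    P[free_l, ] <- exp(matrix(theta, length(free_l), Fn))
    P
  }

  pieces <- function(par) {
    rho_x <- matrix(par[seq_len(3 * n)], n, 3)
    rho_w <- par[3 * n + seq_len(n)]
    st <- geodesic_state(atlas$positions, atlas$weights, rho_x, rho_w)
    sh <- shoot(st, cfg$fk, cfg$n_steps)
    y <- sh$final$positions
    lam <- if (has_lam) exp(par[idx_lam]) else
      if (!is.null(censor)) censor$lambda else NA_real_
    alpha <- if (is.null(censor)) rep(1, n) else
      censor_eval(set_lambda(censor, lam), y)
    W <- alpha * sh$phi$jacobians * atlas$weights
    B <- Pi * W  # n x L
    Kyy <- kernel_matrix(cfg$ks, y, y, truncate = cfg$truncate)
    Kyt <- kernel_matrix(cfg$ks, y, target$positions, truncate = cfg$truncate)
    G <- crossprod(B, Kyy %*% B)
    cc <- crossprod(B, Kyt %*% wpT)
    list(sh = sh, G = G, cc = cc, MA = colSums(B), lam = lam)
  }
  obj_from_pieces <- function(pc, P) {
    data <- sum(P * (pc$G %*% P)) - 2 * sum(P * pc$cc) + Tself
    kl <- kl_prior(P, pc$MA, MTtot)
    lampen <- if (has_lam) lambda_penalty(pc$lam) else 0
    cfg$reg_weight * pc$sh$hamiltonian + kl_weight * kl +
      cfg$data_weight * data + lampen
  }
  objective_raw <- function(par) {
    pc <- pieces(par)
    obj_from_pieces(pc, laws_of(par[idx_theta]))
  }
  objective <- guarded(objective_raw)

  gradient <- function(par) {
    pc <- tryCatch(pieces(par), error = function(e) NULL)
    if (is.null(pc)) return(numeric(length(par)))
    P <- laws_of(par[idx_theta])
    f0 <- obj_from_pieces(pc, P)
    ## analytic gradient in the law block (G, c, M_A fixed given momenta)
    dData <- 2 * (pc$G %*% P - pc$cc)
    S <- rowSums(P)
    dKL <- (pc$MA / MTtot) * log(pmax(P / S, 1e-300) * Fn)
    dP <- cfg$data_weight * dData + kl_weight * dKL
    g_theta <- as.numeric((dP * P)[free_l, , drop = FALSE])
    f_of <- guarded(function(p2) {
      pc2 <- pieces(p2)
      obj_from_pieces(pc2, laws_of(p2[idx_theta]))
    })
    g_rest <- fd_gradient(f_of, par, f0 = f0, sel = c(idx_rho, idx_lam))
    g <- numeric(length(par))
    g[c(idx_rho, idx_lam)] <- g_rest
    g[idx_theta] <- g_theta
    g
  }

  par0 <- c(rep(0, n_rho),
            as.numeric(log(pmax(atlas$feature_laws[free_l, , drop = FALSE],
                                1e-8))),
            if (has_lam) log(censor$lambda))
  unpack <- function(par) {
    rho_x <- matrix(par[seq_len(3 * n)], n, 3)
    rho_w <- par[3 * n + seq_len(n)]
    P <- laws_of(par[idx_theta])
    lam <- if (has_lam) exp(par[idx_lam]) else
      if (!is.null(censor)) censor$lambda else NA_real_
    sh <- shoot(geodesic_state(atlas$positions, atlas$weights, rho_x, rho_w),
                cfg$fk, cfg$n_steps)
    alpha <- if (is.null(censor)) rep(1, n) else
      censor_eval(set_lambda(censor, lam), sh$final$positions)
    deformed <- particle_measure(sh$final$positions,
                                 alpha * sh$phi$jacobians * atlas$weights,
                                 Pi %*% P, labels = atlas$feature_labels,
                                 normalized = FALSE)
    list(rho_x = rho_x, rho_w = rho_w, laws = P,
         laws_normalized = P / rowSums(P), lambda = lam,
         deformed = deformed, phi = sh$phi)
  }
  ## optimize the law block alone with the deformation (and censor) held at
  ## `par`; the geometry-dependent pieces are computed once, so this is a
  ## cheap low-dimensional convex solve used to warm-start the joint descent
  law_warmstart <- function(par, maxit = 200L) {
    pc <- pieces(par)
    fn <- function(th) obj_from_pieces(pc, laws_of(th))
    gr <- function(th) {
      P <- laws_of(th)
      dData <- 2 * (pc$G %*% P - pc$cc)
      S <- rowSums(P)
      dKL <- (pc$MA / MTtot) * log(pmax(P / S, 1e-300) * Fn)
      as.numeric(((cfg$data_weight * dData + kl_weight * dKL) *
                    P)[free_l, , drop = FALSE])
    }
    stats::optim(par[idx_theta], fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, factr = 1e1))$par
  }
  list(objective = objective, gradient = gradient, par0 = par0,
       unpack = unpack, idx_rho = idx_rho, idx_theta = idx_theta,
       idx_lam = idx_lam, law_warmstart = law_warmstart)
}

#' Closed-form optimal feature laws at a fixed deformation
#'
#' With the deformation (and censoring) fixed, the varifold data term is
#' quadratic in the unnormalized laws \eqn{p_\ell}; per feature the
#' unconstrained minimizer solves \eqn{G p = c} with
#' \eqn{G_{\ell\ell'} = \sum_{ij} W_i W_j K(y_i,y_j)\pi_i(\ell)\pi_j(\ell')}
#' and \eqn{c_{\ell f} = \sum_{i,t} W_i K(y_i, u_t)\,\pi_i(\ell) w_t p_t(f)}.
#' Negative entries (rare, boundary-driven) are clipped to zero.
#'
#' @param atlas an [atlas_measure()].
#' @param target a [particle_measure()] over the atlas's target features.
#' @param ks a [space_kernel()].
#' @param positions optional deformed atlas positions (default: as stored).
#' @param weights optional deformed (censored) atlas masses.
#' @param ridge small Tikhonov regularization added to `G` (default 1e-10
#'   of its trace).
#' @return list with `laws` (L x F), `loss` (the squared varifold distance
#'   at the optimum) and `G`, `c` for reuse.
#' @export
optimal_feature_laws <- function(atlas, target, ks,
                                 positions = atlas$positions,
                                 weights = atlas$weights, ridge = 1e-10) {
  stopifnot(inherits(atlas, "atlas_measure"))
  B <- atlas$region_probs * weights
  wpT <- weighted_features(target)
  Kyy <- kernel_matrix(ks, positions, positions)
  Kyt <- kernel_matrix(ks, positions, target$positions)
  G <- crossprod(B, Kyy %*% B)
  cc <- crossprod(B, Kyt %*% wpT)
  Greg <- G + diag(ridge * sum(diag(G)), nrow(G))
  P <- solve(Greg, cc)
  P[P < 0] <- 0
  Tself <- varifold_inner_product(target, target, ks)
  loss <- sum(P * (G %*% P)) - 2 * sum(P * cc) + Tself
  dimnames(P) <- list(atlas$region_labels, atlas$feature_labels)
  list(laws = P, loss = loss, G = G, c = cc)
}

#' Rigid-rotation sweep of the cross-modality loss
#'
#' Rotates the atlas about the z axis through the origin over a grid of
#' angles; at each angle the per-region feature laws are re-estimated in
#' closed form ([optimal_feature_laws()]) and the squared varifold distance
#' between the law-equipped rotated atlas and the target is recorded.  Both
#' measures are assumed centered at the origin.  The atlas self-term is
#' rotation-invariant, so `G` is computed once.
#'
#' @param atlas an [atlas_measure()] (e.g. the three-region toy atlas).
#' @param target a [particle_measure()].
#' @param ks a [space_kernel()].
#' @param angles_deg numeric vector of rotation angles in degrees.
#' @return data.frame with columns `angle` and `loss`; the minimizing angle
#'   is in `attr(, "argmin")`.
#' @export
rotation_sweep <- function(atlas, target, ks, angles_deg = 0:359) {
  stopifnot(inherits(atlas, "atlas_measure"))
  B <- atlas$region_probs * atlas$weights
  wpT <- weighted_features(target)
  Kxx <- kernel_matrix(ks, atlas$positions, atlas$positions)
  G <- crossprod(B, Kxx %*% B)
  Greg <- G + diag(1e-10 * sum(diag(G)), nrow(G))
  Tself <- varifold_inner_product(target, target, ks)
  X <- atlas$positions
  loss <- vapply(angles_deg, function(ang) {
    th <- ang * pi / 180
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    Y <- X %*% t(R)
    Kyt <- kernel_matrix(ks, Y, target$positions)
    cc <- crossprod(B, Kyt %*% wpT)
    P <- solve(Greg, cc)
    P[P < 0] <- 0
    sum(P * (G %*% P)) - 2 * sum(P * cc) + Tself
  }, numeric(1))
  out <- data.frame(angle = angles_deg, loss = loss)
  attr(out, "argmin") <- angles_deg[which.min(loss)]
  out
}

#' Similitude (rotation + isotropic scale + translation) pre-alignment
#'
#' Optimizes a similitude transform minimizing the squared varifold distance
#' to the target; the mass of the transformed measure scales with the
#' Jacobian determinant \eqn{s^3}.  Used as an optional coarse stage before
#' geodesic shooting.
#'
#' @param mu,target [particle_measure()] objects on one feature space.
#' @param ks a [space_kernel()].
#' @param rotation_only if `TRUE`, fix scale at 1 and translation at 0.
#' @param max_iter optimizer budget.
#' @return list with `rotation` (3 x 3), `scale`, `translation`,
#'   `transformed` measure and `objective`.
#' @export
fit_similitude <- function(mu, target, ks, rotation_only = FALSE,
                           max_iter = 100L) {
  if (!same_feature_space(mu, target)) stop("measures do not share a feature space")
  apply_par <- function(par) {
    R <- rotation_from_axis_angle(par[1:3])
    s <- exp(par[4])
    tr <- par[5:7]
    pos <- sweep(mu$positions %*% t(R) * s, 2, tr, "+")
    particle_measure(pos, mu$weights * s^3, mu$features,
                     normalized = mu$normalized)
  }
  obj <- function(par) {
    if (rotation_only) par[4:7] <- 0
    varifold_norm_dist2(apply_par(par), target, ks)
  }
  fit <- stats::optim(rep(0, 7), obj, method = "L-BFGS-B",
                      control = list(maxit = max_iter))
  par <- fit$par
  if (rotation_only) par[4:7] <- 0
  list(rotation = rotation_from_axis_angle(par[1:3]), scale = exp(par[4]),
       translation = par[5:7], transformed = apply_par(par),
       objective = fit$value)
}

rotation_from_axis_angle <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  Kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * Kx + (1 - cos(th)) * (Kx %*% Kx)
}
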