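#' Configuration for optimization-based scale-space resampling
#'
#' @param sigma approximation scale in mm (also the varifold kernel
#'   bandwidth used in the objective).
#' @param cube_edge lattice cube edge in mm (default `sigma`).
#' @param iter_weights iteration budget for the weights/features stage
#'   (default 200).
#' @param iter_joint iteration budget for the joint stage (default 200).
#' @param truncate kernel truncation radius (default `4 * sigma`; use `Inf`
#'   for exact evaluation, the default in small problems is effectively
#'   exact because everything lies within the radius).
#' @param rel_tol early-stop threshold on the relative objective change
#'   (default 1e-7).
#' @param seed integer seed for the random in-cube particle selection.
#' @return object of class `resampling_config`.
#' @export
resampling_config <- function(sigma, cube_edge = sigma,
                              iter_weights = 200L, iter_joint = 200L,
                              truncate = 4 * sigma, rel_tol = 1e-7,
                              seed = 1L) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (iter_weights < 1L || iter_joint < 1L) stop("iteration budgets must be >= 1")
  structure(list(sigma = sigma, cube_edge = cube_edge,
                 iter_weights = as.integer(iter_weights),
                 iter_joint = as.integer(iter_joint),
                 truncate = truncate, rel_tol = rel_tol,
                 seed = as.integer(seed),
                 ks = space_kernel(sigma)),
            class = "resampling_config")
}

## approximation particles carry positions and the weighted laws Q = w * p
approximation_result <- function(positions, Q, labels, cfg, stage,
                                 objective, trajectory = numeric(0)) {
  colnames(Q) <- labels
  structure(list(positions = positions, Q = Q, labels = labels, cfg = cfg,
                 stage = stage, objective = objective,
                 trajectory = trajectory),
            class = "scale_approximation")
}

#' @export
print.scale_approximation <- function(x, ...) {
  cat(sprintf(
    "scale_approximation (%s): %d particles at sigma = %g mm, objective %g\n",
    x$stage, nrow(x$positions), x$cfg$sigma, x$objective))
  invisible(x)
}

#' Convert a scale approximation to a particle measure
#'
#' @param approx a `scale_approximation`.
#' @return a [particle_measure()] with weights `rowSums(Q)` and normalized
#'   feature rows (particles whose mass optimized to zero keep a uniform
#'   row).
#' @export
approximation_measure <- function(approx) {
  w <- rowSums(approx$Q)
  P <- approx$Q / ifelse(w > 0, w, 1)
  P[w <= 0, ] <- 1 / ncol(approx$Q)
  particle_measure(approx$positions, w, P, labels = approx$labels,
                   normalized = TRUE)
}

#' Squared varifold distance of an approximation to its target
#'
#' Evaluates \eqn{\|\mu_\sigma - \mu\|_M^2} with the approximation's
#' weighted laws \eqn{\tilde w_i \tilde p_i}.
#'
#' @param approx a `scale_approximation`.
#' @param mu the high-resolution target [particle_measure()].
#' @param ks a [space_kernel()] (default: Gaussian at the approximation
#'   scale).
#' @param truncate kernel truncation radius.
#' @return nonnegative scalar.
#' @export
approximation_objective <- function(approx, mu, ks = approx$cfg$ks,
                                    truncate = Inf) {
  if (!identical(approx$labels, mu$labels)) {
    stop("approximation and target feature spaces differ")
  }
  wpT <- weighted_features(mu)
  Kaa <- kernel_matrix(ks, approx$positions, approx$positions,
                       truncate = truncate)
  Kat <- kernel_matrix(ks, approx$positions, mu$positions,
                       truncate = truncate)
  Ktt <- kernel_matrix(ks, mu$positions, mu$positions, truncate = truncate)
  sum(Kaa * tcrossprod(approx$Q)) - 2 * sum(Kat * tcrossprod(approx$Q, wpT)) +
    sum(Ktt * tcrossprod(wpT))
}

#' Lattice initialization of the scale-space approximation
#'
#' Lays a cubic lattice of edge `cfg$cube_edge` over the support of `mu`;
#' each occupied cube contributes one approximation particle positioned at a
#' randomly selected high-resolution particle of the cube (seeded), with
#' weight equal to the cube's total mass and a uniform feature law.
#'
#' @param mu high-resolution [particle_measure()].
#' @param cfg a [resampling_config()].
#' @return a `scale_approximation` at stage `"init"`.
#' @export
init_lattice_approximation <- function(mu, cfg) {
  stopifnot(inherits(mu, "particle_measure"),
            inherits(cfg, "resampling_config"))
  if (n_particles(mu) == 0L) stop("cannot approximate an empty measure")
  edge <- cfg$cube_edge
  origin <- apply(mu$positions, 2, min)
  idx <- floor(sweep(mu$positions, 2, origin) / edge + 1e-12)
  key <- paste(idx[, 1], idx[, 2], idx[, 3], sep = ",")
  groups <- split(seq_len(n_particles(mu)), key)
  set.seed(cfg$seed)
  Fn <- length(mu$labels)
  pos <- matrix(0, length(groups), 3)
  Q <- matrix(0, length(groups), Fn, dimnames = list(NULL, mu$labels))
  for (g in seq_along(groups)) {
    ids <- groups[[g]]
    pick <- ids[sample.int(length(ids), 1L)]
    pos[g, ] <- mu$positions[pick, ]
    Q[g, ] <- sum(mu$weights[ids]) / Fn
  }
  obj <- NA_real_
  out <- approximation_result(pos, Q, mu$labels, cfg, "init", obj)
  out$objective <- approximation_objective(out, mu)
  out
}

## shared optimizer over (theta [, positions]) with analytic gradients
optimize_approximation <- function(approx, mu, cfg, joint, maxit) {
  wpT <- weighted_features(mu)
  Xt <- mu$positions
  Ktt_term <- sum(kernel_matrix(cfg$ks, Xt, Xt) * tcrossprod(wpT))
  n <- nrow(approx$positions); Fn <- ncol(approx$Q)
  sig <- cfg$ks$sigma; wgt <- cfg$ks$weight
  trace_env <- new.env(); trace_env$vals <- numeric(0)

  eval_all <- function(par, want_grad = TRUE) {
    theta <- matrix(par[seq_len(n * Fn)], n, Fn)
    Q <- exp(theta)
    X <- if (joint) matrix(par[n * Fn + seq_len(3 * n)], n, 3) else
      approx$positions
    D2aa <- pairwise_sq_dist(X, X)
    D2at <- pairwise_sq_dist(X, Xt)
    Kaa <- matrix(0, n, n); Kat <- matrix(0, n, nrow(Xt))
    Ecomp_aa <- vector("list", length(sig))
    Ecomp_at <- vector("list", length(sig))
    for (c in seq_along(sig)) {
      Ecomp_aa[[c]] <- wgt[c] * exp(-D2aa / (2 * sig[c]^2))
      Ecomp_at[[c]] <- wgt[c] * exp(-D2at / (2 * sig[c]^2))
      Kaa <- Kaa + Ecomp_aa[[c]]
      Kat <- Kat + Ecomp_at[[c]]
    }
    QQ <- tcrossprod(Q)
    QT <- tcrossprod(Q, wpT)
    obj <- sum(Kaa * QQ) - 2 * sum(Kat * QT) + Ktt_term
    if (!want_grad) return(list(obj = obj))
    dQ <- 2 * (Kaa %*% Q - Kat %*% wpT)
    g_theta <- as.numeric(dQ * Q)
    g <- g_theta
    if (joint) {
      gX <- matrix(0, n, 3)
      for (c in seq_along(sig)) {
        Caa <- Ecomp_aa[[c]] * QQ / sig[c]^2
        Cat <- Ecomp_at[[c]] * QT / sig[c]^2
        gX <- gX - 2 * (X * rowSums(Caa) - Caa %*% X) +
          2 * (X * rowSums(Cat) - Cat %*% Xt)
      }
      g <- c(g_theta, as.numeric(gX))
    }
    list(obj = obj, grad = g)
  }

  Q0 <- pmax(approx$Q, 1e-12)
  par0 <- c(as.numeric(log(Q0)),
            if (joint) as.numeric(approx$positions))
  fn <- function(par) {
    v <- eval_all(par, want_grad = FALSE)$obj
    trace_env$vals <- c(trace_env$vals, v)
    v
  }
  gr <- function(par) eval_all(par)$grad
  fit <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit,
                                     factr = cfg$rel_tol / .Machine$double.eps))
  theta <- matrix(fit$par[seq_len(n * Fn)], n, Fn)
  X <- if (joint) matrix(fit$par[n * Fn + seq_len(3 * n)], n, 3) else
    approx$positions
  obj_final <- min(fit$value, approx$objective)
  if (fit$value > approx$objective * (1 + 1e-8) + 1e-12) {
    stop("resampling objective increased beyond tolerance")
  }
  approximation_result(X, exp(theta), approx$labels, cfg,
                       if (joint) "joint" else "weights",
                       fit$value, c(approx$trajectory, trace_env$vals))
}

#' Stage 1: optimize weights and feature laws at fixed positions
#'
#' Minimizes the squared varifold distance over the weighted laws
#' \eqn{\tilde w_i \tilde p_i} (positivity by exponential
#' parameterization), holding the particle positions fixed.
#'
#' @param approx an initialized `scale_approximation`.
#' @param mu the high-resolution target measure.
#' @param cfg the [resampling_config()].
#' @return a `scale_approximation` at stage `"weights"` with a non-increased
#'   objective.
#' @export
optimize_weights_features <- function(approx, mu, cfg = approx$cfg) {
  optimize_approximation(approx, mu, cfg, joint = FALSE,
                         maxit = cfg$iter_weights)
}

#' Stage 2: joint optimization of positions, weights and laws
#'
#' @inheritParams optimize_weights_features
#' @return a `scale_approximation` at stage `"joint"`; its objective is at
#'   most the stage-1 objective.
#' @export
optimize_joint <- function(approx, mu, cfg = approx$cfg) {
  optimize_approximation(approx, mu, cfg, joint = TRUE,
                         maxit = cfg$iter_joint)
}

#' Full scale-space resampling (lattice init, then both stages)
#'
#' @inheritParams optimize_weights_features
#' @return a list with `init`, `weights`, `joint` approximations.
#' @export
resample_scale_space <- function(mu, cfg) {
  a0 <- init_lattice_approximation(mu, cfg)
  a1 <- optimize_weights_features(a0, mu, cfg)
  a2 <- optimize_joint(a1, mu, cfg)
  list(init = a0, weights = a1, joint = a2)
}

#' K-means (Lloyd) resampling baseline
#'
#' Clusters particle positions only (Lloyd's algorithm, seeded random subset
#' initialization); cluster centroids become the approximation positions and
#' each cluster's summed per-feature mass becomes its weighted law.  Empty
#' clusters are re-seeded by retrying the initialization.
#'
#' @param mu high-resolution [particle_measure()].
#' @param K number of clusters, `K <= n_particles(mu)`.
#' @param seed integer seed.
#' @param iter_max Lloyd iteration budget.
#' @return a [particle_measure()] with `K` particles.
#' @export
kmeans_baseline <- function(mu, K, seed = 1L, iter_max = 100L) {
  n <- n_particles(mu)
  if (K > n) stop("K must not exceed the particle count")
  set.seed(seed)
  wp <- weighted_features(mu)
  for (attempt in 1:10) {
    centers <- mu$positions[sample.int(n, K), , drop = FALSE]
    km <- tryCatch(
      suppressWarnings(stats::kmeans(mu$positions, centers = centers,
                                     iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(km)) break
  }
  if (is.null(km)) stop("k-means failed to produce non-empty clusters")
  Q <- rowsum(wp, km$cluster)
  w <- rowSums(Q)
  P <- Q / ifelse(w > 0, w, 1)
  P[w <= 0, ] <- 1 / ncol(Q)
  particle_measure(km$centers, w, P, labels = mu$labels, normalized = TRUE)
}

#' Fixed-grid kernel resampling baseline
#'
#' Redistributes each particle's mass (and per-feature mass) over fixed
#' lattice nodes with normalized Gaussian kernel weights, conserving total
#' mass exactly.
#'
#' @param mu high-resolution [particle_measure()].
#' @param sigma kernel bandwidth and lattice spacing in mm.
#' @param nodes optional m x 3 matrix of lattice nodes; default: centers of
#'   the occupied cubes of the `sigma`-lattice (matching the budget of
#'   [init_lattice_approximation()]).
#' @return a [particle_measure()] at the nodes.
#' @export
grid_resample_baseline <- function(mu, sigma, nodes = NULL) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (is.null(nodes)) {
    origin <- apply(mu$positions, 2, min)
    idx <- floor(sweep(mu$positions, 2, origin) / sigma + 1e-12)
    uidx <- unique(idx)
    nodes <- sweep(uidx * sigma + sigma / 2, 2, origin, "+")
  }
  nodes <- as_point_matrix(nodes)
  if (ncol(nodes) == 2L) nodes <- cbind(nodes, 0)
  K <- kernel_matrix(space_kernel(sigma), nodes, mu$positions)
  A <- sweep(K, 2, pmax(colSums(K), 1e-300), "/")
  Q <- A %*% weighted_features(mu)
  w <- rowSums(Q)
  P <- Q / ifelse(w > 0, w, 1)
  P[w <= 0, ] <- 1 / ncol(Q)
  particle_measure(nodes, w, P, labels = mu$labels, normalized = TRUE)
}

#' Compare resampling schemes at a matched particle budget
#'
#' Runs the optimization-based scheme, then K-means and grid baselines at
#' the same particle count, and reports each scheme's squared varifold
#' distance to the high-resolution measure.
#'
#' @param mu high-resolution [particle_measure()].
#' @param cfg a [resampling_config()].
#' @return data.frame with columns `scheme`, `particles`, `dist2`; the
#'   fitted approximations are attached as `attr(, "fits")`.
#' @export
compare_schemes <- function(mu, cfg) {
  fits <- resample_scale_space(mu, cfg)
  n_budget <- nrow(fits$joint$positions)
  ks <- cfg$ks
  km <- kmeans_baseline(mu, n_budget, seed = cfg$seed)
  ## grid baseline on the same occupied-cube lattice => identical budget
  origin <- apply(mu$positions, 2, min)
  idx <- floor(sweep(mu$positions, 2, origin) / cfg$cube_edge + 1e-12)
  uidx <- unique(idx)
  nodes <- sweep(uidx * cfg$cube_edge + cfg$cube_edge / 2, 2, origin, "+")
  gr <- grid_resample_baseline(mu, cfg$sigma, nodes = nodes)
  d <- c(optimized = fits$joint$objective,
         kmeans = varifold_norm_dist2(km, mu, ks),
         grid = varifold_norm_dist2(gr, mu, ks))
  out <- data.frame(scheme = names(d),
                    particles = c(n_budget, n_particles(km), n_particles(gr)),
                    dist2 = as.numeric(d), row.names = NULL)
  attr(out, "fits") <- list(optimized = fits, kmeans = km, grid = gr)
  out
}
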