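#' Planar (tanh) censoring function
#'
#' Spatial support weight for partial-volume matching along an axis:
#' \deqn{\alpha^\lambda(x) = \tfrac12\Big(\tanh\frac{\langle x-a_0,
#'   n_0\rangle}{\lambda} + \tanh\frac{\langle x-a_1, n_1\rangle}
#'   {\lambda}\Big) \in [0,1],}
#' with anchors \eqn{a_0, a_1} on the first and last measured sections and
#' inward unit normals \eqn{n_0, n_1}.  The bandwidth \eqn{\lambda} (mm)
#' controls the width of the transition zone.
#'
#' @param a0,a1 3-vector anchor points in target coordinates (mm).
#' @param n0,n1 inward normal vectors (normalized internally).
#' @param lambda transition bandwidth, > 0.
#' @return object of class `planar_censor` (and `censor`).
#' @export
planar_censor <- function(a0, n0, a1, n1, lambda = sqrt(0.1)) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  unit <- function(v) {
    v <- as.numeric(v)
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("censor normals must be nonzero")
    v / nv
  }
  structure(list(a0 = as.numeric(a0), n0 = unit(n0),
                 a1 = as.numeric(a1), n1 = unit(n1),
                 lambda = as.numeric(lambda)),
            class = c("planar_censor", "censor"))
}

#' Learned (classifier) censoring function
#'
#' A small 3-layer feed-forward boundary classifier (3 -> 15 -> 5 -> 1,
#' exponential-linear activations) whose scalar output is pushed through a
#' hyperbolic tangent with temperature \eqn{\lambda} and rescaled to
#' `[0, 1]`, giving a smooth support weight for irregular boundaries.
#'
#' @param params list of layer weights/biases `W1` (15 x 3), `b1`, `W2`
#'   (5 x 15), `b2`, `W3` (1 x 5), `b3`.
#' @param lambda tanh temperature, > 0.
#' @return object of class `learned_censor` (and `censor`).
#' @export
learned_censor <- function(params, lambda = sqrt(0.1)) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  stopifnot(all(c("W1", "b1", "W2", "b2", "W3", "b3") %in% names(params)))
  structure(list(params = params, lambda = as.numeric(lambda)),
            class = c("learned_censor", "censor"))
}

set_lambda <- function(censor, lambda) {
  if (is.null(censor) || is.na(lambda)) return(censor)
  censor$lambda <- lambda
  censor
}

elu <- function(z) ifelse(z > 0, z, exp(pmin(z, 0)) - 1)
elu_grad <- function(z) ifelse(z > 0, 1, exp(pmin(z, 0)))

## raw pre-tanh score of the learned censor at points X (n x 3)
censor_net_score <- function(params, X) {
  Z1 <- tcrossprod(X, params$W1) + rep(params$b1, each = nrow(X))
  A1 <- elu(Z1)
  Z2 <- tcrossprod(A1, params$W2) + rep(params$b2, each = nrow(A1))
  A2 <- elu(Z2)
  drop(tcrossprod(A2, params$W3)) + params$b3
}

#' Evaluate a censoring function
#'
#' @param censor a [planar_censor()] or [learned_censor()].
#' @param x m x 3 matrix of points (mm), or a single 3-vector.
#' @return weights in `[0, 1]`, one per point.
#' @export
censor_eval <- function(censor, x) {
  UseMethod("censor_eval")
}

#' @export
censor_eval.planar_censor <- function(censor, x) {
  X <- as_point_matrix(x)
  if (ncol(X) == 2L) X <- cbind(X, 0)
  if (censor$lambda <= 0) stop("lambda must be > 0")
  d0 <- drop(sweep(X, 2, censor$a0) %*% censor$n0)
  d1 <- drop(sweep(X, 2, censor$a1) %*% censor$n1)
  a <- 0.5 * (tanh(d0 / censor$lambda) + tanh(d1 / censor$lambda))
  pmin(pmax(a, 0), 1)
}

#' @export
censor_eval.learned_censor <- function(censor, x) {
  X <- as_point_matrix(x)
  if (ncol(X) == 2L) X <- cbind(X, 0)
  if (censor$lambda <= 0) stop("lambda must be > 0")
  s <- censor_net_score(censor$params, X)
  0.5 * (tanh(s / censor$lambda) + 1)
}

#' Bandwidth regularization for the censor transition zone
#'
#' \deqn{J_s(\lambda) = \frac{\lambda^2}{0.1}\ln\frac{\lambda^2}{0.1} + 1 -
#'   \frac{\lambda^2}{0.1} \ge 0,}
#' with its unique zero at \eqn{\lambda^2 = 0.1}; the \eqn{\lambda \to 0}
#' limit value is 1.
#'
#' @param lam censor bandwidth (mm).
#' @return scalar penalty.
#' @export
lambda_penalty <- function(lam) {
  x <- lam^2 / 0.1
  if (x == 0) return(1)
  x * log(x) + 1 - x
}

#' Censored varifold action
#'
#' Applies the diffeomorphism action and masks the transported masses with
#' the support weight evaluated at the mapped positions:
#' weights become \eqn{\alpha^\lambda(\varphi(x_i))\,|D\varphi|_{x_i} w_i}.
#'
#' @param mu a [particle_measure()].
#' @param phi a [diffeo_sample()].
#' @param censor a censoring function, or `NULL` for the plain action.
#' @return the censored transported [particle_measure()].
#' @export
censored_action <- function(mu, phi, censor = NULL) {
  out <- apply_varifold_action(mu, phi)
  if (is.null(censor)) return(out)
  alpha <- censor_eval(censor, out$positions)
  particle_measure(out$positions, alpha * out$weights, out$features,
                   normalized = out$normalized, kind = out$kind)
}

#' Training set for the boundary classifier
#'
#' Interior particles carry label 1; dummy boundary particles (placed along
#' the medial edge and as copies beyond the rostral-most and caudal-most
#' sections) carry label 0.  A class-weight ratio balances the typically
#' large interior-to-boundary count discrepancy.
#'
#' @param interior m x 3 matrix of interior particle positions.
#' @param boundary k x 3 matrix of dummy boundary positions.
#' @param class_weight weight multiplier for the boundary class
#'   (default 1000, i.e. 1000:1).
#' @return object of class `boundary_training_set`.
#' @export
boundary_training_set <- function(interior, boundary, class_weight = 1000) {
  interior <- as_point_matrix(interior)
  boundary <- as_point_matrix(boundary)
  if (ncol(interior) == 2L) interior <- cbind(interior, 0)
  if (ncol(boundary) == 2L) boundary <- cbind(boundary, 0)
  if (nrow(interior) == 0L || nrow(boundary) == 0L) {
    stop("both interior and boundary classes must be non-empty")
  }
  structure(list(interior = interior, boundary = boundary,
                 class_weight = class_weight),
            class = "boundary_training_set")
}

#' Fit the learned censor's boundary classifier
#'
#' Trains the 3-layer network by weighted binary cross-entropy on the
#' interior (label 1) versus dummy boundary (label 0) particles, with
#' manual backpropagation and L-BFGS-B.  Deterministic given the seed.
#'
#' @param train a [boundary_training_set()].
#' @param seed integer seed for the parameter initialization.
#' @param lambda tanh temperature of the resulting censor.
#' @param max_iter optimizer budget (default 300).
#' @param tol convergence check: training ends with an error if the final
#'   weighted accuracy is below `tol` on a separable problem is not
#'   required; the final loss is always reported in the result attributes.
#' @return a [learned_censor()]; attributes `loss` and `accuracy` record
#'   the final weighted training loss and accuracy.
#' @export
fit_boundary_classifier <- function(train, seed = 1L, lambda = sqrt(0.1),
                                    max_iter = 300L, tol = 0.5) {
  stopifnot(inherits(train, "boundary_training_set"))
  X <- rbind(train$interior, train$boundary)
  y <- c(rep(1, nrow(train$interior)), rep(0, nrow(train$boundary)))
  wts <- c(rep(1, nrow(train$interior)),
           rep(train$class_weight, nrow(train$boundary)))
  wts <- wts / sum(wts)
  ## standardize inputs for conditioning; fold scaling into the first layer
  mu_x <- colMeans(X)
  sd_x <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2, mu_x), 2, sd_x, "/")

  sizes <- list(W1 = c(15, 3), b1 = 15, W2 = c(5, 15), b2 = 5,
                W3 = c(1, 5), b3 = 1)
  unpack <- function(par) {
    out <- list(); k <- 0
    for (nm in names(sizes)) {
      len <- prod(sizes[[nm]])
      v <- par[k + seq_len(len)]; k <- k + len
      out[[nm]] <- if (length(sizes[[nm]]) == 2) {
        matrix(v, sizes[[nm]][1], sizes[[nm]][2])
      } else v
    }
    out
  }
  loss_grad <- function(par) {
    p <- unpack(par)
    Z1 <- tcrossprod(Xs, p$W1) + rep(p$b1, each = nrow(Xs)); A1 <- elu(Z1)
    Z2 <- tcrossprod(A1, p$W2) + rep(p$b2, each = nrow(A1)); A2 <- elu(Z2)
    s <- drop(tcrossprod(A2, p$W3)) + p$b3
    prob <- 0.5 * (tanh(s / lambda) + 1)
    pc <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
    loss <- -sum(wts * (y * log(pc) + (1 - y) * log(1 - pc)))
    ## backprop
    dprob <- -wts * (y / pc - (1 - y) / (1 - pc))
    ds <- dprob * 0.5 * (1 - tanh(s / lambda)^2) / lambda
    dA2 <- outer(ds, drop(p$W3))
    dW3 <- matrix(ds %*% A2, 1); db3 <- sum(ds)
    dZ2 <- dA2 * elu_grad(Z2)
    dW2 <- crossprod(dZ2, A1); db2 <- colSums(dZ2)
    dA1 <- dZ2 %*% p$W2
    dZ1 <- dA1 * elu_grad(Z1)
    dW1 <- crossprod(dZ1, Xs); db1 <- colSums(dZ1)
    list(loss = loss,
         grad = c(as.numeric(dW1), db1, as.numeric(dW2), db2,
                  as.numeric(dW3), db3))
  }
  set.seed(seed)
  par0 <- stats::rnorm(sum(vapply(sizes, prod, numeric(1))), sd = 0.5)
  fit <- stats::optim(par0, fn = function(p) loss_grad(p)$loss,
                      gr = function(p) loss_grad(p)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 1e5))
  if (!is.finite(fit$value)) {
    stop("boundary classifier failed to converge; final loss ", fit$value)
  }
  p <- unpack(fit$par)
  ## fold the input standardization into the first layer
  p$b1 <- drop(p$b1 - p$W1 %*% (mu_x / sd_x))
  p$W1 <- sweep(p$W1, 2, sd_x, "/")
  cen <- learned_censor(p, lambda = lambda)
  prob <- censor_eval(cen, X)
  acc <- sum(wts * ((prob > 0.5) == (y == 1)))
  if (acc < tol) {
    stop("boundary classifier did not separate the classes; final loss ",
         fit$value)
  }
  attr(cen, "loss") <- fit$value
  attr(cen, "accuracy") <- acc
  cen
}

#' Serialize / restore a censoring function as JSON
#'
#' @param censor a censor object.
#' @param path file path to write to (or read from).
#' @return `read_censor` returns the censor; `write_censor` the path,
#'   invisibly.
#' @export
write_censor <- function(censor, path) {
  if (inherits(censor, "planar_censor")) {
    obj <- list(type = "planar", a0 = censor$a0, n0 = censor$n0,
                a1 = censor$a1, n1 = censor$n1, lambda = censor$lambda)
  } else {
    p <- censor$params
    obj <- list(type = "learned", lambda = censor$lambda,
                layer_sizes = c(3, 15, 5, 1),
                params = lapply(p, function(v) as.numeric(v)))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_censor
#' @export
read_censor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$type == "planar") {
    planar_censor(obj$a0, obj$n0, obj$a1, obj$n1, obj$lambda)
  } else {
    p <- obj$params
    learned_censor(list(W1 = matrix(p$W1, 15, 3), b1 = p$b1,
                        W2 = matrix(p$W2, 5, 15), b2 = p$b2,
                        W3 = matrix(p$W3, 1, 5), b3 = p$b3),
                   lambda = obj$lambda)
  }
}
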