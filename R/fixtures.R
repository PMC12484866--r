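## Seeded generators for every input class the toolkit needs.  All
## generators are pure functions of their arguments (fixed seed => identical
## output), so tests and the acceptance script run without external data.

#' Three-region toy atlas and two-feature rotated target
#'
#' A square atlas (side 1 mm, centered at the origin) parcelled into three
#' homogeneous regions over \{R, G, B\}, and a target of identical outline
#' whose homogeneous black/white feature regions correspond to the atlas
#' partition under a half-turn rotation.  The partition is deliberately
#' asymmetric (a left band plus an unequal top/bottom split of the rest) so
#' that the half-turn is the unique aligning rotation.
#'
#' @param n_side particles per side (default 32, ~1k particles per
#'   measure).
#' @return list with `atlas` (an [atlas_measure()] over regions R, G, B
#'   with target features black/white), `target` (a [particle_measure()]
#'   over \{black, white\}) and `angle_true` (180).
#' @export
make_three_region_toy <- function(n_side = 32L) {
  h <- 1 / n_side
  g <- seq(-0.5 + h / 2, 0.5 - h / 2, length.out = n_side)
  pts <- as.matrix(expand.grid(x = g, y = g))
  region_of <- function(x, y) {
    ifelse(x < -0.1, 1L, ifelse(y >= 0.15, 2L, 3L))
  }
  reg <- region_of(pts[, 1], pts[, 2])
  Pi <- matrix(0, nrow(pts), 3, dimnames = list(NULL, c("R", "G", "B")))
  Pi[cbind(seq_len(nrow(pts)), reg)] <- 1
  atlas <- atlas_measure(cbind(pts, 0), h^2, Pi,
                         feature_labels = c("black", "white"))
  ## target features: the atlas partition seen under a half turn,
  ## region R -> black, G -> white, B -> black
  reg_t <- region_of(-pts[, 1], -pts[, 2])
  feat <- c("black", "white", "black")[reg_t]
  target <- particle_measure(cbind(pts, 0), h^2, feat,
                             labels = c("black", "white"))
  list(atlas = atlas, target = target, angle_true = 180)
}

#' Known-deformation pair for parameter-recovery tests
#'
#' Deforms a regular grid measure by geodesic shooting with small seeded
#' random momenta and returns both measures together with the ground-truth
#' momenta.  If the random momenta produce a degenerate map (nonpositive
#' Jacobian), they are halved and the shot repeated.
#'
#' @param seed integer seed.
#' @param n_side grid particles per side (3D grid, default 3).
#' @param sigma_v flow-kernel bandwidth in mm.
#' @param momenta_scale standard deviation of the space momenta relative to
#'   `sigma_v` (default 0.3).
#' @param n_steps RK4 steps for the generating shot.
#' @return list with `mu`, `nu` (deformed), `rho_x`, `rho_w`, `fk`.
#' @export
make_known_deformation_pair <- function(seed = 1L, n_side = 3L,
                                        sigma_v = 0.5,
                                        momenta_scale = 0.3,
                                        n_steps = 10L) {
  set.seed(seed)
  g <- seq(0, 1, length.out = n_side)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  n <- nrow(pts)
  mu <- particle_measure(pts, 1, rep("a", n), labels = "a")
  fk <- flow_kernel(sigma_v)
  scale <- momenta_scale * sigma_v
  repeat {
    rho_x <- matrix(stats::rnorm(3 * n, sd = scale), n, 3)
    rho_w <- stats::rnorm(n, sd = scale / 4)
    sh <- tryCatch(shoot(geodesic_state(pts, mu$weights, rho_x, rho_w),
                         fk, n_steps),
                   error = function(e) NULL)
    if (!is.null(sh) && all(sh$phi$jacobians > 0)) break
    scale <- scale / 2
    message("degenerate deformation; retrying with halved momenta")
  }
  list(mu = mu, nu = apply_varifold_action(mu, sh$phi),
       rho_x = rho_x, rho_w = rho_w, fk = fk)
}

#' Striped versus uniform synthetic gene field
#'
#' Detections for two genes on the unit square: gene `striped` has a
#' left/right (or banded) Poisson intensity contrast, gene `uniform` is
#' spatially homogeneous Poisson with the same expected total.
#'
#' @param seed integer seed.
#' @param n_expected expected detections per gene (default 4000).
#' @param contrast intensity ratio between high and low stripes (default
#'   4).
#' @param bands number of high-intensity vertical bands (default 1: left
#'   half high).
#' @return data.frame with columns `x`, `y` (mm on `[0,1]`), `feature`.
#' @export
make_striped_gene_field <- function(seed = 1L, n_expected = 4000L,
                                    contrast = 4, bands = 1L) {
  set.seed(seed)
  nA <- stats::rpois(1, n_expected)
  nB <- stats::rpois(1, n_expected)
  ## striped gene: piecewise-constant intensity over 2*bands vertical strips
  n_strip <- 2L * bands
  strip_w <- rep(c(contrast, 1), bands)
  strip_p <- strip_w / sum(strip_w)
  sA <- sample.int(n_strip, nA, replace = TRUE, prob = strip_p)
  xA <- (sA - 1 + stats::runif(nA)) / n_strip
  det <- data.frame(
    x = c(xA, stats::runif(nB)),
    y = stats::runif(nA + nB),
    feature = rep(c("striped", "uniform"), c(nA, nB)),
    stringsAsFactors = FALSE)
  det[sample.int(nrow(det)), , drop = FALSE]
}

#' Censored-slab phantom: full atlas, half-covered deformed target
#'
#' A rectangular slab atlas with two lateral regions; the target keeps only
#' the particles below a known axial cut, deformed by a ground-truth
#' geodesic shot whose momenta live on the measured half only.  This
#' emulates a partially measured specimen whose measured half is smoothly
#' deformed (spatially varying Jacobian) relative to the atlas while the
#' unmeasured half is untouched.  The true support planes are returned for
#' censor construction and recovery checks.
#'
#' The slab is brain-scale (millimeters): sections 1 mm apart along the
#' cut axis, so the censor's preferred transition bandwidth
#' (\eqn{\lambda \approx 0.32} mm, the zero of [lambda_penalty()]) is thin
#' relative to the unmeasured extent.
#'
#' @param seed integer seed (jitters positions and draws the ground-truth
#'   momenta).
#' @param nx,ny,nz atlas grid size (default 3 x 3 x 6).
#' @param z_extent slab length along the cut axis in mm (default 6).
#' @param support_frac fraction of the slab measured (default 0.5).
#' @param deform_scale standard deviation of the ground-truth mass momenta
#'   (space momenta use 1.5x this; default 0.05, giving mean
#'   \eqn{|D\varphi| - 1 \approx 0.3} on the measured half).
#' @param flow_sigma flow-kernel bandwidth of the generating shot (mm).
#' @return list with `atlas` (two-region [atlas_measure()] with features
#'   fA/fB), `target` ([particle_measure()]), `a0`, `n0`, `a1`, `n1` (true
#'   support planes: inward normals), `z_cut`, `true_jacobians` (at the
#'   atlas particles) and `flow_sigma`.
#' @export
make_censored_slab <- function(seed = 1L, nx = 3L, ny = 3L, nz = 6L,
                               z_extent = 6, support_frac = 0.5,
                               deform_scale = 0.05, flow_sigma = 0.6) {
  set.seed(seed)
  gx <- seq(1, 4, length.out = nx)
  gy <- seq(1, 4, length.out = ny)
  gz <- seq(z_extent / (2 * nz), z_extent * (1 - 1 / (2 * nz)),
            length.out = nz)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  pts[, 1:2] <- pts[, 1:2] + matrix(stats::rnorm(2 * nrow(pts), sd = 0.05),
                                    ncol = 2)
  n <- nrow(pts)
  ctr <- c(2.5, 2.5)
  reg <- ifelse(pts[, 1] < ctr[1], 1L, 2L)
  Pi <- matrix(0, n, 2, dimnames = list(NULL, c("left", "right")))
  Pi[cbind(seq_len(n), reg)] <- 1
  atlas <- atlas_measure(pts, 1, Pi, feature_labels = c("fA", "fB"))
  z_cut <- z_extent * support_frac
  keep <- pts[, 3] <= z_cut
  ## ground-truth deformation: in-plane space momenta and mass momenta on
  ## the measured half only
  rho_x <- matrix(0, n, 3)
  rho_w <- rep(0, n)
  rho_x[keep, 1:2] <- stats::rnorm(2 * sum(keep), sd = 1.5 * deform_scale)
  rho_w[keep] <- stats::rnorm(sum(keep), sd = deform_scale)
  sh <- shoot(geodesic_state(pts, 1, rho_x, rho_w), flow_kernel(flow_sigma),
              n_steps = 10L)
  tp <- sh$final$positions[keep, , drop = FALSE]
  feat <- c("fA", "fB")[reg[keep]]
  target <- particle_measure(tp, sh$phi$jacobians[keep], feat,
                             labels = c("fA", "fB"))
  list(atlas = atlas, target = target,
       a0 = c(ctr, 0), n0 = c(0, 0, 1),
       a1 = c(ctr, z_cut), n1 = c(0, 0, -1),
       z_cut = z_cut, true_jacobians = sh$phi$jacobians,
       flow_sigma = flow_sigma)
}

#' Curvilinear-arc phantom for resampling comparisons
#'
#' Particles scattered in a thin annular arc, with two features whose
#' prevalence varies along the arc; the mass lies on a curve rather than a
#' lattice, the regime where optimized particle placement beats regridding.
#'
#' @param seed integer seed.
#' @param n number of particles (default 600).
#' @param radius arc radius in mm (default 1).
#' @param thickness radial thickness in mm (default 0.05).
#' @param arc_span angular span in radians (default `pi`).
#' @return a [particle_measure()].
#' @export
make_curvilinear_arc <- function(seed = 1L, n = 600L, radius = 1,
                                 thickness = 0.05, arc_span = pi) {
  set.seed(seed)
  th <- stats::runif(n, 0, arc_span)
  r <- radius + stats::rnorm(n, sd = thickness)
  pts <- cbind(r * cos(th), r * sin(th), 0)
  pA <- th / arc_span  # feature gradient along the arc
  feat <- ifelse(stats::runif(n) < pA, "geneA", "geneB")
  particle_measure(pts, 1 / n, feat, labels = c("geneA", "geneB"))
}

#' Four-region phantom with concentrated per-region laws
#'
#' A 2D grid atlas split into quadrant regions; the target shares the
#' geometry, with each region expressing a single distinct feature.  Used
#' for latent-law recovery: the estimated normalized laws should
#' concentrate on each region's true feature.
#'
#' @param seed integer seed (small positional jitter).
#' @param n_side grid particles per side (default 8).
#' @return list with `atlas` (4 regions, 4 target features) and `target`;
#'   `truth` names each region's true feature.
#' @export
make_law_recovery_phantom <- function(seed = 1L, n_side = 8L) {
  set.seed(seed)
  g <- seq(0.5 / n_side, 1 - 0.5 / n_side, length.out = n_side)
  pts <- as.matrix(expand.grid(x = g, y = g))
  pts <- pts + matrix(stats::rnorm(2 * nrow(pts), sd = 0.005), ncol = 2)
  n <- nrow(pts)
  reg <- 1L + (pts[, 1] >= 0.5) + 2L * (pts[, 2] >= 0.5)
  regions <- c("q1", "q2", "q3", "q4")
  feats <- c("geneW", "geneX", "geneY", "geneZ")
  Pi <- matrix(0, n, 4, dimnames = list(NULL, regions))
  Pi[cbind(seq_len(n), reg)] <- 1
  atlas <- atlas_measure(cbind(pts, 0), 1, Pi, feature_labels = feats)
  target <- particle_measure(cbind(pts, 0), 1, feats[reg],
                             labels = feats)
  list(atlas = atlas, target = target,
       truth = stats::setNames(feats, regions))
}

#' Section stack phantom with an asymmetric footprint
#'
#' A stack of near-identical 2D sections shaped like an asymmetric "C"
#' (an annular arc plus a bar), with two particle labels and small seeded
#' positional jitter per section.  The shape has no rotational symmetry, so
#' rigid alignment has a unique optimum.
#'
#' @param seed integer seed.
#' @param n_sections number of sections (default 5).
#' @param n_per particles per section (default 80).
#' @param spacing inter-section spacing in mm.
#' @param jitter per-section positional noise sd in mm (default 0.005).
#' @return a [section_stack()].
#' @export
make_section_stack <- function(seed = 1L, n_sections = 5L, n_per = 80L,
                               spacing = 0.2, jitter = 0.005) {
  set.seed(seed)
  n_arc <- round(0.7 * n_per)
  n_bar <- n_per - n_arc
  th <- stats::runif(n_arc, -0.75 * pi, 0.6 * pi)
  base <- rbind(
    cbind(cos(th) + stats::rnorm(n_arc, sd = 0.03),
          sin(th) + stats::rnorm(n_arc, sd = 0.03)),
    cbind(stats::runif(n_bar, 0.1, 0.9), stats::rnorm(n_bar, sd = 0.05)))
  lab <- rep(c("typeA", "typeB"), c(n_arc, n_bar))
  secs <- lapply(seq_len(n_sections), function(s) {
    pos <- base + matrix(stats::rnorm(2 * n_per, sd = jitter), ncol = 2)
    particle_measure(cbind(pos, 0), 1 / n_per, lab,
                     labels = c("typeA", "typeB"))
  })
  section_stack(secs, spacing = spacing)
}
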