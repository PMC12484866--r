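test_that("lattice initialization books mass exactly and seeds stably", {
  mu <- random_measure(100, 3, seed = 2, box = 1)
  cfg <- resampling_config(sigma = 0.25, seed = 7)
  a0 <- init_lattice_approximation(mu, cfg)
  expect_equal(sum(a0$Q), total_mass(mu), tolerance = 1e-12)
  # uniform laws at init
  expect_equal(a0$Q / rowSums(a0$Q), matrix(1 / 3, nrow(a0$Q), 3),
               ignore_attr = TRUE)
  # positions are selected high-resolution particles
  expect_true(all(apply(a0$positions, 1, function(p) {
    any(rowSums(abs(sweep(mu$positions, 2, p))) < 1e-12)
  })))
  a0b <- init_lattice_approximation(mu, cfg)
  expect_identical(a0$positions, a0b$positions)
  # all particles in one cube collapse to a single approximation particle
  tight <- random_measure(10, 2, seed = 3, box = 0.05)
  one <- init_lattice_approximation(tight, resampling_config(sigma = 1))
  expect_equal(nrow(one$positions), 1)
  expect_equal(sum(one$Q), total_mass(tight))
  expect_error(init_lattice_approximation(
    particle_measure(matrix(0, 1, 3), 1, "a"), "bad"), "resampling_config")
})

test_that("objective decreases across stages and matches the norm distance", {
  mu <- make_curvilinear_arc(seed = 2, n = 300)
  cfg <- resampling_config(sigma = 0.15, seed = 3)
  fits <- resample_scale_space(mu, cfg)
  expect_gte(fits$init$objective, fits$weights$objective)
  expect_gte(fits$weights$objective, fits$joint$objective)
  # positions unchanged by the weights stage
  expect_equal(fits$weights$positions, fits$init$positions)
  # objective is the squared varifold distance of the induced measure
  m <- approximation_measure(fits$joint)
  expect_equal(approximation_objective(fits$joint, mu),
               varifold_norm_dist2(m, mu, cfg$ks), tolerance = 1e-9)
  # total mass drifts less than 2% under free-weight optimization
  expect_lt(abs(sum(fits$joint$Q) - total_mass(mu)) / total_mass(mu), 0.02)
  # determinism
  fits2 <- resample_scale_space(mu, cfg)
  expect_equal(fits$joint$positions, fits2$joint$positions)
  expect_equal(fits$joint$Q, fits2$joint$Q)
})

test_that("single-feature targets concentrate the optimized laws", {
  set.seed(4)
  mu <- particle_measure(matrix(stats::runif(90), 30, 3), 1,
                         rep("only", 30), labels = c("only", "other"))
  cfg <- resampling_config(sigma = 0.4, seed = 1)
  a1 <- optimize_weights_features(init_lattice_approximation(mu, cfg), mu, cfg)
  P <- a1$Q / rowSums(a1$Q)
  # mass-weighted concentration on the observed feature; individual
  # low-mass particles decay more slowly under the log parameterization
  expect_gt(stats::weighted.mean(P[, "only"], rowSums(a1$Q)), 0.98)
  expect_true(all(P[, "only"] > 0.7))
  expect_lt(a1$objective, init_lattice_approximation(mu, cfg)$objective)
})

test_that("joint stage moves particles toward curvilinear geometry", {
  mu <- make_curvilinear_arc(seed = 5, n = 400, radius = 1, thickness = 0.03)
  cfg <- resampling_config(sigma = 0.2, seed = 2)
  fits <- resample_scale_space(mu, cfg)
  dist_to_arc <- function(X) mean(abs(sqrt(X[, 1]^2 + X[, 2]^2) - 1))
  expect_lt(dist_to_arc(fits$joint$positions),
            dist_to_arc(fits$init$positions))
  # at a scale far below particle spacing the particles barely move
  tiny <- resampling_config(sigma = 0.002, seed = 2, iter_joint = 50)
  small <- optimize_joint(optimize_weights_features(
    init_lattice_approximation(mu, tiny), mu, tiny), mu, tiny)
  move <- sqrt(rowSums((small$positions -
                          init_lattice_approximation(mu, tiny)$positions)^2))
  expect_lt(mean(move), 0.05 * 0.002)
})

test_that("k-means baseline recovers structure and exact budgets", {
  mu <- random_measure(40, 2, seed = 6)
  km <- kmeans_baseline(mu, K = n_particles(mu), seed = 1)
  expect_equal(n_particles(km), n_particles(mu))
  expect_equal(total_mass(km), total_mass(mu), tolerance = 1e-9)
  # K = 1: single centroid at the unweighted mean (Lloyd on positions)
  one <- kmeans_baseline(mu, K = 1, seed = 1)
  expect_equal(drop(one$positions), colMeans(mu$positions), tolerance = 1e-9)
  # two well-separated blobs
  set.seed(8)
  blobs <- particle_measure(
    rbind(matrix(stats::rnorm(60, 0, 0.05), 20, 3),
          matrix(stats::rnorm(60, 5, 0.05), 20, 3)),
    1, rep(c("a", "b"), each = 20))
  two <- kmeans_baseline(blobs, K = 2, seed = 2)
  centers <- two$positions[order(two$positions[, 1]), ]
  expect_lt(max(abs(centers[1, ] - 0)), 0.2)
  expect_lt(max(abs(centers[2, ] - 5)), 0.2)
  expect_error(kmeans_baseline(mu, K = 100), "exceed")
})

test_that("grid baseline conserves mass and spreads uniform fields evenly", {
  mu <- random_measure(200, 3, seed = 9)
  gr <- grid_resample_baseline(mu, sigma = 0.3)
  expect_equal(total_mass(gr), total_mass(mu), tolerance = 1e-9)
  # single particle at a node keeps all mass there
  single <- particle_measure(matrix(c(0.5, 0.5, 0.5), 1, 3), 2, "a")
  out <- grid_resample_baseline(single, 1, nodes = matrix(c(0.5, 0.5, 0.5), 1, 3))
  expect_equal(out$weights, 2)
  # uniform field: interior node masses nearly equal
  set.seed(10)
  unif <- particle_measure(matrix(stats::runif(3000, 0, 2), 1000, 3), 1,
                           rep("a", 1000))
  gru <- grid_resample_baseline(unif, 0.4)
  interior <- apply(gru$positions, 1, function(p) all(p > 0.5 & p < 1.5))
  cv <- stats::sd(gru$weights[interior]) / mean(gru$weights[interior])
  expect_lt(cv, 0.25)
})

test_that("scheme comparison enforces matched budgets", {
  mu <- make_curvilinear_arc(seed = 11, n = 300)
  cmp <- compare_schemes(mu, resampling_config(sigma = 0.2, seed = 4))
  expect_equal(length(unique(cmp$particles)), 1)
  expect_setequal(cmp$scheme, c("optimized", "kmeans", "grid"))
  expect_true(all(cmp$dist2 > -1e-9))
})

test_that("coarser scales use fewer particles and approximate less closely", {
  mu <- make_curvilinear_arc(seed = 12, n = 400)
  ks_ref <- space_kernel(0.2)
  f_coarse <- resample_scale_space(mu, resampling_config(sigma = 0.4, seed = 1))
  f_fine <- resample_scale_space(mu, resampling_config(sigma = 0.2, seed = 1))
  expect_lt(nrow(f_coarse$joint$positions), nrow(f_fine$joint$positions))
  d_coarse <- varifold_norm_dist2(approximation_measure(f_coarse$joint), mu, ks_ref)
  d_fine <- varifold_norm_dist2(approximation_measure(f_fine$joint), mu, ks_ref)
  expect_lte(d_fine, d_coarse)
})
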