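test_that("space kernel evaluates its closed form and rejects bad input", {
  ks1 <- space_kernel(1)
  expect_equal(space_kernel_eval(ks1, c(0, 0, 0), c(0, 0, 0)), 1)
  ks2 <- space_kernel(c(0.15, 0.75))
  expect_equal(space_kernel_eval(ks2, c(1, 2, 3), c(1, 2, 3)), 2)
  # unit distance, sigma 1
  expect_equal(space_kernel_eval(ks1, c(0, 0, 0), c(1, 0, 0)), exp(-0.5),
               tolerance = 1e-12)
  # symmetry
  x <- c(0.3, -0.2, 1); y <- c(-1, 0.4, 0.2)
  expect_equal(space_kernel_eval(ks2, x, y), space_kernel_eval(ks2, y, x))
  expect_error(space_kernel(0), "bandwidth")
  expect_error(space_kernel_eval(ks1, c(NA, 0, 0), c(0, 0, 0)), "finite")
})

test_that("particle measures enforce their invariants", {
  expect_error(particle_measure(matrix(0, 2, 3), c(1, -1),
                                c("a", "b")), ">= 0")
  expect_error(particle_measure(matrix(0, 2, 3), c(1, 1),
                                matrix(1, 2, 2,
                                       dimnames = list(NULL, c("a", "a")))),
               "unique")
  m <- particle_measure(matrix(0, 2, 3), 1, c("a", "b"))
  expect_true(m$normalized)
  expect_equal(total_mass(m), 2)
  expect_error(particle_measure(matrix(0, 1, 3), 1, matrix(0.7, 1, 2),
                                normalized = TRUE), "sum to 1")
})

test_that("inner product matches trivial closed forms", {
  ks <- space_kernel(0.5)
  one <- particle_measure(matrix(0, 1, 3), 2, "a", labels = c("a", "b"))
  expect_equal(varifold_inner_product(one, one, ks), 4)
  # disjoint single labels kill the cross term
  two <- particle_measure(rbind(c(0, 0, 0), c(0.3, 0, 0)), c(1.5, 2),
                          c("a", "b"))
  k12 <- space_kernel_eval(ks, c(0, 0, 0), c(0.3, 0, 0))
  expect_equal(varifold_inner_product(two, two, ks), 1.5^2 + 2^2,
               tolerance = 1e-12)
  # mismatched feature spaces rejected
  other <- particle_measure(matrix(0, 1, 3), 1, "c", labels = c("c", "d"))
  expect_error(varifold_inner_product(one, other, ks), "feature space")
})

test_that("inner product equals the brute-force quadruple-sum oracle", {
  ks <- space_kernel(c(0.2, 0.6), weight = c(1, 0.5))
  for (seed in 1:3) {
    mu <- random_measure(10, 3, seed = seed)
    nu <- random_measure(8, 3, seed = seed + 100)
    expect_close(varifold_inner_product(mu, nu, ks), brute_inner(mu, nu, ks))
    expect_close(varifold_inner_product(mu, mu, ks), brute_inner(mu, mu, ks))
  }
  # a larger instance, still brute-forced
  mu <- random_measure(50, 5, seed = 42)
  expect_close(varifold_inner_product(mu, mu, ks), brute_inner(mu, mu, ks))
})

test_that("inner product is symmetric, bilinear, and PSD on Gram matrices", {
  ks <- space_kernel(0.4)
  mu <- random_measure(12, 4, seed = 7)
  nu <- random_measure(9, 4, seed = 8)
  expect_equal(varifold_inner_product(mu, nu, ks),
               varifold_inner_product(nu, mu, ks), tolerance = 1e-12)
  # bilinearity in the weights
  mu2 <- mu; mu2$weights <- 3 * mu$weights
  expect_equal(varifold_inner_product(mu2, nu, ks),
               3 * varifold_inner_product(mu, nu, ks), tolerance = 1e-9)
  # Gram matrix over single-particle pieces is PSD
  singles <- lapply(seq_len(n_particles(mu)), function(i) subset_single(mu, i))
  G <- outer(seq_along(singles), seq_along(singles),
             Vectorize(function(i, j) {
               varifold_inner_product(singles[[i]], singles[[j]], ks)
             }))
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
})

test_that("norm distance expands from inner products and is nonnegative", {
  ks <- space_kernel(0.3)
  mu <- random_measure(10, 3, seed = 11)
  nu <- random_measure(10, 3, seed = 12)
  expect_equal(varifold_norm_dist2(mu, mu, ks), 0, tolerance = 1e-10)
  d <- varifold_norm_dist2(mu, nu, ks)
  expect_gt(d, -1e-9)
  expect_close(d, brute_inner(mu, mu, ks) - 2 * brute_inner(mu, nu, ks) +
                 brute_inner(nu, nu, ks), tol = 1e-9)
  # single particle, weight doubled: distance (2w - w)^2 * K(0) = w^2
  one <- particle_measure(matrix(0, 1, 3), 1.3, "a")
  two <- one; two$weights <- 2.6
  expect_equal(varifold_norm_dist2(one, two, ks), 1.3^2, tolerance = 1e-12)
})

test_that("norm distance grows monotonically with translation", {
  ks <- space_kernel(0.5)
  one <- particle_measure(matrix(0, 1, 3), 1, "a")
  d <- vapply(c(0.05, 0.2, 0.5, 1), function(s) {
    moved <- particle_measure(matrix(c(s, 0, 0), 1, 3), 1, "a")
    varifold_norm_dist2(one, moved, ks)
  }, numeric(1))
  expect_true(all(diff(d) > 0))
  expect_lt(d[1], 0.01)
})

test_that("varifold action maps positions, scales mass by the Jacobian", {
  mu <- random_measure(15, 3, seed = 5)
  # identity
  id <- diffeo_sample(mu$positions, 1)
  out <- apply_varifold_action(mu, id)
  expect_equal(out$positions, mu$positions)
  expect_equal(out$weights, mu$weights)
  # uniform scaling by 2: |Dphi| = 8, mass x8
  sc <- diffeo_sample(2 * mu$positions, 8)
  out <- apply_varifold_action(mu, sc)
  expect_equal(total_mass(out), 8 * total_mass(mu))
  expect_equal(out$positions, 2 * mu$positions)
  expect_equal(out$features, mu$features)
  # translation conserves mass
  tr <- diffeo_sample(sweep(mu$positions, 2, c(1, -2, 0.5), "+"), 1)
  expect_equal(total_mass(apply_varifold_action(mu, tr)), total_mass(mu))
  # degenerate map rejected
  expect_error(diffeo_sample(mu$positions, c(rep(1, 14), -0.1)), "> 0")
})

test_that("truncated kernel sums equal exact sums inside the radius", {
  ks <- space_kernel(0.3)
  mu <- random_measure(20, 3, seed = 9, box = 0.5)  # all pairs well inside 4*sigma
  exact <- varifold_inner_product(mu, mu, ks)
  trunc <- varifold_inner_product(mu, mu, ks, truncate = 4 * 0.3)
  expect_close(trunc, exact, tol = 1e-12)
})
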