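random_state <- function(n, seed = 1, mom_sd = 0.3) {
  set.seed(seed)
  geodesic_state(matrix(stats::rnorm(n * 3), n, 3),
                 stats::runif(n, 0.5, 2),
                 matrix(stats::rnorm(n * 3, sd = mom_sd), n, 3),
                 stats::rnorm(n, sd = mom_sd))
}

test_that("velocity field reduces to closed forms", {
  fk <- flow_kernel(0.8)
  st0 <- random_state(6, seed = 2)
  st0$rho_x[] <- 0; st0$rho_w[] <- 0
  expect_equal(max(abs(velocity_field(st0, fk, matrix(rnorm(9), 3, 3)))), 0)
  # single particle, no mass momentum: v at the particle equals rho_x
  st1 <- geodesic_state(matrix(c(0.2, -1, 0.5), 1, 3), 1.5,
                        matrix(c(1, 2, -3), 1, 3), 0)
  expect_equal(drop(velocity_field(st1, fk, st1$positions)), c(1, 2, -3))
})

test_that("divergence matches finite differences of the velocity field", {
  fk <- flow_kernel(0.7)
  st <- random_state(7, seed = 3)
  q <- matrix(stats::rnorm(9), 3, 3)
  dv <- velocity_divergence(st, fk, q)
  eps <- 1e-5
  num <- vapply(1:3, function(m) {
    s <- 0
    for (d in 1:3) {
      qp <- q; qm <- q
      qp[m, d] <- qp[m, d] + eps; qm[m, d] <- qm[m, d] - eps
      s <- s + (velocity_field(st, fk, qp)[m, d] -
                  velocity_field(st, fk, qm)[m, d]) / (2 * eps)
    }
    s
  }, numeric(1))
  expect_lt(max(abs(dv - num)), 1e-5)
  # pure space momentum: divergence vanishes at the particle itself
  st1 <- geodesic_state(matrix(0, 1, 3), 1, matrix(c(1, 0, 0), 1, 3), 0)
  expect_equal(velocity_divergence(st1, fk, st1$positions), 0)
})

test_that("Hamiltonian closed forms and position gradient are exact", {
  fk <- flow_kernel(0.8)
  st0 <- random_state(5, seed = 4)
  st0$rho_x[] <- 0; st0$rho_w[] <- 0
  expect_equal(hamiltonian(st0, fk), 0)
  # one landmark: H = 0.5 * |rho_x|^2
  st1 <- geodesic_state(matrix(0, 1, 3), 1, matrix(c(1, 2, 2), 1, 3), 0)
  expect_equal(hamiltonian(st1, fk), 0.5 * 9)
  # analytic grad_x H vs central differences
  st <- random_state(6, seed = 5)
  g <- ivmatch:::grad_x_hamiltonian(st, fk)
  eps <- 1e-5
  for (m in c(1, 4)) for (d in 1:3) {
    sp <- st; sm <- st
    sp$positions[m, d] <- sp$positions[m, d] + eps
    sm$positions[m, d] <- sm$positions[m, d] - eps
    num <- (hamiltonian(sp, fk) - hamiltonian(sm, fk)) / (2 * eps)
    expect_lt(abs(g[m, d] - num), 1e-7)
  }
})

test_that("one-landmark geodesic is a unit translation", {
  fk <- flow_kernel(0.8)
  st <- geodesic_state(matrix(0, 1, 3), 1, matrix(c(1, 0, 0), 1, 3), 0)
  out <- shoot(st, fk, n_steps = 40)
  expect_lt(max(abs(out$final$positions - c(1, 0, 0))), 1e-3)
  expect_equal(out$phi$jacobians, 1, tolerance = 1e-8)
})

test_that("Hamiltonian is conserved with drift decreasing in step count", {
  fk <- flow_kernel(0.8)
  st <- random_state(20, seed = 6, mom_sd = 0.2)
  H0 <- hamiltonian(st, fk)
  drift <- vapply(c(10, 40), function(ns) {
    out <- shoot(st, fk, n_steps = ns)
    abs(hamiltonian(out$final, fk) - H0) / abs(H0)
  }, numeric(1))
  expect_lt(drift[1], 1e-3)
  expect_lt(drift[2], 1e-4)
  expect_lt(drift[2], drift[1])
})

test_that("zero momenta give the identity and shooting composes in time", {
  fk <- flow_kernel(0.6)
  st <- random_state(8, seed = 7)
  st0 <- st; st0$rho_x[] <- 0; st0$rho_w[] <- 0
  out <- shoot(st0, fk, n_steps = 5)
  expect_equal(out$final$positions, st0$positions)
  expect_equal(out$final$weights, st0$weights)
  expect_equal(out$phi$jacobians, rep(1, 8))
  # composition: integrate halfway, then re-shoot from the midpoint state
  # with momenta rescaled for the remaining half-time (the Hamiltonian is
  # quadratic, so flowing for time 1/2 equals unit-time flow at half momenta)
  full <- shoot(st, fk, n_steps = 40, keep_trajectory = TRUE)
  mid <- full$trajectory[[21]]
  second <- geodesic_state(mid$positions, mid$weights,
                           mid$rho_x / 2, mid$rho_w / 2)
  resumed <- shoot(second, fk, n_steps = 20)
  expect_lt(max(abs(resumed$final$positions - full$final$positions)), 1e-6)
})

test_that("weights evolve with the divergence and match the Jacobian", {
  fk <- flow_kernel(0.7)
  st <- random_state(10, seed = 8, mom_sd = 0.1)
  out <- shoot(st, fk, n_steps = 20)
  expect_equal(out$final$weights / st$weights, out$phi$jacobians,
               tolerance = 1e-6)
  expect_true(all(out$final$weights >= 0))
  # passive points follow the same flow as control particles placed there
  out2 <- shoot(st, fk, n_steps = 20, passive = st$positions[1:3, ])
  expect_equal(out2$passive, out$final$positions[1:3, ], tolerance = 1e-10)
  expect_equal(out2$passive_jacobians, out$phi$jacobians[1:3],
               tolerance = 1e-10)
})
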