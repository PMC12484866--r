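# Independent brute-force oracles and small random-measure builders shared
# across the suite.  The oracles deliberately use naive loops so they stay
# independent of the vectorized implementation paths they check.

random_measure <- function(n, n_feat = 3, seed = 1, box = 1) {
  set.seed(seed)
  labels <- paste0("f", seq_len(n_feat))
  P <- matrix(stats::rexp(n * n_feat), n, n_feat)
  P <- P / rowSums(P)
  colnames(P) <- labels
  particle_measure(matrix(stats::runif(n * 3, 0, box), n, 3),
                   stats::runif(n, 0.5, 2), P)
}

# literal quadruple-sum evaluation of the varifold inner product
brute_inner <- function(mu, nu, ks) {
  total <- 0
  for (i in seq_len(n_particles(mu))) {
    for (j in seq_len(n_particles(nu))) {
      kxy <- space_kernel_eval(ks, mu$positions[i, ], nu$positions[j, ])
      fsum <- 0
      for (f in seq_along(mu$labels)) {
        for (g in seq_along(nu$labels)) {
          if (f == g) fsum <- fsum + mu$features[i, f] * nu$features[j, g]
        }
      }
      total <- total + mu$weights[i] * nu$weights[j] * kxy * fsum
    }
  }
  total
}

# exhaustive enumeration of the megasquare sample space for conditional MI
brute_mi <- function(binned_mat, K) {
  nx <- nrow(binned_mat); ny <- ncol(binned_mat)
  side <- 2 * K
  corners <- expand.grid(ci = seq_len(nx - side + 1),
                         cj = seq_len(ny - side + 1))
  rows <- list()
  for (r in seq_len(nrow(corners))) {
    for (i in seq_len(side)) for (j in seq_len(side)) for (d in c("h", "v")) {
      m <- binned_mat[corners$ci[r] + i - 1, corners$cj[r] + j - 1]
      rows[[length(rows) + 1]] <- data.frame(
        c = r, x = split_label(i, j, d, K), m = m)
    }
  }
  om <- do.call(rbind, rows)
  total <- 0
  n_om <- nrow(om)
  for (cc in unique(om$c)) {
    sub <- om[om$c == cc, ]
    pc <- nrow(sub) / n_om
    for (x in unique(sub$x)) for (m in unique(sub$m)) {
      pxm <- mean(sub$x == x & sub$m == m)
      if (pxm == 0) next
      px <- mean(sub$x == x); pm <- mean(sub$m == m)
      total <- total + pc * pxm * log(pxm / (px * pm))
    }
  }
  total
}

expect_close <- function(x, y, tol = 1e-10) {
  expect_lt(abs(x - y) / max(1e-12, abs(y)), tol)
}

# row matcher for exact position lookups in fixtures
match_rows <- function(A, B, tol = 1e-9) {
  vapply(seq_len(nrow(A)), function(i) {
    which(rowSums(abs(sweep(B, 2, A[i, ]))) < tol)[1]
  }, integer(1))
}

subset_single <- function(mu, i) {
  particle_measure(mu$positions[i, , drop = FALSE], mu$weights[i],
                   mu$features[i, , drop = FALSE])
}
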