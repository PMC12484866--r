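test_that("rasterization counts detections with a half-open convention", {
  det <- data.frame(x = c(0.01, 0.5, 0.99), y = c(0.01, 0.5, 0.99),
                    feature = c("g1", "g1", "g2"))
  gc <- rasterize_counts(det, sigma = 0.5, bbox = c(0, 1, 0, 1))
  expect_equal(dim(gc$counts), c(2, 2, 2))
  expect_equal(sum(gc$counts[, , "g1"]), 2)
  expect_equal(sum(gc$counts[, , "g2"]), 1)
  # the edge detection at exactly 0.5 opens the second square
  expect_equal(unname(gc$counts[2, 2, "g1"]), 1L)
  # totals conserved on random scatter
  set.seed(1)
  det2 <- data.frame(x = stats::runif(500), y = stats::runif(500),
                     feature = sample(c("a", "b"), 500, TRUE))
  gc2 <- rasterize_counts(det2, sigma = 0.1, bbox = c(0, 1, 0, 1))
  expect_equal(sum(gc2$counts[, , "a"]), sum(det2$feature == "a"))
  expect_error(rasterize_counts(data.frame(x = NA, y = 1, feature = "a"),
                                0.1, c(0, 1, 0, 1)), "finite")
})

test_that("quantile binning follows the empirical CDF and is rank-invariant", {
  # constant counts collapse to one bin
  det <- data.frame(x = rep(seq(0.05, 0.95, by = 0.1), each = 10),
                    y = rep(seq(0.05, 0.95, by = 0.1), times = 10),
                    feature = "g")
  gc <- rasterize_counts(det, sigma = 0.1, bbox = c(0, 1, 0, 1))
  qb <- quantile_bin(gc, q = 4)
  expect_equal(length(unique(as.integer(qb$binned))), 1)
  # distinct counts 1..100 with q = 4: thresholds at the 25/50/75/100
  # quantiles give bins of ~25 squares (the maximum opens a bin of its own)
  gc$counts[, , 1] <- matrix(1:100, 10, 10)
  gc$mask[] <- TRUE
  qb <- quantile_bin(gc, q = 4)
  expect_equal(as.integer(table(qb$binned)), c(24L, 25L, 25L, 25L, 1L))
  # a monotone transform of the counts leaves the bins unchanged
  gc2 <- gc
  gc2$counts[, , 1] <- gc$counts[, , 1]^2 + 3L
  expect_equal(quantile_bin(gc2, q = 4)$binned, qb$binned)
  expect_error(quantile_bin(gc, q = 1), "q must be")
})

test_that("split labels follow the megasquare case table", {
  K <- 2
  expect_equal(split_label(1, 1, "h", K), "l")
  expect_equal(split_label(K + 1, 1, "h", K), "r")
  expect_equal(split_label(1, 2 * K, "v", K), "t")
  expect_equal(split_label(1, K, "v", K), "b")
  # the two halves are equal-sized for both directions
  grid <- expand.grid(i = 1:(2 * K), j = 1:(2 * K))
  for (d in c("h", "v")) {
    labs <- split_label(grid$i, grid$j, d, K)
    expect_equal(as.integer(table(labs)), c(2 * K^2, 2 * K^2))
  }
  expect_error(split_label(0, 1, "h", K), "out of")
})

test_that("mi_score equals the exhaustive sample-space oracle", {
  set.seed(3)
  for (K in c(1, 2)) {
    m <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
    ens <- megasquare_ensemble(8, 8, K = K)
    expect_close(mi_score(m, ens)[[1]], brute_mi(m, K), tol = 1e-12)
  }
})

test_that("mi_score is zero for constant fields and maximal for clean splits", {
  ens <- megasquare_ensemble(8, 8, K = 2)
  expect_equal(mi_score(matrix(5L, 8, 8), ens)[[1]], 0)
  # single megasquare, feature present exactly in the left half: the
  # horizontal direction is fully informative, the vertical not at all;
  # I(X; M | C) = 0.5 * log 2
  ens1 <- megasquare_ensemble(4, 4, K = 2)
  half <- matrix(rep(c(1L, 0L), c(8, 8)), 4, 4)
  expect_equal(mi_score(half, ens1)[[1]], 0.5 * log(2), tolerance = 1e-12)
  expect_close(mi_score(half, ens1)[[1]], brute_mi(half, 2), tol = 1e-12)
})

test_that("permuting square positions destroys the score", {
  # binary stripes at the megasquare half-width: strong spatial structure
  # whose permutation null collapses to the small-sample bias floor
  g <- 24; K <- 6
  pat <- rep(rep(c(1L, 0L), each = K), length.out = g)
  m <- outer(pat, rep(1L, g))
  ens <- megasquare_ensemble(g, g, K = K)
  structured <- mi_score(m, ens)[[1]]
  set.seed(21)
  perms <- replicate(20, mi_score(matrix(sample(as.integer(m)), g, g),
                                  ens)[[1]])
  expect_lt(mean(perms), 0.05 * structured)
  # the Poisson striped-gene field shows the same collapse relative to the
  # structured score, above its own permutation floor
  det <- make_striped_gene_field(seed = 13, n_expected = 3000)
  gc <- rasterize_counts(det, sigma = 0.05, bbox = c(0, 1, 0, 1))
  qb <- quantile_bin(gc, q = 10)
  ens4 <- megasquare_ensemble(dim(gc$counts)[1], dim(gc$counts)[2], K = 4)
  structured2 <- mi_score(qb, ens4)[["striped"]]
  set.seed(22)
  b <- qb$binned[, , "striped"]
  perm2 <- mi_score(matrix(sample(as.integer(b)), nrow(b), ncol(b)),
                    ens4)[[1]]
  expect_lt(perm2, structured2)
})

test_that("ranking is by descending score with lexicographic ties", {
  s <- c(b = 0.2, a = 0.5, c = 0.2)
  expect_equal(rank_features(s), c("a", "b", "c"))
  expect_equal(rank_features(s, 2), c("a", "b"))
  expect_error(rank_features(s, 5), "exceeds")
})

test_that("section aggregation tallies scores with missing features as zero", {
  s1 <- c(a = 1, b = 2)
  s2 <- c(b = 0.5, c = 3)
  expect_equal(aggregate_sections(list(s1)), sort(s1))
  expect_equal(aggregate_sections(list(s1, s1)), 2 * sort(s1))
  agg <- aggregate_sections(list(s1, s2))
  expect_equal(agg, c(a = 1, b = 2.5, c = 3))
})
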