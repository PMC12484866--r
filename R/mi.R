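#' Rasterize point detections onto a square-grid count image
#'
#' Covers the bounding box with squares of size `sigma x sigma` (half-open
#' convention: a detection on a lower/left edge belongs to the square it
#' opens) and counts detections per square and feature.
#'
#' @param detections data.frame with columns `x`, `y` (mm) and `feature`.
#' @param sigma square edge in mm (default 0.05, i.e. 50 microns).
#' @param bbox numeric vector `c(xmin, xmax, ymin, ymax)`; default the data
#'   range.
#' @return object of class `grid_counts`: a list with `counts` (nx x ny x F
#'   integer array), `features`, `sigma`, `origin`, and `mask` (occupied
#'   squares: any detection of any feature).
#' @export
rasterize_counts <- function(detections, sigma = 0.05, bbox = NULL) {
  stopifnot(all(c("x", "y", "feature") %in% names(detections)))
  x <- as.numeric(detections$x); y <- as.numeric(detections$y)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite detection coordinates")
  }
  if (is.null(bbox)) bbox <- c(min(x), max(x), min(y), max(y))
  if (any(x < bbox[1] | x > bbox[2] | y < bbox[3] | y > bbox[4])) {
    stop("detections fall outside the bounding box")
  }
  nx <- max(1L, ceiling((bbox[2] - bbox[1]) / sigma))
  ny <- max(1L, ceiling((bbox[4] - bbox[3]) / sigma))
  ix <- pmin(1L + floor((x - bbox[1]) / sigma), nx)
  iy <- pmin(1L + floor((y - bbox[3]) / sigma), ny)
  feats <- sort(unique(as.character(detections$feature)))
  counts <- array(0L, dim = c(nx, ny, length(feats)),
                  dimnames = list(NULL, NULL, feats))
  for (k in seq_along(feats)) {
    sel <- detections$feature == feats[k]
    if (any(sel)) {
      tab <- table(factor(ix[sel], levels = seq_len(nx)),
                   factor(iy[sel], levels = seq_len(ny)))
      counts[, , k] <- as.integer(tab)
    }
  }
  mask <- apply(counts, c(1, 2), sum) > 0
  structure(list(counts = counts, features = feats, sigma = sigma,
                 origin = c(bbox[1], bbox[3]), mask = mask),
            class = "grid_counts")
}

#' Quantile binning of grid counts
#'
#' Per feature, bins the per-square counts by the empirical CDF over
#' occupied squares: thresholds \eqn{t_k = \inf\{t \ge 0 : F^g(t) \ge
#' k/q\}} and binning map \eqn{\phi^g(n) = \sum_k 1\{n \ge t_k\}}.  The map
#' is invariant under monotone transforms of the counts.
#'
#' @param counts a [rasterize_counts()] result.
#' @param q number of quantiles, >= 2.
#' @return list with `binned` (nx x ny x F array of bins in `0..q`) and
#'   `thresholds` (q x F).
#' @export
quantile_bin <- function(counts, q = 10L) {
  stopifnot(inherits(counts, "grid_counts"))
  q <- as.integer(q)
  if (q < 2L) stop("q must be >= 2")
  dims <- dim(counts$counts)
  binned <- array(0L, dim = dims, dimnames = dimnames(counts$counts))
  thr <- matrix(NA_real_, q, dims[3], dimnames = list(NULL, counts$features))
  occ <- counts$mask
  for (k in seq_len(dims[3])) {
    nk <- counts$counts[, , k]
    vals <- sort(nk[occ])
    Fcdf <- function(t) mean(vals <= t)
    support <- sort(unique(c(0L, vals)))
    tk <- vapply(seq_len(q), function(kk) {
      cand <- support[vapply(support, Fcdf, numeric(1)) >= kk / q]
      if (length(cand) == 0) max(support) + 1 else min(cand)
    }, numeric(1))
    thr[, k] <- tk
    binned[, , k] <- matrix(rowSums(outer(as.numeric(nk), tk, ">=")),
                            dims[1], dims[2])
  }
  list(binned = binned, thresholds = thr, q = q)
}

#' Megasquare split ensemble
#'
#' The sample space for the mutual-information score: all megasquares of
#' `2K x 2K` grid squares fully contained in the grid, each split either
#' horizontally or vertically into two equal halves of `2K^2` squares.
#'
#' @param nx,ny grid dimensions in squares.
#' @param K megasquare half-width (side = `2K` squares, default 4).
#' @return object of class `megasquare_ensemble` listing the top-left
#'   (lowest-index) corners of all placements.
#' @export
megasquare_ensemble <- function(nx, ny, K = 4L) {
  K <- as.integer(K)
  side <- 2L * K
  if (nx < side || ny < side) {
    stop("grid too small for a single megasquare")
  }
  corners <- expand.grid(ci = seq_len(nx - side + 1L),
                         cj = seq_len(ny - side + 1L))
  structure(list(K = K, side = side, corners = corners, nx = nx, ny = ny),
            class = "megasquare_ensemble")
}

#' Split label of a square within a megasquare
#'
#' For the horizontal split direction the square is `l`eft when its column
#' index `i <= K`, else `r`ight; for the vertical direction it is `b`ottom
#' when its row index `j <= K`, else `t`op.
#'
#' @param i,j column and row index within the megasquare, in `1..2K`.
#' @param d split direction, `"h"` (left/right) or `"v"` (bottom/top).
#' @param K megasquare half-width.
#' @return one of `"l"`, `"r"`, `"b"`, `"t"` (vectorized).
#' @export
split_label <- function(i, j, d, K) {
  if (any(i < 1 | i > 2 * K | j < 1 | j > 2 * K)) {
    stop("square index out of the megasquare range")
  }
  d <- match.arg(d, c("h", "v"))
  if (d == "h") ifelse(i <= K, "l", "r") else ifelse(j <= K, "b", "t")
}

#' Conditional mutual-information score of spatial variability
#'
#' For each feature, computes \eqn{I(X; M^g \mid C)} where \eqn{C} is a
#' uniformly chosen megasquare, \eqn{M^g} the quantile bin of the feature's
#' count in a uniformly chosen square of it, and \eqn{X} the half
#' (left/right or bottom/top) the square falls in under a uniformly chosen
#' split direction.  Natural logarithm; `0 log 0 := 0`.  A feature constant
#' within every megasquare scores exactly 0.
#'
#' @param binned a [quantile_bin()] result (or an nx x ny integer matrix
#'   for a single feature).
#' @param ensemble a [megasquare_ensemble()].
#' @return named numeric vector of scores (nats), one per feature; each is
#'   the mean per-megasquare conditional MI.
#' @export
mi_score <- function(binned, ensemble) {
  stopifnot(inherits(ensemble, "megasquare_ensemble"))
  if (is.matrix(binned)) {
    arr <- array(binned, dim = c(dim(binned), 1),
                 dimnames = list(NULL, NULL, "f1"))
  } else {
    arr <- binned$binned
  }
  K <- ensemble$K; side <- ensemble$side
  feats <- dimnames(arr)[[3]]
  scores <- numeric(dim(arr)[3]); names(scores) <- feats
  li <- seq_len(K); ri <- K + seq_len(K)
  for (f in seq_len(dim(arr)[3])) {
    M <- arr[, , f]
    tot <- 0
    for (r in seq_len(nrow(ensemble$corners))) {
      ci <- ensemble$corners$ci[r]; cj <- ensemble$corners$cj[r]
      sub <- M[ci:(ci + side - 1L), cj:(cj + side - 1L)]
      bins <- sort(unique(as.integer(sub)))
      pm <- tabulate(match(as.integer(sub), bins), length(bins)) / side^2
      halves <- list(l = sub[li, ], r = sub[ri, ],
                     b = sub[, li], t = sub[, ri])
      mi_c <- 0
      for (h in halves) {
        ph <- tabulate(match(as.integer(h), bins), length(bins)) / (2 * K^2)
        nz <- ph > 0
        ## P(x) = 1/4; sum_m P(m|x)/4 * log(P(m|x)/P(m))
        mi_c <- mi_c + sum(ph[nz] / 4 * log(ph[nz] / pm[nz]))
      }
      tot <- tot + mi_c
    }
    scores[f] <- tot / nrow(ensemble$corners)
  }
  pmax(scores, 0)
}

#' Greedy ranking of features by MI score
#'
#' @param scores named numeric vector from [mi_score()] (or an aggregate).
#' @param n number of features to keep (default all).
#' @return character vector of feature names in strictly descending score
#'   order; ties broken lexicographically by feature name.
#' @export
rank_features <- function(scores, n = length(scores)) {
  if (n > length(scores)) stop("n exceeds the number of features")
  ord <- order(-scores, names(scores))
  names(scores)[ord][seq_len(n)]
}

#' Aggregate per-section MI scores
#'
#' Tallies each feature's score across sections; a feature missing from a
#' section contributes 0 there.
#'
#' @param section_scores list of named numeric vectors, one per section.
#' @return named numeric vector of per-feature totals.
#' @export
aggregate_sections <- function(section_scores) {
  feats <- sort(unique(unlist(lapply(section_scores, names))))
  out <- stats::setNames(numeric(length(feats)), feats)
  for (s in section_scores) {
    out[names(s)] <- out[names(s)] + s
  }
  out
}
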