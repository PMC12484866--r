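#' Read a particle table as a particle measure
#'
#' The dialect is delimited text with header columns `x`, `y`, `z` (z
#' optional), `weight`, followed either by one numeric column per feature or
#' by a single `label` column of discrete labels (expanded to one-hot
#' rows).  Coordinates are converted to the package's internal unit,
#' millimeters.
#'
#' @param path file path.
#' @param unit input length unit, `"mm"` or `"um"`.
#' @param sep field separator (default comma).
#' @return a [particle_measure()].
#' @export
read_particles <- function(path, unit = c("mm", "um"), sep = ",") {
  unit <- match.arg(unit)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("x", "y", "weight")
  if (!all(need %in% names(df))) {
    stop("particle table must have columns x, y[, z], weight")
  }
  scale <- if (unit == "um") 1e-3 else 1
  z <- if ("z" %in% names(df)) df$z else 0
  pos <- cbind(df$x, df$y, z) * scale
  if (any(df$weight < 0)) stop("negative weights in particle table")
  featcols <- setdiff(names(df), c("x", "y", "z", "weight"))
  if (length(featcols) == 0L) stop("particle table carries no feature columns")
  if (identical(featcols, "label")) {
    particle_measure(pos, df$weight, as.character(df$label))
  } else {
    particle_measure(pos, df$weight, as.matrix(df[featcols]))
  }
}

#' Write a particle measure in the particle-table dialect
#'
#' @param mu a [particle_measure()].
#' @param path output file path.
#' @param unit output length unit.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_particles <- function(mu, path, unit = c("mm", "um"), sep = ",") {
  unit <- match.arg(unit)
  scale <- if (unit == "um") 1e3 else 1
  df <- data.frame(x = mu$positions[, 1] * scale,
                   y = mu$positions[, 2] * scale,
                   z = mu$positions[, 3] * scale,
                   weight = mu$weights, check.names = FALSE)
  feats <- as.data.frame(mu$features)
  names(feats) <- mu$labels
  utils::write.table(cbind(df, feats), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Convert a labeled volume to an atlas measure
#'
#' Accepts either a NIfTI file path (read via \pkg{RNifti}) or an in-memory
#' 3D integer array of region labels.  Each foreground voxel (label != 0,
#' the background convention) becomes one particle at the voxel center
#' (0-based, half-open voxel indexing: center of voxel `(i,j,k)` is at
#' `(i + 0.5) * spacing`), with weight equal to the voxel volume and a
#' one-hot region membership.  Voxels may be aggregated into blocks; block
#' particles sit at the block's center of labeled mass and per-label volume
#' is conserved by emitting one particle per label present in the block.
#'
#' @param x file path or 3D array of integer labels.
#' @param spacing voxel edge lengths in mm (scalar or length 3); for NIfTI
#'   input the header spacing is used when `spacing` is `NULL`.
#' @param block aggregation factor (integer >= 1, default 1: one particle
#'   per voxel).
#' @return an [atlas_measure()] over the observed region labels (feature
#'   laws uniform over a placeholder feature space equal to the region
#'   labels until set).
#' @export
read_label_volume <- function(x, spacing = NULL, block = 1L) {
  if (is.character(x)) {
    img <- RNifti::readNifti(x)
    if (is.null(spacing)) spacing <- RNifti::pixdim(img)[1:3]
    arr <- as.array(img)
  } else {
    arr <- x
    if (is.null(spacing)) stop("spacing must be given for array input")
  }
  if (length(dim(arr)) != 3L) stop("label volume must be a 3D array")
  if (max(abs(arr - round(arr))) > 1e-8) {
    stop("label volume must carry integer labels")
  }
  arr <- round(arr)
  spacing <- rep_len(as.numeric(spacing), 3L)
  block <- as.integer(block)
  idx <- which(arr != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("label volume has no foreground voxels")
  labs <- arr[idx]
  vox_vol <- prod(spacing)
  centers <- sweep(idx - 0.5, 2, spacing, "*")
  if (block > 1L) {
    bid <- paste((idx[, 1] - 1L) %/% block, (idx[, 2] - 1L) %/% block,
                 (idx[, 3] - 1L) %/% block, labs, sep = ",")
    groups <- split(seq_len(nrow(idx)), bid)
    centers <- t(vapply(groups, function(g) colMeans(centers[g, , drop = FALSE]),
                        numeric(3)))
    w <- vapply(groups, length, numeric(1)) * vox_vol
    labs <- vapply(groups, function(g) labs[g[1]], numeric(1))
  } else {
    w <- rep(vox_vol, nrow(idx))
  }
  ulab <- sort(unique(labs))
  Pi <- matrix(0, length(labs), length(ulab),
               dimnames = list(NULL, paste0("label", ulab)))
  Pi[cbind(seq_along(labs), match(labs, ulab))] <- 1
  atlas_measure(centers, w, Pi, feature_labels = paste0("label", ulab))
}

.config_schema <- list(
  varifold_sigma = "numeric", varifold_weight = "numeric",
  flow_sigma = "numeric", reg_weight = "numeric", data_weight = "numeric",
  kl_weight = "numeric", n_steps = "integer", max_iter = "integer",
  seed = "integer", unit = "character", censor = "character",
  resample_sigma = "numeric", mi_q = "integer", mi_K = "integer",
  truncate = "numeric")

#' Read and validate a run configuration
#'
#' YAML file with kernel scales, loss weights, iteration budgets,
#' integrator steps, seed, unit declaration and censor mode.  Unknown keys
#' are rejected.
#'
#' @param path YAML file path.
#' @return a validated named list of class `run_config` (defaults filled
#'   in).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(.config_schema))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(varifold_sigma = 0.2, varifold_weight = 1,
                   flow_sigma = 0.5, reg_weight = 1, data_weight = 1,
                   kl_weight = 1, n_steps = 10L, max_iter = 150L,
                   seed = 1L, unit = "mm", censor = "none",
                   resample_sigma = 0.2, mi_q = 10L, mi_K = 4L,
                   truncate = Inf)
  cfg <- utils::modifyList(defaults, raw)
  for (nm in names(cfg)) {
    type <- .config_schema[[nm]]
    if (type == "integer") cfg[[nm]] <- as.integer(cfg[[nm]])
    if (type == "numeric") cfg[[nm]] <- as.numeric(cfg[[nm]])
    if (!is.finite(cfg[[nm]]) && type != "character" && nm != "truncate") {
      stop("config key ", nm, " must be finite")
    }
  }
  if (!cfg$unit %in% c("mm", "um")) stop("unit must be mm or um")
  if (!cfg$censor %in% c("none", "planar", "learned")) {
    stop("censor must be none, planar or learned")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Machine-readable run report
#'
#' Writes (or returns) a JSON document echoing the configuration and seed
#' and recording the objective trajectory and summary invariants of a
#' mapping result.
#'
#' @param result a `mapping_result`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @param config optional configuration list echoed verbatim.
#' @return the JSON string (invisibly when written to `path`).
#' @export
run_report <- function(result, path = NULL, config = NULL) {
  stopifnot(inherits(result, "mapping_result"))
  doc <- list(
    config = config,
    objective = result$objective,
    objective_zero = result$objective_zero,
    evaluations = length(result$trajectory),
    objective_trajectory = result$trajectory,
    convergence = result$convergence,
    momentum_norm = sqrt(sum(result$rho_x^2) + sum(result$rho_w^2)),
    lambda = if (!is.null(result$lambda)) result$lambda else NULL,
    laws = if (!is.null(result$laws)) as.data.frame(result$laws) else NULL)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
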