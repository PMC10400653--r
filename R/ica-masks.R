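#' Mask-threshold grids
#'
#' The two threshold grids used for feature selection. Node masks keep, per
#' independent component, the voxels above a percentile of that component's
#' in-mask values ("percentage of voxels discarded"), swept from 99.9% down
#' to 94.5% in 0.1% steps. Watershed boundary masks record the
#' percent-of-component-maximum level at which two components first meet,
#' swept from a stop level of 94% down to 50% in 1% steps. The two scales
#' intentionally differ.
#'
#' @param node_grid Decreasing vector of discard percentiles.
#' @param watershed_grid Increasing vector of stop levels (percent of
#'   component maximum).
#' @param watershed_step Descent step in percent. Default 1.
#' @param isolation_connectivity Adjacency used for the single-voxel rule
#'   (a region voxel with no same-region neighbour under this adjacency is
#'   ignored when intersections are detected). Default 6.
#' @return An object of class `mask_config`.
#' @export
mask_config <- function(node_grid = seq(99.9, 94.5, by = -0.1),
                        watershed_grid = seq(50, 94, by = 1),
                        watershed_step = 1,
                        isolation_connectivity = 6L) {
  stopifnot(all(node_grid > 0 & node_grid < 100),
            all(watershed_grid > 0 & watershed_grid < 100),
            watershed_step > 0)
  structure(list(node_grid = node_grid, watershed_grid = watershed_grid,
                 watershed_step = watershed_step,
                 isolation_connectivity = as.integer(isolation_connectivity)),
            class = "mask_config")
}

#' Group spatial ICA of an independent session set
#'
#' Voxelwise-standardizes each session, concatenates them in time, and runs
#' spatial ICA (FastICA backend) for `K` components. Each spatial map is
#' sign-fixed so its largest-magnitude value is positive, then rescaled to
#' unit maximum.
#'
#' @param sessions List of `bold_session` objects on a common geometry.
#' @param K Number of components (`>=2`, at most the temporal rank).
#' @param seed Integer seed (the decomposition is deterministic given it).
#' @param backend A function `(X, K)` returning a voxels x K source matrix;
#'   default wraps [ica::icafast()].
#' @return An object of class `component_set`: `maps` (list of K unit-max
#'   [scalar_map()]s), `mask`, `K`, `seed`.
#' @export
fit_group_ica <- function(sessions, K, seed, backend = NULL) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  mask <- sessions[[1]]$mask
  Xs <- lapply(sessions, function(s) {
    stopifnot(identical(dim(s$data)[1:3], mask$geometry$shape))
    X <- session_matrix(s)
    X <- sweep(X, 2, colMeans(X))
    sds <- sqrt(colSums(X^2) / (nrow(X) - 1))
    sds[sds == 0] <- 1
    sweep(X, 2, sds, "/")
  })
  X <- do.call(rbind, Xs)                  # total time x voxels
  if (K > min(dim(X)))
    stop("K exceeds the temporal rank of the concatenated data", call. = FALSE)
  set.seed(seed)
  if (is.null(backend))
    backend <- function(X, K) ica::icafast(t(X), nc = K)$S
  S <- backend(X, K)                        # voxels x K spatial sources
  maps <- vector("list", K)
  for (k in seq_len(K)) {
    v <- S[, k]
    if (abs(min(v)) > abs(max(v))) v <- -v  # sign-fix: peak positive
    v <- v / max(v)
    maps[[k]] <- scalar_map(mask, v)
  }
  structure(list(maps = maps, mask = mask, K = K, seed = seed),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d spatial components, %d in-mask voxels\n",
              x$K, sum(x$mask$included)))
  invisible(x)
}

#' Match ICA components to ground-truth phantom networks
#'
#' For synthetic studies: pairs each phantom network with the component of
#' maximal absolute spatial correlation (greedy, best first).
#'
#' @param components A [fit_group_ica()] result.
#' @param phantom A [make_phantom()] result.
#' @return Integer vector: component index for each network, with the
#'   achieved correlations as attribute `correlation`.
#' @export
match_components <- function(components, phantom) {
  K <- components$K
  W <- vapply(phantom$networks, map_values, numeric(sum(phantom$mask$included)))
  M <- vapply(components$maps, map_values, numeric(sum(components$mask$included)))
  cm <- abs(stats::cor(W, M))               # networks x components
  pairs <- integer(ncol(W))
  corrs <- numeric(ncol(W))
  for (step in seq_len(ncol(W))) {
    best <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pairs[best[1]] <- best[2]
    corrs[best[1]] <- cm[best[1], best[2]]
    cm[best[1], ] <- NA
    cm[, best[2]] <- NA
  }
  structure(pairs, correlation = corrs)
}

#' Node mask from IC overlay
#'
#' Per component, keeps the in-mask voxels whose value exceeds the
#' `discard_fraction` percentile of that component's in-mask values, then
#' merges (unions) the components.
#'
#' @param components A [fit_group_ica()] result (or any `component_set`).
#' @param discard_fraction Percent of voxels discarded per component, in
#'   (0, 100).
#' @return A `feature_mask`: list with `kind = "node"`, `threshold`,
#'   `voxels` (linear indices in increasing order), `mask`.
#' @export
node_mask_from_ics <- function(components, discard_fraction) {
  if (discard_fraction <= 0 || discard_fraction >= 100)
    stop("discard_fraction must be in (0, 100)", call. = FALSE)
  mask <- components$mask
  idx <- which(mask$included)
  keep <- logical(length(idx))
  for (m in components$maps) {
    v <- map_values(m)
    thr <- stats::quantile(v, discard_fraction / 100, names = FALSE, type = 7)
    keep <- keep | v > thr
  }
  voxels <- idx[keep]
  if (!length(voxels))
    warning("empty node mask at discard fraction ", discard_fraction)
  structure(list(kind = "node", threshold = discard_fraction,
                 voxels = voxels, mask = mask),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask> %s @ %g: %d voxels\n", x$kind, x$threshold,
              length(x$voxels)))
  invisible(x)
}

#' Watershed-style boundary mask from IC intersections
#'
#' Starting at each component's maximum (level 100% of its unit-max scale)
#' and lowering the level in `watershed_step` percent steps, every
#' component's region grows. A voxel is recorded as a boundary, with the
#' current level as its onset, the first time it belongs to two or more
#' regions; boundary voxels are excluded from later region growth (dam
#' semantics). A region voxel with no same-region neighbour under the
#' isolation adjacency is ignored when intersections are detected. The mask
#' collects all boundary voxels with onset level at or above `stop_level`.
#'
#' @param components A `component_set`.
#' @param stop_level Lowest level descended to, percent of component
#'   maximum, in (0, 100).
#' @param config A [mask_config()] (step and isolation adjacency).
#' @return A `feature_mask` with `kind = "boundary"`; attribute `onset`
#'   gives each voxel's onset level.
#' @export
boundary_mask_watershed <- function(components, stop_level,
                                    config = mask_config()) {
  if (stop_level <= 0 || stop_level >= 100)
    stop("stop_level must be in (0, 100)", call. = FALSE)
  mask <- components$mask
  shape <- mask$geometry$shape
  idx <- which(mask$included)
  V <- vapply(components$maps, map_values, numeric(length(idx)))
  off <- neighbour_offsets(config$isolation_connectivity)
  pd <- shape + 2L
  loffs <- as.integer(off %*% c(1, pd[1], pd[1] * pd[2]))
  pidx <- lin_index(pd, arrayInd(idx, shape) + 1L)   # padded positions

  claimed <- logical(length(idx))          # boundary voxels (dams)
  onset <- rep(NA_real_, length(idx))
  levels <- seq(100, stop_level, by = -config$watershed_step)
  pmem <- logical(prod(pd))
  for (L in levels) {
    counts <- integer(length(idx))
    for (k in seq_len(ncol(V))) {
      memb <- V[, k] >= L / 100 & !claimed
      if (!any(memb)) next
      # single-voxel rule: need >= 1 same-region neighbour
      pmem[] <- FALSE
      pmem[pidx[memb]] <- TRUE
      has_nb <- rep(FALSE, length(idx))
      wm <- which(memb)
      for (o in loffs) has_nb[wm] <- has_nb[wm] | pmem[pidx[wm] + o]
      counts <- counts + as.integer(memb & has_nb)
    }
    new_bnd <- counts >= 2L & !claimed
    claimed <- claimed | new_bnd
    onset[new_bnd] <- L
  }
  voxels <- idx[claimed & onset >= stop_level]
  structure(list(kind = "boundary", threshold = stop_level,
                 voxels = voxels, mask = mask),
            class = "feature_mask",
            onset = onset[claimed & onset >= stop_level])
}

#' Select a stimulation target
#'
#' Thresholds and overlaps two components, then returns the node-density
#' local maximum closest (Euclidean, world mm) to the overlap centroid.
#' Ties go to the lowest linear index.
#'
#' @param component_a,component_b [scalar_map()]s (unit-max IC maps).
#' @param density A `node_density_map`.
#' @param overlap_level Fraction of each component's maximum above which a
#'   voxel belongs to it. Default 0.5.
#' @return Length-3 integer voxel index (one-based), with attribute
#'   `world` (mm coordinates).
#' @export
select_stimulation_target <- function(component_a, component_b, density,
                                      overlap_level = 0.5) {
  stopifnot(inherits(density, "scalar_map"))
  geom <- density$geometry
  a <- component_a$values >= overlap_level * max(map_values(component_a))
  b <- component_b$values >= overlap_level * max(map_values(component_b))
  a[is.na(a)] <- FALSE; b[is.na(b)] <- FALSE
  overlap <- which(a & b)
  if (!length(overlap)) stop("component overlap is empty", call. = FALSE)
  centroid <- colMeans(voxel_to_world(geom, arrayInd(overlap, geom$shape)))
  mx <- local_maxima(density)
  mx <- mx[density$values[mx] > 0, , drop = FALSE]
  if (!nrow(mx)) stop("density map has no positive maxima", call. = FALSE)
  w <- voxel_to_world(geom, mx)
  d2 <- colSums((t(w) - centroid)^2)
  lins <- lin_index(geom$shape, mx)
  best <- order(d2, lins)[1]
  structure(mx[best, ], world = w[best, ])
}
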