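#' Resample a map or 4D series to a coarser grid
#'
#' Block mode (the default when the target voxel size is an integer multiple
#' of the source) averages the source voxels under each target voxel; a
#' target voxel is in-mask iff more than half of its source voxels are
#' in-mask. Linear mode samples the source by trilinear interpolation at the
#' target voxel centres and is available for arbitrary target sizes.
#'
#' @param x A [scalar_map()], a [brain_mask()], or a 4D numeric array paired
#'   with `mask`.
#' @param target_voxel_mm Numeric (scalar or length 3) target voxel size in
#'   mm; must not exceed the whole-volume extent.
#' @param mode `"auto"` (block when the ratio is integer, else linear),
#'   `"block"` or `"linear"`.
#' @param mask Required when `x` is a bare 4D array: the source
#'   [brain_mask()].
#' @return Same kind of object as `x` on the coarser geometry (for a 4D
#'   array, a list with `data` and `mask`).
#' @export
resample_volume <- function(x, target_voxel_mm, mode = c("auto", "block", "linear"),
                            mask = NULL) {
  mode <- match.arg(mode)
  target_voxel_mm <- as.numeric(target_voxel_mm)
  if (length(target_voxel_mm) == 1L) target_voxel_mm <- rep(target_voxel_mm, 3L)
  if (any(!is.finite(target_voxel_mm)) || any(target_voxel_mm <= 0))
    stop("target voxel size must be positive", call. = FALSE)

  if (inherits(x, "scalar_map")) {
    src_mask <- x$mask
    res <- resample_volume(x$mask, target_voxel_mm, mode)
    vals <- resample_values(x$values, x$mask, target_voxel_mm, mode, res$geometry)
    vals[!res$included] <- NA_real_
    vals[res$included & !is.finite(vals)] <- 0
    return(scalar_map(res, vals))
  }
  if (inherits(x, "brain_mask")) {
    geom <- x$geometry
    tgeom <- coarse_geometry(geom, target_voxel_mm)
    frac <- resample_values(array(as.numeric(x$included), geom$shape), NULL,
                            target_voxel_mm, mode, tgeom, geometry = geom)
    return(brain_mask(tgeom, frac > 0.5))
  }
  if (is.array(x) && length(dim(x)) == 4L) {
    if (is.null(mask)) stop("`mask` required for a 4D array", call. = FALSE)
    tmask <- resample_volume(mask, target_voxel_mm, mode)
    nt <- dim(x)[4L]
    out <- array(0, dim = c(tmask$geometry$shape, nt))
    for (t in seq_len(nt)) {
      v <- resample_values(x[, , , t], mask, target_voxel_mm, mode, tmask$geometry)
      v[!tmask$included] <- 0
      v[!is.finite(v)] <- 0
      out[, , , t] <- v
    }
    return(list(data = out, mask = tmask))
  }
  stop("unsupported input to resample_volume()", call. = FALSE)
}

coarse_geometry <- function(geom, target_voxel_mm) {
  extent <- geom$shape * geom$voxel_mm
  if (any(target_voxel_mm > extent + 1e-9))
    stop("target voxel coarser than the whole volume", call. = FALSE)
  shape <- pmax(1L, as.integer(round(extent / target_voxel_mm)))
  volume_geometry(shape, target_voxel_mm, geom$origin)
}

# Resample a single 3D array of values. For scalar maps, out-of-mask source
# voxels carry no weight (mask-weighted block mean / normalized trilinear).
resample_values <- function(values, mask, target_voxel_mm, mode, tgeom,
                            geometry = NULL) {
  geom <- if (!is.null(mask)) mask$geometry else geometry
  if (!is.null(mask)) values[!mask$included] <- 0
  ratio <- target_voxel_mm / geom$voxel_mm
  is_block <- all(abs(ratio - round(ratio)) < 1e-8) &&
    all(geom$shape %% round(ratio) == 0)
  if (mode == "block" && !is_block)
    stop("block resampling needs an integer voxel ratio dividing the shape",
         call. = FALSE)
  use_block <- mode == "block" || (mode == "auto" && is_block)

  if (use_block) {
    f <- as.integer(round(ratio))
    if (is.null(mask)) {
      # bare-array call (mask fraction): plain block mean
      out <- block_sum(values, f) / prod(f)
    } else {
      w <- array(as.numeric(mask$included), geom$shape)
      num <- block_sum(values * w, f)
      den <- block_sum(w, f)
      out <- num / den
      out[den == 0] <- 0
    }
    out
  } else {
    centers <- voxel_to_world(tgeom, as.matrix(expand.grid(
      i = seq_len(tgeom$shape[1]), j = seq_len(tgeom$shape[2]),
      k = seq_len(tgeom$shape[3]))))
    w <- if (!is.null(mask)) array(as.numeric(mask$included), geom$shape) else NULL
    v <- values
    if (!is.null(w)) v[w == 0] <- 0
    num <- trilinear_sample(v, geom, centers)
    out <- if (is.null(w)) num else {
      den <- trilinear_sample(w, geom, centers)
      r <- num / den
      r[!is.finite(r)] <- 0
      r
    }
    array(out, dim = tgeom$shape)
  }
}

# Sum over f1 x f2 x f3 blocks of a 3D array.
block_sum <- function(a, f) {
  d <- dim(a)
  dim(a) <- c(f[1], d[1] %/% f[1], f[2], d[2] %/% f[2], f[3], d[3] %/% f[3])
  apply(a, c(2, 4, 6), sum)
}

# Trilinear interpolation of a 3D array at world points (zero outside).
trilinear_sample <- function(a, geom, world) {
  fi <- world_to_voxel(geom, world)          # fractional one-based indices
  d <- dim(a)
  i0 <- floor(fi)
  fr <- fi - i0
  acc <- numeric(nrow(world))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- i0 + matrix(rep(c(dx, dy, dz), each = nrow(world)), ncol = 3)
    wgt <- (if (dx == 1) fr[, 1] else 1 - fr[, 1]) *
      (if (dy == 1) fr[, 2] else 1 - fr[, 2]) *
      (if (dz == 1) fr[, 3] else 1 - fr[, 3])
    ok <- ii[, 1] >= 1 & ii[, 1] <= d[1] & ii[, 2] >= 1 & ii[, 2] <= d[2] &
      ii[, 3] >= 1 & ii[, 3] <= d[3]
    if (any(ok)) {
      lin <- lin_index(d, ii[ok, , drop = FALSE])
      acc[ok] <- acc[ok] + wgt[ok] * a[lin]
    }
  }
  acc
}

#' Mask-normalized Gaussian smoothing
#'
#' Smooths a map with a separable Gaussian kernel of the given full width at
#' half maximum, renormalizing by the smoothed mask so that values near the
#' brain edge are not dimmed by out-of-mask zeros. The internal standard
#' deviation is `fwhm / (2 * sqrt(2 * log(2)))` per axis, divided by the
#' voxel size.
#'
#' @param map A [scalar_map()].
#' @param fwhm_mm Full width at half maximum in mm (`>= 0`; 0 returns the
#'   input unchanged).
#' @return A smoothed [scalar_map()].
#' @export
gaussian_smooth <- function(map, fwhm_mm) {
  stopifnot(inherits(map, "scalar_map"))
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(map)
  w <- array(as.numeric(map$mask$included), map$geometry$shape)
  v <- map$values
  v[!map$mask$included] <- 0
  sig_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / map$geometry$voxel_mm
  num <- separable_gauss(v * w, sig_vox)
  den <- separable_gauss(w, sig_vox)
  out <- num / den
  out[den == 0 | !is.finite(out)] <- 0
  scalar_map(map$mask, out)
}

gauss_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4.5 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

separable_gauss <- function(a, sig_vox) {
  for (ax in 1:3) {
    k <- gauss_kernel_1d(sig_vox[ax])
    if (length(k) == 1L) next
    r <- (length(k) - 1L) / 2L
    out <- array(0, dim = dim(a))
    for (j in seq_along(k)) {
      off <- c(0L, 0L, 0L); off[ax] <- j - 1L - r
      out <- out + k[j] * shift_array(a, off, fill = 0)
    }
    a <- out
  }
  a
}

#' Local maxima of a scalar map
#'
#' A voxel is a local maximum when its value is `>=` all in-mask neighbours
#' under the chosen connectivity; plateau ties are broken in favour of the
#' lowest linear index, so a flat plateau yields exactly one maximum. Maxima
#' closer together than `min_separation_mm` are pruned, keeping the higher
#' (ties again by lowest linear index).
#'
#' @param map A [scalar_map()].
#' @param connectivity 6, 18 or 26 (default 26).
#' @param min_separation_mm Minimum world distance between reported maxima
#'   (default 0 = no pruning).
#' @return Integer matrix (n x 3) of one-based voxel indices, ordered by
#'   decreasing value.
#' @export
local_maxima <- function(map, connectivity = 26L, min_separation_mm = 0) {
  stopifnot(inherits(map, "scalar_map"))
  m <- map$mask$included
  if (!any(m)) stop("empty mask", call. = FALSE)
  v <- map$values
  shape <- map$geometry$shape
  # padded lattice so neighbour arithmetic with linear offsets never wraps;
  # padded linear order is lexicographic in (k, j, i) like the original, so
  # index comparisons (plateau tie-break) carry over
  pd <- shape + 2L
  pmask <- array(FALSE, pd)
  pmask[2:(pd[1] - 1), 2:(pd[2] - 1), 2:(pd[3] - 1)] <- m
  pvals <- array(0, pd)
  pv <- v; pv[!m] <- 0
  pvals[2:(pd[1] - 1), 2:(pd[2] - 1), 2:(pd[3] - 1)] <- pv
  loffs <- as.integer(neighbour_offsets(connectivity) %*%
                        c(1, pd[1], pd[1] * pd[2]))
  L <- which(pmask)
  is_max <- rep(TRUE, length(L))
  for (o in loffs) {
    nb <- L + o
    ok <- pmask[nb]
    beat <- ok & (pvals[nb] > pvals[L] | (pvals[nb] == pvals[L] & nb < L))
    is_max <- is_max & !beat
  }
  pin <- arrayInd(L[is_max], pd) - 1L
  lin <- lin_index(shape, pin)
  lin <- sort(lin)
  if (!length(lin)) return(matrix(integer(0), ncol = 3))
  ord <- order(-v[lin], lin)
  lin <- lin[ord]
  ai <- arrayInd(lin, shape)
  if (min_separation_mm > 0 && nrow(ai) > 1) {
    w <- voxel_to_world(map$geometry, ai)
    keep <- logical(nrow(ai))
    for (i in seq_len(nrow(ai))) {
      if (!any(keep)) { keep[i] <- TRUE; next }
      d2 <- colSums((t(w[keep, , drop = FALSE]) - w[i, ])^2)
      keep[i] <- all(d2 >= min_separation_mm^2)
    }
    ai <- ai[keep, , drop = FALSE]
  }
  ai
}

#' Connected components of a voxel set
#'
#' Labels the `TRUE` voxels of a boolean lattice into connected components
#' under 6-, 18- or 26-connectivity by iterative minimum-label propagation.
#'
#' @param voxels Logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return List with `labels` (integer array, 0 = background, components
#'   numbered 1..C in order of their smallest linear index) and `sizes`
#'   (integer vector of component voxel counts).
#' @export
connected_components <- function(voxels, connectivity = 26L) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  voxels <- voxels & !is.na(voxels)
  shape <- dim(voxels)
  pd <- shape + 2L                 # pad so linear-offset BFS never wraps
  pvox <- array(FALSE, pd)
  pvox[2:(pd[1] - 1), 2:(pd[2] - 1), 2:(pd[3] - 1)] <- voxels
  loffs <- as.integer(neighbour_offsets(connectivity) %*%
                        c(1, pd[1], pd[1] * pd[2]))
  plab <- flood_labels(pvox, loffs)
  lab <- max(plab)
  relab <- array(plab, pd)[2:(pd[1] - 1), 2:(pd[2] - 1), 2:(pd[3] - 1)]
  relab <- array(as.integer(relab), shape)
  sizes <- if (lab > 0L) as.integer(tabulate(relab[relab > 0L], lab))
           else integer(0)
  list(labels = relab, sizes = sizes)
}

# BFS component labelling on a padded logical array via linear offsets.
# Labels are assigned in increasing order of each component's smallest
# (padded, hence also original) linear index.
flood_labels <- function(pvox, loffs) {
  plab <- integer(length(pvox))
  lab <- 0L
  for (s in which(pvox)) {
    if (plab[s] > 0L) next
    lab <- lab + 1L
    plab[s] <- lab
    frontier <- s
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, loffs, `+`)))
      nb <- nb[pvox[nb] & plab[nb] == 0L]
      plab[nb] <- lab
      frontier <- nb
    }
  }
  plab
}

#' Spatial gradient magnitude of a scalar map
#'
#' Per-voxel Euclidean norm of the three axis derivatives, in map-value
#' units per mm. Central differences are used where both axis neighbours
#' are in-mask, one-sided differences where only one is, and the axis
#' contributes zero where neither is. Voxels with no in-mask neighbour on
#' any axis get value 0 and are flagged in the `isolated` attribute.
#'
#' @param map A [scalar_map()].
#' @return A nonnegative [scalar_map()] with attribute `isolated` (linear
#'   indices of flagged voxels).
#' @export
gradient_magnitude <- function(map) {
  stopifnot(inherits(map, "scalar_map"))
  m <- map$mask$included
  v <- map$values
  v[!m] <- 0
  shape <- map$geometry$shape
  total <- array(0, dim = shape)
  any_axis <- array(FALSE, dim = shape)
  for (ax in 1:3) {
    e <- c(0L, 0L, 0L); e[ax] <- 1L
    h <- map$geometry$voxel_mm[ax]
    vp <- shift_array(v, -e, fill = 0); mp <- shift_array(m, -e, fill = FALSE)
    vm <- shift_array(v,  e, fill = 0); mm_ <- shift_array(m, e, fill = FALSE)
    mp[is.na(mp)] <- FALSE; mm_[is.na(mm_)] <- FALSE
    g <- array(0, dim = shape)
    both <- mp & mm_
    g[both] <- (vp[both] - vm[both]) / (2 * h)
    ponly <- mp & !mm_
    g[ponly] <- (vp[ponly] - v[ponly]) / h
    monly <- mm_ & !mp
    g[monly] <- (v[monly] - vm[monly]) / h
    any_axis <- any_axis | mp | mm_
    total <- total + g^2
  }
  total <- sqrt(total)
  total[!m] <- 0
  isolated <- which(m & !any_axis)
  out <- scalar_map(map$mask, total)
  attr(out, "isolated") <- isolated
  out
}
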