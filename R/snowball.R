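#' Snowballing configuration
#'
#' Parameters of the iterative seed-based node-density parcellation: seed
#' sphere radius, the correlation threshold applied to every seed's
#' whole-brain correlation map, the number of snowballing zones
#' (iterations), the minimum suprathreshold cluster size, and the clustering
#' connectivity.
#'
#' @param seed_radius_mm Seed sphere radius in mm. Default 5.
#' @param corr_threshold Correlation threshold in (0, 1). Default 0.3.
#' @param n_zones Number of zones (`>= 1`). Default 3.
#' @param min_cluster_voxels Minimum voxels per suprathreshold cluster.
#'   Default 5.
#' @param connectivity Clustering connectivity (6, 18, 26). Default 26.
#' @param seed_spacing_vox When no explicit seed set is given, starting
#'   seeds are placed on a regular in-mask grid with this voxel spacing.
#'   Default 4.
#' @param peak_separation_mm Minimum world distance between the local
#'   maxima reported within one cluster (suppresses duplicate peaks from
#'   residual noise ripples). Default 8.
#' @param corr_smooth_fwhm_mm FWHM of the Gaussian applied to every seed's
#'   correlation map before thresholding and peak extraction, so each
#'   cluster carries distinct, stable local maxima instead of noise
#'   ripples. Default 6; 0 disables.
#' @return An object of class `snowball_config`.
#' @export
snowball_config <- function(seed_radius_mm = 5, corr_threshold = 0.3,
                            n_zones = 3L, min_cluster_voxels = 5L,
                            connectivity = 26L, seed_spacing_vox = 4L,
                            peak_separation_mm = 8,
                            corr_smooth_fwhm_mm = 6) {
  if (corr_threshold <= 0 || corr_threshold >= 1)
    stop("corr_threshold must be in (0, 1)", call. = FALSE)
  if (n_zones < 1L) stop("n_zones must be >= 1", call. = FALSE)
  structure(list(seed_radius_mm = seed_radius_mm,
                 corr_threshold = corr_threshold, n_zones = as.integer(n_zones),
                 min_cluster_voxels = as.integer(min_cluster_voxels),
                 connectivity = as.integer(connectivity),
                 seed_spacing_vox = as.integer(seed_spacing_vox),
                 peak_separation_mm = peak_separation_mm,
                 corr_smooth_fwhm_mm = corr_smooth_fwhm_mm),
            class = "snowball_config")
}

#' Default seed set: a regular in-mask grid of world coordinates
#'
#' @param mask A [brain_mask()].
#' @param spacing_vox Grid spacing in voxels.
#' @return Numeric n x 3 matrix of world coordinates (mm).
#' @export
default_seed_grid <- function(mask, spacing_vox = 4L) {
  shape <- mask$geometry$shape
  pts <- as.matrix(expand.grid(
    i = seq(ceiling(spacing_vox / 2), shape[1], by = spacing_vox),
    j = seq(ceiling(spacing_vox / 2), shape[2], by = spacing_vox),
    k = seq(ceiling(spacing_vox / 2), shape[3], by = spacing_vox)))
  keep <- mask$included[pts]
  voxel_to_world(mask$geometry, pts[keep, , drop = FALSE])
}

#' Seed-based correlation map
#'
#' Averages the time series of all in-mask voxels whose centres lie within
#' `radius_mm` of the seed centre, and correlates that mean series with
#' every in-mask voxel's series.
#'
#' @param session A preprocessed `bold_session`.
#' @param seed_center Length-3 world coordinate (mm).
#' @param radius_mm Seed sphere radius.
#' @return A [scalar_map()] of Pearson correlations in `[-1, 1]`.
#' @export
seed_correlation_map <- function(session, seed_center, radius_mm = 5) {
  ctx <- snowball_ctx(session)
  r <- ctx_corr(ctx, seed_center, radius_mm, strict = TRUE)
  scalar_map(session$mask, r)
}

# Precomputed per-session quantities shared by all seeds of all zones.
snowball_ctx <- function(session, smooth_fwhm_mm = 0) {
  X <- session_matrix(session)                # time x voxels
  idx <- which(session$mask$included)
  world <- voxel_to_world(session$geometry, arrayInd(idx, session$geometry$shape))
  Xc <- sweep(X, 2, colMeans(X))
  nrm <- sqrt(colSums(Xc^2))
  ctx <- list(Xc = Xc, nrm = nrm, idx = idx, world = world,
              geometry = session$geometry, mask = session$mask)
  if (smooth_fwhm_mm > 0) {
    shape <- session$geometry$shape
    sig_vox <- smooth_fwhm_mm / (2 * sqrt(2 * log(2))) / session$geometry$voxel_mm
    kerns <- lapply(1:3, function(ax) gauss_kernel_1d(sig_vox[ax]))
    rad <- vapply(kerns, function(k) (length(k) - 1L) %/% 2L, integer(1))
    pshape <- shape + 2L * rad              # zero padding: no FFT wrap-around
    k3 <- outer(outer(centered_kernel(kerns[[1]], pshape[1]),
                      centered_kernel(kerns[[2]], pshape[2])),
                centered_kernel(kerns[[3]], pshape[3]))
    dim(k3) <- pshape
    ctx$kernel_fft <- stats::fft(k3)
    ctx$pshape <- pshape
    w <- array(0, pshape)
    w[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3])] <-
      as.numeric(session$mask$included)
    den <- Re(stats::fft(stats::fft(w) * ctx$kernel_fft, inverse = TRUE)) /
      prod(pshape)
    den[den < 1e-10] <- Inf                 # no mask support: smoothed value 0
    ctx$smooth_den <- den
  }
  ctx
}

# 1D kernel laid out for circular convolution on n (padded) samples.
centered_kernel <- function(k, n) {
  r <- (length(k) - 1L) %/% 2L
  out <- numeric(n)
  for (j in seq_along(k)) out[(j - 1L - r) %% n + 1L] <-
      out[(j - 1L - r) %% n + 1L] + k[j]
  out
}

# Mask-normalized FFT smoothing of an in-mask map (zeros elsewhere).
ctx_smooth <- function(ctx, rfull0) {
  shape <- ctx$geometry$shape
  p <- array(0, ctx$pshape)
  p[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3])] <-
    array(rfull0, shape)
  num <- Re(stats::fft(stats::fft(p) * ctx$kernel_fft, inverse = TRUE)) /
    prod(ctx$pshape)
  out <- num / ctx$smooth_den
  out[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3])]
}

# Correlation of the sphere-mean series with every in-mask voxel.
ctx_corr <- function(ctx, seed_center, radius_mm, strict = FALSE) {
  d2 <- colSums((t(ctx$world) - as.numeric(seed_center))^2)
  inside <- d2 <= radius_mm^2
  if (!any(inside)) {
    if (strict) stop("seed sphere contains no in-mask voxel", call. = FALSE)
    return(NULL)
  }
  s <- rowMeans(ctx$Xc[, inside, drop = FALSE])
  s <- s - mean(s)
  sn <- sqrt(sum(s^2))
  if (sn == 0) {
    if (strict) stop("zero-variance seed series", call. = FALSE)
    return(NULL)
  }
  r <- as.numeric(crossprod(s, ctx$Xc)) / (sn * ctx$nrm)
  r[!is.finite(r)] <- 0                       # zero-variance voxels
  pmin(1, pmax(-1, r))
}

#' One snowballing zone: seeds to new peaks
#'
#' For every seed, thresholds its correlation map, clusters the
#' suprathreshold voxels, drops clusters below the minimum size, and takes
#' each surviving cluster's local maxima of the correlation map. The zone
#' output is the union of peak voxels over all seeds, deduplicated by voxel
#' identity.
#'
#' @param session A preprocessed `bold_session`.
#' @param seed_points n x 3 matrix of world coordinates.
#' @param config A [snowball_config()].
#' @param ctx Internal precomputed context (leave `NULL`).
#' @return Integer vector of unique peak linear indices (possibly empty).
#' @export
snowball_zone <- function(session, seed_points, config = snowball_config(),
                          ctx = NULL) {
  seed_points <- as.matrix(seed_points)
  if (!nrow(seed_points)) stop("empty seed list", call. = FALSE)
  if (is.null(ctx)) ctx <- snowball_ctx(session, config$corr_smooth_fwhm_mm)
  shape <- ctx$geometry$shape
  peaks <- integer(0)
  for (s in seq_len(nrow(seed_points))) {
    r <- ctx_corr(ctx, seed_points[s, ], config$seed_radius_mm)
    if (is.null(r)) next            # empty sphere / flat seed: contributes nothing
    rfull <- numeric(prod(shape))
    rfull[ctx$idx] <- r
    if (!is.null(ctx$kernel_fft)) {
      rfull <- as.numeric(ctx_smooth(ctx, rfull))
      r <- rfull[ctx$idx]
    }
    supra_lin <- ctx$idx[r > config$corr_threshold]
    if (length(supra_lin) < config$min_cluster_voxels) next
    peaks <- c(peaks,
               cluster_peaks(supra_lin, rfull, ctx$geometry, config))
  }
  sort(unique(peaks))
}

# Threshold survivors -> connected clusters -> per-cluster local maxima
# with minimum-separation pruning (compiled kernel).
cluster_peaks <- function(supra_lin, values_full, geometry, config) {
  .cluster_peaks_cpp(as.integer(supra_lin), as.numeric(values_full),
                     as.integer(geometry$shape),
                     neighbour_offsets(config$connectivity),
                     as.integer(config$min_cluster_voxels),
                     as.numeric(config$peak_separation_mm),
                     as.numeric(geometry$voxel_mm))
}

#' Snowballing node-density map
#'
#' Runs `n_zones` snowballing iterations: zone 1 from the starting seed
#' set, each later zone from the previous zone's peaks (peak voxel centres
#' become the new seed centres). Every zone's deduplicated peaks increment
#' their voxel's count, so the map records the number of zones in which a
#' voxel was identified as a node.
#'
#' @param session A preprocessed `bold_session`.
#' @param config A [snowball_config()].
#' @param seed_points Optional explicit starting seeds (world coordinates);
#'   default is [default_seed_grid()] at `config$seed_spacing_vox`.
#' @return A `node_density_map`: a [scalar_map()] of nonnegative integer
#'   counts with attributes `config` and `session_id`.
#' @export
node_density_map <- function(session, config = snowball_config(),
                             seed_points = NULL) {
  if (is.null(seed_points))
    seed_points <- default_seed_grid(session$mask, config$seed_spacing_vox)
  seed_points <- as.matrix(seed_points)
  if (!nrow(seed_points)) stop("empty seed set", call. = FALSE)
  shape <- session$geometry$shape
  counts <- array(0, dim = shape)
  ctx <- snowball_ctx(session, config$corr_smooth_fwhm_mm)
  seeds <- seed_points
  for (z in seq_len(config$n_zones)) {
    peaks <- snowball_zone(session, seeds, config, ctx = ctx)
    if (!length(peaks)) break
    counts[peaks] <- counts[peaks] + 1
    seeds <- voxel_to_world(session$geometry, arrayInd(peaks, shape))
  }
  out <- scalar_map(session$mask, counts)
  class(out) <- c("node_density_map", class(out))
  attr(out, "config") <- config
  attr(out, "session_id") <- paste(session$subject, session$visit,
                                   session$interval, sep = "_")
  out
}

#' Write a node-density map as int32 NIfTI
#'
#' @param map A `node_density_map`.
#' @param path Output path.
#' @export
write_density_map <- function(map, path) {
  write_volume(map, path, datatype = "int")
}

#' Read a seed set from CSV (columns x, y, z in mm)
#'
#' @param path CSV path.
#' @return n x 3 matrix of world coordinates.
#' @export
read_seed_csv <- function(path) {
  d <- utils::read.csv(path)
  as.matrix(d[, c("x", "y", "z")])
}
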