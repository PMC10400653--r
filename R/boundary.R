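#' Boundary-mapping configuration
#'
#' @param coarse_voxel_mm Voxel size of the coarse analysis grid the session
#'   is resampled to before the similarity matrix is computed (must not be
#'   finer than the source grid). Default 4.5.
#' @param chunk_size Number of similarity-matrix rows processed per block;
#'   bounds peak memory at O(N * chunk) instead of O(N^2). Default 512.
#' @return An object of class `boundary_config`.
#' @export
boundary_config <- function(coarse_voxel_mm = 4.5, chunk_size = 512L) {
  if (coarse_voxel_mm <= 0) stop("coarse voxel size must be > 0", call. = FALSE)
  structure(list(coarse_voxel_mm = coarse_voxel_mm,
                 chunk_size = as.integer(chunk_size)),
            class = "boundary_config")
}

# Temporal-correlation matrix of a (coarse) session plus summary statistics
# needed to exclude the self-correlation entries from spatial correlations.
similarity_prep <- function(X) {
  nv <- ncol(X)
  if (nv < 3L) stop("need at least 3 in-mask voxels", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance voxels: ", paste(utils::head(which(sds == 0), 10),
                                         collapse = ", "), call. = FALSE)
  C <- stats::cor(X)
  list(C = C, su = rowSums(C), squ = rowSums(C^2), nv = nv)
}

# Similarity rows for reference voxels `rows`: Pearson correlation between
# row i's and row j's temporal-correlation maps with entries i and j removed
# from both vectors (closed-form correction of the full-vector sums).
similarity_rows <- function(prep, rows) {
  C <- prep$C
  n2 <- prep$nv - 2
  Ci <- C[rows, , drop = FALSE]
  CC <- Ci %*% C
  cij <- Ci
  Sx <- prep$su[rows] - 1 - cij              # row sums minus entries i, j
  Sy <- matrix(prep$su, nrow = length(rows), ncol = prep$nv, byrow = TRUE) -
    1 - cij
  Sxx <- prep$squ[rows] - 1 - cij^2
  Syy <- matrix(prep$squ, nrow = length(rows), ncol = prep$nv, byrow = TRUE) -
    1 - cij^2
  Sxy <- CC - 2 * cij
  num <- n2 * Sxy - Sx * Sy
  vx <- pmax(n2 * Sxx - Sx^2, 0)
  vy <- pmax(n2 * Syy - Sy^2, 0)
  S <- num / sqrt(vx * vy)
  # degenerate pairs: Pearson is undefined for constant vectors; two maps
  # that are constant AND equal (uniform connectivity) count as identical
  eps <- n2 * 1e-12
  degen <- vx < eps & vy < eps
  S[degen & abs(Sx - Sy) < eps] <- 1
  S[degen & abs(Sx - Sy) >= eps] <- 0
  S[!is.finite(S)] <- 0
  S <- pmin(pmax(S, -1), 1)   # argument order keeps the dim attribute
  S[cbind(seq_along(rows), rows)] <- 1
  S
}

#' Voxelwise spatial-similarity matrix
#'
#' For a session on the coarse grid: correlates every voxel's time series
#' with every other voxel's (the temporal-correlation maps), then computes
#' the spatial Pearson correlation between every pair of those maps. The
#' two self-correlation entries (positions i and j) are removed from both
#' vectors before the spatial correlation, since the trivial 1.0 at self
#' would inflate similarity.
#'
#' @param session A `bold_session` (already on the coarse grid; see
#'   [coarse_session()]).
#' @return An object of class `similarity_matrix`: `S` (N x N symmetric,
#'   unit diagonal), `idx` (linear voxel indices of the rows/columns),
#'   `mask` (the coarse [brain_mask()]).
#' @export
similarity_matrix <- function(session) {
  X <- session_matrix(session)
  prep <- similarity_prep(X)
  S <- similarity_rows(prep, seq_len(prep$nv))
  S <- (S + t(S)) / 2                       # symmetrize roundoff
  structure(list(S = S, idx = which(session$mask$included),
                 mask = session$mask),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d coarse voxels\n",
              nrow(x$S), ncol(x$S)))
  invisible(x)
}

#' Resample a session to the coarse analysis grid
#'
#' @param session A `bold_session`.
#' @param config A [boundary_config()].
#' @return The session on the coarse grid.
#' @export
coarse_session <- function(session, config = boundary_config()) {
  res <- resample_volume(session$data, config$coarse_voxel_mm,
                         mask = session$mask)
  session$data <- res$data
  session$mask <- res$mask
  session$geometry <- res$mask$geometry
  session
}

#' Average boundary-gradient map
#'
#' Scatters every similarity-matrix row into the coarse brain mask, takes
#' the spatial gradient magnitude of that similarity map, and averages the
#' gradient maps over all reference voxels. High values mark locations
#' where whole-brain connectivity patterns change abruptly — putative
#' boundaries between functional regions.
#'
#' Accepts either a precomputed [similarity_matrix()] or a coarse session,
#' in which case rows are generated and consumed in blocks of
#' `config$chunk_size` so the full N x N matrix is never materialized.
#'
#' @param x A `similarity_matrix` or a coarse `bold_session`.
#' @param config A [boundary_config()] (chunked path only).
#' @return A `boundary_gradient_map`: nonnegative [scalar_map()] on the
#'   coarse grid.
#' @export
boundary_gradient_map <- function(x, config = boundary_config()) {
  if (inherits(x, "similarity_matrix")) {
    mask <- x$mask
    idx <- x$idx
    nv <- length(idx)
    get_rows <- function(rows) x$S[rows, , drop = FALSE]
  } else {
    mask <- x$mask
    idx <- which(mask$included)
    nv <- length(idx)
    X <- session_matrix(x)
    prep <- similarity_prep(X)
    get_rows <- function(rows) similarity_rows(prep, rows)
  }
  shape <- mask$geometry$shape
  acc <- array(0, dim = shape)
  starts <- seq(1L, nv, by = max(1L, config$chunk_size))
  for (s0 in starts) {
    rows <- s0:min(s0 + config$chunk_size - 1L, nv)
    S <- get_rows(rows)
    acc <- acc + gradient_sum(S, mask, idx)
  }
  out <- scalar_map(mask, acc / nv)
  class(out) <- c("boundary_gradient_map", class(out))
  out
}

# Sum over a block of similarity rows of the per-row gradient magnitude,
# vectorized by treating rows as frames of a 4D array. Must agree with
# gradient_magnitude() applied row by row.
gradient_sum <- function(S, mask, idx) {
  shape <- mask$geometry$shape
  nr <- nrow(S)
  flat <- matrix(0, prod(shape), nr)
  flat[idx, ] <- t(S)
  a <- array(flat, c(shape, nr))
  m <- mask$included
  total <- array(0, c(shape, nr))
  for (ax in 1:3) {
    e <- c(0L, 0L, 0L); e[ax] <- 1L
    h <- mask$geometry$voxel_mm[ax]
    vp <- shift_frames(a, -e); vm <- shift_frames(a, e)
    mp <- shift_array(m, -e, fill = FALSE); mm_ <- shift_array(m, e, fill = FALSE)
    mp[is.na(mp)] <- FALSE; mm_[is.na(mm_)] <- FALSE
    coef_p <- ifelse(mp & mm_, 0.5, ifelse(mp, 1, 0)) / h
    coef_m <- ifelse(mp & mm_, 0.5, ifelse(mm_, 1, 0)) / h
    coef_c <- ifelse(mp & !mm_, 1, ifelse(mm_ & !mp, -1, 0)) / h
    g <- vp * array(coef_p, dim(a)) - vm * array(coef_m, dim(a)) -
      a * array(coef_c, dim(a))
    total <- total + g^2
  }
  total <- sqrt(total)
  total[array(!m, dim(total))] <- 0
  rowSums(total, dims = 3)
}
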