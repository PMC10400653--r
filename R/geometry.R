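#' Volume geometry
#'
#' Describes the 3D voxel lattice that every map in an analysis shares: the
#' number of voxels per axis, the voxel edge lengths in mm, and the world
#' (mm) offset of the lattice origin. World coordinates follow the
#' voxel-centre convention: the centre of the voxel with zero-based index
#' `i` lies at `origin + (i + 0.5) * voxel_mm` (in R's one-based indexing,
#' `origin + (i - 0.5) * voxel_mm`).
#'
#' @param shape Integer vector of length 3, voxels per axis (all `>= 1`).
#' @param voxel_mm Numeric vector of length 3, voxel size in mm (all `> 0`).
#'   A scalar is recycled.
#' @param origin Numeric vector of length 3, world offset in mm of the
#'   lattice corner. Defaults to `c(0, 0, 0)`.
#' @return An object of class `volume_geometry`.
#' @export
#' @examples
#' geom <- volume_geometry(c(16, 16, 16), 3)
#' dim_mm <- geom$shape * geom$voxel_mm
volume_geometry <- function(shape, voxel_mm, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 integers >= 1", call. = FALSE)
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (length(voxel_mm) != 3L || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("`voxel_mm` must be 3 positive numbers", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers", call. = FALSE)
  structure(list(shape = shape, voxel_mm = voxel_mm, origin = origin),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf("<volume_geometry> %s voxels at %s mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_mm), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-8) {
  identical(a$shape, b$shape) &&
    all(abs(a$voxel_mm - b$voxel_mm) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Brain mask
#'
#' The set of in-brain voxels on a [volume_geometry()] lattice. All maps in
#' an analysis are defined only inside this set.
#'
#' @param geometry A [volume_geometry()].
#' @param included Logical 3D array with `dim == geometry$shape`, or a
#'   vector recycled to that shape. Must include at least one voxel.
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(geometry, included) {
  stopifnot(inherits(geometry, "volume_geometry"))
  included <- array(as.logical(included), dim = geometry$shape)
  if (any(is.na(included))) stop("mask contains NA", call. = FALSE)
  if (!any(included)) stop("mask must include at least one voxel", call. = FALSE)
  structure(list(geometry = geometry, included = included), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %d / %d voxels included\n",
              sum(x$included), prod(x$geometry$shape)))
  invisible(x)
}

#' Scalar map
#'
#' A real-valued map on the in-mask voxels of a lattice (node density,
#' boundary gradient, IC map, similarity row, ...). Values outside the mask
#' are stored as `NA`.
#'
#' @param mask A [brain_mask()].
#' @param values Either a full 3D array (out-of-mask entries ignored) or a
#'   vector with one value per in-mask voxel, in linear-index order.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(mask, values) {
  stopifnot(inherits(mask, "brain_mask"))
  shape <- mask$geometry$shape
  if (is.array(values) || length(values) == prod(shape)) {
    vals <- array(as.numeric(values), dim = shape)
  } else if (length(values) == sum(mask$included)) {
    vals <- array(NA_real_, dim = shape)
    vals[mask$included] <- as.numeric(values)
  } else {
    stop("`values` length matches neither lattice nor mask", call. = FALSE)
  }
  if (any(!is.finite(vals[mask$included])))
    stop("scalar_map values must be finite inside the mask", call. = FALSE)
  vals[!mask$included] <- NA_real_
  structure(list(geometry = mask$geometry, mask = mask, values = vals),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[x$mask$included]
  cat(sprintf("<scalar_map> %s lattice, %d in-mask voxels, range [%g, %g]\n",
              paste(x$geometry$shape, collapse = "x"), length(v),
              min(v), max(v)))
  invisible(x)
}

#' In-mask values of a scalar map
#'
#' @param map A [scalar_map()].
#' @return Numeric vector of the in-mask values in linear-index order.
#' @export
map_values <- function(map) {
  stopifnot(inherits(map, "scalar_map"))
  map$values[map$mask$included]
}

#' Convert voxel indices to world coordinates
#'
#' Voxel-centre convention: one-based voxel `(i, j, k)` maps to
#' `origin + (c(i, j, k) - 0.5) * voxel_mm`.
#'
#' @param geometry A [volume_geometry()].
#' @param idx Integer matrix (n x 3) of one-based voxel indices, or a vector
#'   of linear indices.
#' @return Numeric n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(geometry, idx) {
  if (!is.matrix(idx)) idx <- arrayInd(as.integer(idx), geometry$shape)
  sweep(sweep(idx - 0.5, 2, geometry$voxel_mm, "*"), 2, geometry$origin, "+")
}

#' Convert world coordinates to (fractional) voxel indices
#'
#' Inverse of [voxel_to_world()]; returns fractional one-based indices (the
#' voxel containing a point is `round()` of the result only at its centre;
#' use `ceiling((w - origin)/voxel)` semantics via `world_to_voxel` + round).
#'
#' @param geometry A [volume_geometry()].
#' @param world Numeric n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return Numeric n x 3 matrix of fractional one-based voxel indices.
#' @export
world_to_voxel <- function(geometry, world) {
  if (!is.matrix(world)) world <- matrix(world, ncol = 3L)
  sweep(sweep(world, 2, geometry$origin, "-"), 2, geometry$voxel_mm, "/") + 0.5
}

# linear index <-> array index helpers (column-major, R native)
lin_index <- function(shape, idx) {
  as.integer((idx[, 3L] - 1L) * shape[1L] * shape[2L] +
               (idx[, 2L] - 1L) * shape[1L] + idx[, 1L])
}

# 26/18/6-connectivity neighbour offsets as an m x 3 integer matrix (cached)
.offset_cache <- new.env(parent = emptyenv())
neighbour_offsets <- function(connectivity = 26L) {
  key <- as.character(connectivity)
  if (!key %in% c("6", "18", "26"))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  if (is.null(.offset_cache[[key]])) {
    off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    ord <- rowSums(abs(off))
    keep <- switch(key, "6" = ord == 1, "18" = ord >= 1 & ord <= 2,
                   "26" = ord >= 1)
    .offset_cache[[key]] <- off[keep, , drop = FALSE]
  }
  .offset_cache[[key]]
}

# Shift a 3D array by an integer offset, filling with `fill`.
shift_array <- function(a, off, fill = NA) {
  d <- dim(a)
  src <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax]) - off[ax]
    ifelse(i >= 1L & i <= d[ax], i, NA_integer_)
  })
  out <- array(fill, dim = d)
  ok1 <- !is.na(src[[1]]); ok2 <- !is.na(src[[2]]); ok3 <- !is.na(src[[3]])
  out[ok1, ok2, ok3] <- a[src[[1]][ok1], src[[2]][ok2], src[[3]][ok3]]
  out
}
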