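#' NIfTI and motion-table input/output
#'
#' Volumes are written as NIfTI-1 with an RAS+ affine built from the
#' [volume_geometry()] (diagonal voxel sizes, translation so that voxel
#' centres land at `origin + (index + 0.5) * voxel_mm` with zero-based
#' indices). Masks are written as uint8, node-density maps as int32, other
#' maps as float32. Motion parameters use the common realignment-parameter
#' dialect: 6 whitespace-separated columns (3 translations in mm, 3
#' rotations in rad), one row per volume.
#'
#' @param map A [scalar_map()], [brain_mask()], or 4D array (with
#'   `geometry`).
#' @param path Output file path (`.nii` / `.nii.gz`).
#' @param datatype NIfTI datatype string for [RNifti::writeNifti()].
#' @param geometry Required for bare arrays.
#' @return `path`, invisibly (writers); the reconstructed object (readers).
#' @name nifti_io
NULL

geometry_affine <- function(geom) {
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(geom$voxel_mm)
  # voxel (0,0,0) centre at origin + 0.5 * voxel
  aff[1:3, 4] <- geom$origin + 0.5 * geom$voxel_mm
  aff
}

#' @rdname nifti_io
#' @export
write_volume <- function(map, path, datatype = "auto", geometry = NULL) {
  if (inherits(map, "scalar_map")) {
    arr <- map$values
    arr[!map$mask$included] <- 0
    geom <- map$geometry
    if (identical(datatype, "auto")) datatype <- "float"
  } else if (inherits(map, "brain_mask")) {
    arr <- array(as.integer(map$included), map$geometry$shape)
    geom <- map$geometry
    if (identical(datatype, "auto")) datatype <- "uint8"
  } else {
    stopifnot(is.array(map), !is.null(geometry))
    arr <- map
    geom <- geometry
    if (identical(datatype, "auto")) datatype <- "float"
  }
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(geometry_affine(geom), code = 2L))
  RNifti::pixdim(img) <- geom$voxel_mm
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  aff <- RNifti::xform(img)
  voxel_mm <- sqrt(colSums(aff[1:3, 1:3]^2))
  origin <- aff[1:3, 4] - 0.5 * voxel_mm
  geom <- volume_geometry(dim(arr)[1:3], voxel_mm, origin)
  list(data = arr, geometry = geom)
}

#' @rdname nifti_io
#' @export
write_motion <- function(motion, path) {
  stopifnot(is.matrix(motion), ncol(motion) == 6L)
  utils::write.table(format(motion, digits = 10, scientific = FALSE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6L) stop("motion table must have 6 columns", call. = FALSE)
  dimnames(m) <- NULL
  m
}
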