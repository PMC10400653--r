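# Shared fixtures: tiny geometries, brute-force reference implementations.

full_mask <- function(shape, voxel_mm = 1) {
  brain_mask(volume_geometry(shape, voxel_mm), array(TRUE, shape))
}

# Brute-force local maxima: exhaustive neighbour scan with the plateau
# tie-break (equal neighbour with lower linear index wins).
bf_local_maxima <- function(values, mask, connectivity = 26L) {
  shape <- dim(values)
  off <- nodebound:::neighbour_offsets(connectivity)
  out <- NULL
  for (lin in which(mask)) {
    ijk <- arrayInd(lin, shape)[1, ]
    ok <- TRUE
    for (o in seq_len(nrow(off))) {
      n <- ijk + off[o, ]
      if (any(n < 1) || any(n > shape)) next
      nl <- nodebound:::lin_index(shape, matrix(n, ncol = 3))
      if (!mask[nl]) next
      if (values[nl] > values[lin] ||
          (values[nl] == values[lin] && nl < lin)) { ok <- FALSE; break }
    }
    if (ok) out <- rbind(out, ijk)
  }
  if (is.null(out)) matrix(integer(0), ncol = 3) else unname(out)
}

# Brute-force connected components by repeated flood fill.
bf_connected_components <- function(voxels, connectivity = 26L) {
  shape <- dim(voxels)
  off <- nodebound:::neighbour_offsets(connectivity)
  lab <- array(0L, dim = shape)
  nextlab <- 0L
  for (lin in which(voxels)) {
    if (lab[lin] > 0) next
    nextlab <- nextlab + 1L
    queue <- lin
    lab[lin] <- nextlab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(cur, shape)[1, ]
      for (o in seq_len(nrow(off))) {
        n <- ijk + off[o, ]
        if (any(n < 1) || any(n > shape)) next
        nl <- nodebound:::lin_index(shape, matrix(n, ncol = 3))
        if (voxels[nl] && lab[nl] == 0) { lab[nl] <- nextlab; queue <- c(queue, nl) }
      }
    }
  }
  lab
}

# Partition-equivalence of two labelings (same components up to renumbering).
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  pos <- a > 0
  length(unique(paste(a[pos], b[pos]))) ==
    length(unique(a[pos])) &&
    length(unique(a[pos])) == length(unique(b[pos]))
}
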