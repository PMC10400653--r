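# Exhaustive-descent watershed oracle: plain per-level, per-component,
# per-voxel loops with direct neighbour scanning. Same contract as
# boundary_mask_watershed (dam semantics, single-voxel rule), written
# naively and independently.
bf_watershed <- function(maps, mask, stop_level, step = 1, conn = 6L) {
  shape <- mask$geometry$shape
  idx <- which(mask$included)
  V <- vapply(maps, function(m) m$values[mask$included], numeric(length(idx)))
  off <- nodebound:::neighbour_offsets(conn)
  claimed <- logical(length(idx))
  onset <- rep(NA_real_, length(idx))
  pos <- arrayInd(idx, shape)
  lookup <- array(0L, shape)               # lattice -> row in idx
  lookup[idx] <- seq_along(idx)
  for (L in seq(100, stop_level, by = -step)) {
    counts <- integer(length(idx))
    for (k in seq_len(ncol(V))) {
      memb <- V[, k] >= L / 100 & !claimed
      for (r in which(memb)) {
        ok <- FALSE
        for (o in seq_len(nrow(off))) {
          p <- pos[r, ] + off[o, ]
          if (any(p < 1) || any(p > shape)) next
          rr <- lookup[p[1], p[2], p[3]]
          if (rr > 0 && memb[rr]) { ok <- TRUE; break }
        }
        if (ok) counts[r] <- counts[r] + 1L
      }
    }
    new_bnd <- counts >= 2L & !claimed
    claimed <- claimed | new_bnd
    onset[new_bnd] <- L
  }
  list(voxels = idx[claimed], onset = onset[claimed])
}

# Build a component_set directly from a list of value vectors/arrays.
fake_components <- function(mask, values_list) {
  maps <- lapply(values_list, function(v) {
    v <- if (is.array(v)) v[mask$included] else v
    scalar_map(mask, v / max(v))
  })
  structure(list(maps = maps, mask = mask, K = length(maps), seed = NA),
            class = "component_set")
}
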