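# Brute-force similarity matrix: explicit double loop over voxel pairs with
# the self-entry exclusion, straight from the definition.
bf_similarity <- function(X) {
  C <- stats::cor(X)
  nv <- ncol(X)
  S <- diag(nv)
  for (i in seq_len(nv)) for (j in seq_len(nv)) {
    if (i == j) next
    keep <- setdiff(seq_len(nv), c(i, j))
    S[i, j] <- stats::cor(C[i, keep], C[j, keep])
  }
  S
}

# Brute-force boundary map: per-row loop over gradient_magnitude.
bf_boundary <- function(sim) {
  nv <- length(sim$idx)
  acc <- array(0, dim = sim$mask$geometry$shape)
  for (i in seq_len(nv)) {
    g <- gradient_magnitude(scalar_map(sim$mask, sim$S[i, ]))
    v <- g$values
    v[is.na(v)] <- 0
    acc <- acc + v
  }
  scalar_map(sim$mask, acc / nv)
}

# A small session wrapper around arbitrary in-mask series.
session_from_matrix <- function(X, mask, tr = 2.5) {
  s <- structure(list(subject = 1, visit = "real", interval = "R0",
                      data = array(0, c(mask$geometry$shape, nrow(X))),
                      motion = matrix(0, nrow(X), 6),
                      nuisance = matrix(0, nrow(X), 3),
                      geometry = mask$geometry, mask = mask, tr_s = tr,
                      seed = 0),
                 class = "bold_session")
  nodebound:::session_with_matrix(s, X)
}
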