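test_that("group ICA recovers spatially disjoint sources", {
  shape <- c(10, 10, 6)
  g <- volume_geometry(shape, 3)
  m <- brain_mask(g, array(TRUE, shape))
  nv <- prod(shape)
  # three sparse disjoint blocks, noiseless random mixing over 90 frames.
  # Disjoint supports are anti-dependent, so recovery sharpens as the
  # supports get sparser; ~10% support is comfortably identifiable.
  # Constant within-block amplitude: voxelwise standardization rescales
  # every voxel anyway, so amplitude structure is not recoverable.
  src <- matrix(0, nv, 3)
  src[1:80, 1] <- 1
  src[101:145, 2] <- 1
  src[201:260, 3] <- 1
  set.seed(17)
  mix <- matrix(rnorm(90 * 3), 90, 3)
  sessions <- list(session_from_matrix(mix %*% t(src), m))
  cs <- fit_group_ica(sessions, K = 3, seed = 5)
  expect_length(cs$maps, 3)
  for (mp in cs$maps) expect_equal(max(map_values(mp)), 1)
  # every source matches some component with |spatial correlation| > 0.95
  M <- vapply(cs$maps, map_values, numeric(nv))
  cc <- abs(cor(src, M))
  expect_true(all(apply(cc, 1, max) > 0.95))
  # determinism
  cs2 <- fit_group_ica(sessions, K = 3, seed = 5)
  expect_identical(vapply(cs$maps, map_values, numeric(nv)),
                   vapply(cs2$maps, map_values, numeric(nv)))
  expect_error(fit_group_ica(sessions, K = 200, seed = 1), "rank")
})

test_that("node masks follow percentile thresholds and nest monotonically", {
  shape <- c(4, 4, 2)
  g <- volume_geometry(shape, 3)
  m <- brain_mask(g, array(TRUE, shape))
  set.seed(2)
  v1 <- runif(32); v2 <- runif(32)
  cs <- fake_components(m, list(v1, v2))
  fm <- node_mask_from_ics(cs, 75)
  # brute-force union of per-component percentile survivors
  keep1 <- which(v1 / max(v1) > quantile(v1 / max(v1), 0.75))
  keep2 <- which(v2 / max(v2) > quantile(v2 / max(v2), 0.75))
  expect_identical(fm$voxels, sort(union(keep1, keep2)))
  # monotone nesting: lower discard fraction keeps a superset
  lower <- node_mask_from_ics(cs, 50)
  expect_true(all(fm$voxels %in% lower$voxels))
  counts <- vapply(c(95, 90, 75, 50, 25),
                   function(d) length(node_mask_from_ics(cs, d)$voxels),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(node_mask_from_ics(cs, 0), "discard_fraction")
})

test_that("watershed boundary onset equals the min of two triangular ridges", {
  shape <- c(9, 3, 1)
  g <- volume_geometry(shape, 3)
  m <- brain_mask(g, array(TRUE, shape))
  hA <- c(1, .9, .8, .7, .6, .5, .4, .3, .2)
  hB <- rev(hA)
  A <- array(rep(hA, 3), shape)
  B <- array(rep(hB, 3), shape)
  cs <- fake_components(m, list(A, B))
  fm <- boundary_mask_watershed(cs, stop_level = 50)
  got <- data.frame(vox = fm$voxels, onset = attr(fm, "onset"))
  # overlap columns x = 4, 5, 6; onset = 100 * min(hA, hB), x = 5 first
  ai <- arrayInd(got$vox, shape)
  expect_setequal(unique(ai[, 1]), c(4, 5, 6))
  expect_true(all(got$onset[ai[, 1] == 5] == 60))
  expect_true(all(got$onset[ai[, 1] %in% c(4, 6)] == 50))
  # disjoint components above the stop level: empty mask
  C1 <- array(c(rep(1, 3), rep(0.01, 24)), shape)
  C2 <- array(c(rep(0.01, 24), rep(1, 3)), shape)
  fm0 <- boundary_mask_watershed(fake_components(m, list(C1, C2)), 50)
  expect_length(fm0$voxels, 0)
})

test_that("watershed masks grow monotonically as the stop level descends", {
  set.seed(9)
  shape <- c(8, 8, 4)
  g <- volume_geometry(shape, 3)
  m <- brain_mask(g, array(TRUE, shape))
  vals <- lapply(1:3, function(k) {
    sm <- gaussian_smooth(scalar_map(m, array(runif(prod(shape)), shape)), 8)
    map_values(sm)
  })
  cs <- fake_components(m, vals)
  m63 <- boundary_mask_watershed(cs, 63)
  m59 <- boundary_mask_watershed(cs, 59)
  expect_true(all(m63$voxels %in% m59$voxels))
})

test_that("watershed agrees with the exhaustive-descent oracle on random sets", {
  set.seed(77)
  for (rep in 1:100) {
    shape <- sample(3:8, 3, replace = TRUE)
    g <- volume_geometry(shape, 3)
    inc <- array(runif(prod(shape)) < 0.9, shape)
    if (!any(inc)) inc[1] <- TRUE
    m <- brain_mask(g, inc)
    K <- sample(2:4, 1)
    vals <- lapply(seq_len(K), function(k) {
      v <- runif(sum(inc)); v / max(v)
    })
    cs <- fake_components(m, vals)
    stop_level <- sample(c(50, 63, 80), 1)
    got <- boundary_mask_watershed(cs, stop_level)
    want <- bf_watershed(cs$maps, m, stop_level)
    expect_identical(got$voxels, want$voxels)
    expect_identical(as.numeric(attr(got, "onset")), as.numeric(want$onset))
  }
})

test_that("node and boundary masks from one component set stay complementary", {
  geom <- volume_geometry(c(16, 16, 16), 3)
  ph <- make_phantom(geom, K = 6, seed = 1)
  des <- study_design(n_subjects = 8, n_volumes = 64)
  sessions <- lapply(1:8, function(s)
    preprocess_session(simulate_session(ph, des, s, "ica", "R0", seed = 100 + s)))
  cs <- fit_group_ica(sessions, K = 6, seed = 11)
  # components recover the ground-truth networks
  mm <- match_components(cs, ph)
  expect_gt(median(attr(mm, "correlation")), 0.7)
  nodes <- node_mask_from_ics(cs, 97)
  bnd <- boundary_mask_watershed(cs, 30)
  expect_gt(length(nodes$voxels), 0)
  expect_gt(length(bnd$voxels), 0)
  inter <- length(intersect(nodes$voxels, bnd$voxels))
  expect_lt(inter, 0.2 * min(length(nodes$voxels), length(bnd$voxels)))
})

test_that("stimulation target is the density maximum nearest the IC overlap", {
  shape <- c(9, 9, 3)
  g <- volume_geometry(shape, 3)
  m <- brain_mask(g, array(TRUE, shape))
  blob <- function(c0) {
    gr <- as.matrix(expand.grid(1:9, 1:9, 1:3))
    array(exp(-rowSums(sweep(gr, 2, c0)^2) / 6), shape)
  }
  A <- blob(c(4, 5, 2)); B <- blob(c(6, 5, 2))
  dens <- array(0, shape)
  dens[5, 5, 2] <- 3                      # maximum inside the overlap
  dens[9, 9, 3] <- 5                      # stronger but far away
  dmap <- scalar_map(m, dens)
  tgt <- select_stimulation_target(scalar_map(m, A), scalar_map(m, B), dmap)
  expect_equal(as.integer(tgt), c(5L, 5L, 2L))

  # two equidistant maxima: lowest linear index wins
  dens2 <- array(0, shape)
  dens2[4, 5, 2] <- 1
  dens2[6, 5, 2] <- 1
  t2 <- select_stimulation_target(scalar_map(m, A), scalar_map(m, B),
                                  scalar_map(m, dens2))
  expect_equal(as.integer(t2), c(4L, 5L, 2L))

  far <- blob(c(1, 1, 1)); far[far < 0.9] <- 0
  off <- blob(c(9, 9, 3)); off[off < 0.9] <- 0
  expect_error(select_stimulation_target(scalar_map(m, far), scalar_map(m, off),
                                         dmap), "empty")
})
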