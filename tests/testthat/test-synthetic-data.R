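desk_geom <- volume_geometry(c(16, 16, 16), 3)

test_that("phantom construction: determinism, ground truth disjointness, K = 2 plane", {
  ph1 <- make_phantom(desk_geom, K = 2, seed = 7)
  ph2 <- make_phantom(desk_geom, K = 2, seed = 7)
  expect_identical(ph1$networks[[1]]$values, ph2$networks[[1]]$values)
  expect_identical(ph1$boundary_voxels, ph2$boundary_voxels)

  # node and boundary sets are disjoint; every in-mask voxel has weight > 0
  expect_length(intersect(ph1$node_lin, ph1$boundary_voxels), 0)
  tot <- Reduce(`+`, lapply(ph1$networks, map_values))
  expect_true(all(tot > 0))
  # every network map has unit maximum
  for (nw in ph1$networks) expect_equal(max(map_values(nw)), 1)

  # K = 2: boundary voxels form a planar slab (perpendicular to the line
  # joining the two network centres) halfway between the supports
  u <- ph1$centers[2, ] - ph1$centers[1, ]
  u <- u / sqrt(sum(u^2))
  mid <- sum(colMeans(ph1$centers) * u)
  bw <- voxel_to_world(ph1$geometry, arrayInd(ph1$boundary_voxels, ph1$geometry$shape))
  proj <- bw %*% u
  expect_gt(length(proj), 10)
  expect_true(all(abs(proj - mid) < 4 * max(ph1$geometry$voxel_mm)))
  # and the plane separates the two node voxels
  nproj <- voxel_to_world(ph1$geometry, ph1$node_voxels) %*% u
  expect_true((nproj[1] - mid) * (nproj[2] - mid) < 0)

  expect_error(make_phantom(volume_geometry(c(3, 3, 3), 3), K = 50, seed = 1),
               "too large")
})

test_that("subject jitter preserves network count and creates subject-specific layouts", {
  ph <- make_phantom(desk_geom, K = 4, seed = 3)
  W1 <- subject_networks(ph, 1)
  W1b <- subject_networks(ph, 1)
  W2 <- subject_networks(ph, 2)
  expect_identical(W1, W1b)           # same subject -> same layout
  expect_equal(ncol(W1), 4L)
  expect_true(all(rowSums(W1) > 0))
  expect_gt(max(abs(W1 - W2)), 0.05)  # different subjects differ
})

test_that("latent signals are band-limited to 0.01-0.1 Hz", {
  set.seed(1)
  s <- nodebound:::band_limited_signals(128, 4, tr = 2.5)
  f <- stats::mvfft(s)
  freqs <- (seq_len(128) - 1) / (128 * 2.5)
  freqs <- pmin(freqs, 1 / 2.5 - freqs)
  inband <- freqs >= 0.01 & freqs <= 0.1
  pow <- Mod(f)^2
  expect_lt(sum(pow[!inband, ]) / sum(pow), 0.05)
  expect_equal(apply(s, 2, sd), rep(1, 4), tolerance = 1e-10)
})

test_that("noiseless single-network sessions have perfectly correlated voxels", {
  geom <- volume_geometry(c(10, 10, 10), 3)
  ph <- make_phantom(geom, K = 2, seed = 5, jitter_amp_vox = 0)
  des <- study_design(n_subjects = 2, n_volumes = 32)
  ses <- simulate_session(ph, des, 1, "real", "R0", noise_sd = 0, seed = 9,
                          nuisance_amp = 0)
  # two voxels dominated by the same network: r = 1 (identical up to scale)
  idx <- which(ph$mask$included)
  W <- subject_networks(ph, 1)
  core1 <- idx[order(W[, 1] - W[, 2], decreasing = TRUE)[1:2]]
  flat <- matrix(ses$data, ncol = 32)
  # pick voxels where network 1 overwhelmingly dominates
  dom <- idx[W[, 1] > 0.9 & W[, 2] < 0.05 * W[, 1]]
  if (length(dom) >= 2) {
    r <- cor(flat[dom[1], ], flat[dom[2], ])
    expect_gt(r, 0.999)
  } else {
    r <- cor(flat[core1[1], ], flat[core1[2], ])
    expect_gt(r, 0.99)
  }
  expect_identical(ses$data,
                   simulate_session(ph, des, 1, "real", "R0", noise_sd = 0,
                                    seed = 9, nuisance_amp = 0)$data)
})

test_that("boundary_blur strictly increases correlation with the neighbour network core", {
  geom <- volume_geometry(c(12, 12, 12), 3)
  ph <- make_phantom(geom, K = 2, seed = 11, jitter_amp_vox = 0)
  des <- study_design(n_subjects = 2, n_volumes = 64)
  target <- ph$boundary_voxels
  idx <- which(ph$mask$included)
  W <- subject_networks(ph, 1)

  r_to_neighbour <- function(delta) {
    eff <- effect_spec(target, "R1", "boundary_blur", delta = delta)
    ses <- simulate_session(ph, des, 1, "real", "R1", effect = eff,
                            noise_sd = 0, seed = 21, nuisance_amp = 0)
    flat <- matrix(ses$data, ncol = 64)
    v <- target[1]
    row <- match(v, idx)
    nb <- order(W[row, ], decreasing = TRUE)[2]
    core <- idx[which.max(W[, nb] - W[, -nb])]
    cor(flat[v, ], flat[core, ])
  }
  expect_gt(r_to_neighbour(1), r_to_neighbour(0) + 0.01)
})

test_that("effect targets outside the mask are rejected", {
  geom <- volume_geometry(c(10, 10, 10), 3)
  ph <- make_phantom(geom, K = 2, seed = 5)
  des <- study_design(n_subjects = 2, n_volumes = 32)
  out <- which(!ph$mask$included)[1]
  eff <- effect_spec(out, "R1", "boundary_blur", 1)
  expect_error(simulate_session(ph, des, 1, "real", "R1", effect = eff, seed = 1),
               "outside")
})

test_that("make_study emits the full crossover design with stable manifest", {
  geom <- volume_geometry(c(10, 10, 10), 3)
  ph <- make_phantom(geom, K = 2, seed = 5)
  des <- study_design(n_subjects = 3, n_volumes = 16)
  st <- make_study(ph, des, seed = 100, ica_visit = TRUE)
  # 2 visits x 4 intervals + 1 ica session per subject
  expect_equal(nrow(st$manifest), 3 * (2 * 4 + 1))
  expect_equal(length(st$sessions), nrow(st$manifest))
  per_subject <- table(st$manifest$subject[st$manifest$visit != "ica"])
  expect_true(all(per_subject == 8))
  # default full design: 184 sessions for 23 subjects
  man_full <- study_manifest(study_design(), seed = 1, ica_visit = FALSE)
  expect_equal(nrow(man_full), 184)
  # manifest seeds are deterministic given the master seed
  expect_identical(st$manifest$seed, study_manifest(des, 100)$seed)
})

test_that("session files round-trip through NIfTI and motion text", {
  geom <- volume_geometry(c(8, 8, 8), 3)
  ph <- make_phantom(geom, K = 2, seed = 5)
  des <- study_design(n_subjects = 2, n_volumes = 16)
  dir <- withr::local_tempdir()
  st <- make_study(ph, des, seed = 2, ica_visit = FALSE, out_dir = dir)
  expect_true(all(file.exists(st$manifest$path)))
  back <- read_volume(st$manifest$path[1])
  expect_equal(dim(back$data), c(8, 8, 8, 16))
  expect_equal(back$geometry$voxel_mm, c(3, 3, 3), tolerance = 1e-5)
  expect_equal(back$data, st$sessions[[1]]$data, tolerance = 1e-5)
  mot <- read_motion(file.path(dir, "sub-01_real_R0_motion.txt"))
  expect_equal(mot, st$sessions[[1]]$motion, tolerance = 1e-8)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
})
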