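test_that("block resampling averages source blocks and conserves mass", {
  # constant volume stays constant
  m <- full_mask(c(6, 6, 6), 2)
  cm <- scalar_map(m, array(3.7, c(6, 6, 6)))
  out <- resample_volume(cm, 4)
  expect_identical(out$geometry$shape, c(3L, 3L, 3L))
  expect_true(all(abs(map_values(out) - 3.7) < 1e-12))

  # each output voxel equals the hand-computed mean of its 8 sources
  set.seed(11)
  v <- array(rnorm(8^3), c(8, 8, 8))
  m8 <- full_mask(c(8, 8, 8), 1)
  out <- resample_volume(scalar_map(m8, v), 2)
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    blk <- v[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), (2 * k - 1):(2 * k)]
    expect_equal(out$values[i, j, k], mean(blk), tolerance = 1e-12)
  }
  # mass conservation: sum(target) * block volume == sum(source)
  expect_equal(sum(map_values(out)) * 8, sum(v), tolerance = 1e-9)
})

test_that("resampled mask keeps target voxels with > 50% in-mask sources", {
  g <- volume_geometry(c(2, 2, 2), 1)
  m <- brain_mask(g, array(TRUE, c(2, 2, 2)))
  out <- resample_volume(m, 2)
  expect_equal(sum(out$included), 1L)

  # 5/8 sources in-mask -> included; exactly half -> excluded (strict majority)
  inc <- array(FALSE, c(2, 2, 2)); inc[1:2, 1:2, 1] <- TRUE; inc[1, 1, 2] <- TRUE
  out2 <- resample_volume(brain_mask(g, inc), 2)
  expect_equal(sum(out2$included), 1L)
  half <- array(FALSE, c(2, 2, 2)); half[1:2, 1:2, 1] <- TRUE
  expect_error(resample_volume(brain_mask(g, half), 2), "at least")
})

test_that("resampling rejects bad target sizes", {
  m <- full_mask(c(4, 4, 4), 1)
  cm <- scalar_map(m, array(1, c(4, 4, 4)))
  expect_error(resample_volume(cm, -1), "positive")
  expect_error(resample_volume(cm, 10), "coarser")
})

test_that("mask-normalized smoothing preserves constants, bounds, and unit mass", {
  m <- full_mask(c(9, 9, 9), 2)
  const <- scalar_map(m, array(2.5, c(9, 9, 9)))
  expect_true(all(abs(map_values(gaussian_smooth(const, 6)) - 2.5) < 1e-9))

  # interior unit spike, fwhm 4 mm on 2 mm grid: output sums to 1
  m15 <- full_mask(c(15, 15, 15), 2)
  v <- array(0, c(15, 15, 15)); v[8, 8, 8] <- 1
  sm <- gaussian_smooth(scalar_map(m15, v), 4)
  expect_equal(sum(map_values(sm)), 1, tolerance = 1e-6)

  # monotone: output within input range
  set.seed(2)
  r <- array(runif(9^3), c(9, 9, 9))
  sr <- gaussian_smooth(scalar_map(m, r), 5)
  expect_true(all(map_values(sr) >= min(r) - 1e-12))
  expect_true(all(map_values(sr) <= max(r) + 1e-12))

  # fwhm 0 returns input; negative rejected
  expect_identical(map_values(gaussian_smooth(scalar_map(m, r), 0)), r[m$included])
  expect_error(gaussian_smooth(scalar_map(m, r), -1), ">= 0")
})

test_that("smoothing kernel uses sigma = fwhm / (2 sqrt(2 ln 2))", {
  # measure the effective sigma from the second moment of a smoothed spike
  n <- 31
  m <- full_mask(c(n, n, n), 1)
  v <- array(0, c(n, n, n)); v[16, 16, 16] <- 1
  fwhm <- 6
  sm <- gaussian_smooth(scalar_map(m, v), fwhm)
  prof <- apply(sm$values, 1, sum)    # 1D marginal along x
  x <- seq_len(n) - 16
  sigma_hat <- sqrt(sum(prof * x^2) / sum(prof))
  expect_equal(sigma_hat, fwhm / (2 * sqrt(2 * log(2))), tolerance = 0.01)
})

test_that("local maxima: single peak, plateau tie-break, separation pruning", {
  n <- 11
  m <- full_mask(c(n, n, n), 1)
  ctr <- c(4, 4, 4)
  d2 <- function(c0) {
    g <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
    array(rowSums(sweep(as.matrix(g), 2, c0)^2), c(n, n, n))
  }
  blob <- exp(-d2(ctr) / 8)
  mx <- local_maxima(scalar_map(m, blob))
  expect_equal(unname(mx), matrix(ctr, ncol = 3))

  # plateau of two equal adjacent voxels -> lowest linear index only
  v <- array(0, c(n, n, n)); v[3, 3, 3] <- 1; v[4, 3, 3] <- 1
  mx <- local_maxima(scalar_map(m, v))
  # background plateau at 0 also resolves to its lowest-index voxel; restrict
  # to positive maxima
  pos <- mx[v[mx] > 0, , drop = FALSE]
  expect_equal(unname(pos), matrix(c(3, 3, 3), ncol = 3))

  # two blobs further apart than min_separation -> both kept; closer -> one
  two <- exp(-d2(c(3, 6, 6)) / 4) + 0.9 * exp(-d2(c(9, 6, 6)) / 4)
  mx2 <- local_maxima(scalar_map(m, two), min_separation_mm = 4)
  expect_equal(nrow(mx2), 2L)
  mx1 <- local_maxima(scalar_map(m, two), min_separation_mm = 8)
  expect_equal(unname(mx1), matrix(c(3, 6, 6), ncol = 3))  # higher peak wins
})

test_that("corner-touching voxels connect at 26- but not 6-connectivity", {
  v <- array(FALSE, c(3, 3, 3))
  v[1, 1, 1] <- TRUE; v[2, 2, 2] <- TRUE
  expect_equal(length(connected_components(v, 26)$sizes), 1L)
  expect_equal(length(connected_components(v, 6)$sizes), 2L)
  expect_equal(length(connected_components(array(FALSE, c(3, 3, 3)))$sizes), 0L)
})

test_that("maxima and components match brute force on random small lattices", {
  set.seed(42)
  for (rep in 1:100) {
    shape <- sample(2:5, 3, replace = TRUE)
    conn <- sample(c(6L, 18L, 26L), 1)
    vox <- array(runif(prod(shape)) < 0.45, shape)
    cc <- connected_components(vox, conn)
    expect_true(same_partition(cc$labels, bf_connected_components(vox, conn)))

    mask <- array(runif(prod(shape)) < 0.8, shape)
    if (!any(mask)) mask[1] <- TRUE
    vals <- array(sample(0:3, prod(shape), replace = TRUE), shape)  # force plateaus
    sm <- scalar_map(brain_mask(volume_geometry(shape, 1), mask), vals)
    got <- local_maxima(sm, conn)
    want <- bf_local_maxima(sm$values, mask, conn)
    expect_equal(nrow(got), nrow(want))
    key <- function(m) sort(nodebound:::lin_index(shape, m))
    if (nrow(got)) expect_equal(key(got), key(want))
  }
})

test_that("gradient magnitude: constant, linear ramp, step edge", {
  n <- 8
  m <- full_mask(c(n, n, n), 1)
  expect_true(all(map_values(gradient_magnitude(
    scalar_map(m, array(5, c(n, n, n))))) == 0))

  # ramp a*x on 1 mm grid: |a| at interior voxels (and at one-sided edges)
  a <- 1.75
  ramp <- array(rep(a * (1:n), times = n * n), c(n, n, n))
  g <- gradient_magnitude(scalar_map(m, ramp))
  expect_true(all(abs(map_values(g) - a) < 1e-10))

  # step edge: gradient maximal on the two planes flanking the jump
  step <- array(rep(c(0, 0, 0, 0, 1, 1, 1, 1), times = n * n), c(n, n, n))
  gs <- gradient_magnitude(scalar_map(m, step))$values
  expect_true(all(gs[4, , ] == 0.5) && all(gs[5, , ] == 0.5))
  expect_true(max(gs) == 0.5)

  # a fully isolated in-mask voxel is flagged and zero
  inc <- array(FALSE, c(n, n, n)); inc[1, 1, 1] <- TRUE; inc[5:6, 5, 5] <- TRUE
  iso <- gradient_magnitude(scalar_map(brain_mask(m$geometry, inc),
                                       array(1:(n^3), c(n, n, n))))
  expect_equal(attr(iso, "isolated"), which(array(seq_len(n^3), c(n, n, n)) == 1))
  expect_equal(iso$values[1, 1, 1], 0)
})
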