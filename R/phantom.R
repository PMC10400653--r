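#' Study design for a sham-controlled crossover rsfMRI experiment
#'
#' Describes the sampling scheme the generator emulates: every subject is
#' scanned on a real-stimulation visit and a sham visit, and on each visit
#' contributes one pre-stimulation scan (R0) and three post-stimulation
#' scans (R1, R2, R3), each an `n_volumes`-frame BOLD series at repetition
#' time `tr_s`.
#'
#' @param n_subjects Number of subjects (`>= 2`). Default 23.
#' @param n_volumes Frames per session (`>= 16`). Default 125.
#' @param tr_s Repetition time in seconds (`> 0`). Default 2.5.
#' @param visits Visit labels; first is the stimulated visit, second sham.
#' @param intervals Ordered scan-interval labels.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_subjects = 23L, n_volumes = 125L, tr_s = 2.5,
                         visits = c("real", "sham"),
                         intervals = c("R0", "R1", "R2", "R3")) {
  n_subjects <- as.integer(n_subjects)
  n_volumes <- as.integer(n_volumes)
  if (is.na(n_subjects) || n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (is.na(n_volumes) || n_volumes < 16L) stop("n_volumes must be >= 16", call. = FALSE)
  if (!is.finite(tr_s) || tr_s <= 0) stop("tr_s must be > 0", call. = FALSE)
  structure(list(n_subjects = n_subjects, n_volumes = n_volumes, tr_s = tr_s,
                 visits = visits, intervals = intervals),
            class = "study_design")
}

#' Synthetic multi-network brain phantom
#'
#' Builds `K` smooth, blob-like network weight maps tiling an (ellipsoidal
#' by default) brain mask, with overlap zones between neighbouring networks.
#' Ground truth is returned alongside: the node voxels (each network's
#' weight maximum) and the boundary voxels (in-mask voxels where two or
#' more network supports overlap, i.e. where the second-strongest network
#' weight still reaches `support_floor`), which are disjoint from the node
#' set by construction. Per-subject spatial layouts are produced by
#' [subject_networks()] from the jitter seeds stored here.
#'
#' @param geometry A [volume_geometry()].
#' @param K Number of networks (`>= 2`).
#' @param seed Integer seed; the phantom is deterministic given it.
#' @param mask Optional [brain_mask()]; default is the inscribed ellipsoid.
#' @param n_subjects Number of per-subject jitter seeds to draw. Default 32.
#' @param jitter_amp_vox Amplitude of the subject displacement field, in
#'   voxels. Default 1.
#' @param sigma_scale Blob width as a fraction of the expected
#'   centre-to-centre spacing. Default 0.35: networks overlap at their
#'   rims (voxel-scale transition zones) but stay individually
#'   identifiable, as resting-state networks are.
#' @param support_floor Weight at which a network still counts as
#'   supporting a voxel; a voxel whose second-strongest network weight
#'   reaches this floor lies in an overlap (boundary) zone. Default 0.15.
#' @return An object of class `phantom` with fields `geometry`, `mask`,
#'   `networks` (list of K unit-maximum [scalar_map()]s), `node_voxels`
#'   (K x 3 index matrix), `boundary_voxels` (linear indices), `jitter`
#'   (per-subject seeds and amplitude), `seed`.
#' @export
make_phantom <- function(geometry, K, seed, mask = NULL, n_subjects = 32L,
                         jitter_amp_vox = 1, sigma_scale = 0.35,
                         support_floor = 0.15) {
  stopifnot(inherits(geometry, "volume_geometry"))
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  if (is.null(mask)) mask <- ellipsoid_mask(geometry)
  nvox <- sum(mask$included)
  if (nvox < 8L * K) stop("K too large for this geometry/mask", call. = FALSE)

  set.seed(seed)
  idx <- which(mask$included)
  coords <- voxel_to_world(geometry, arrayInd(idx, geometry$shape))
  km <- stats::kmeans(coords, centers = K, nstart = 5L, iter.max = 50L)
  centers <- km$centers

  vol_mm3 <- nvox * prod(geometry$voxel_mm)
  spacing <- (vol_mm3 / K)^(1 / 3)
  sigma <- sigma_scale * spacing

  networks <- vector("list", K)
  W <- matrix(0, nrow = nvox, ncol = K)
  for (k in seq_len(K)) {
    d2 <- colSums((t(coords) - centers[k, ])^2)
    w <- exp(-d2 / (2 * sigma^2))
    W[, k] <- w / max(w)
    networks[[k]] <- scalar_map(mask, W[, k])
  }

  node_lin <- idx[apply(W, 2, which.max)]
  ord <- apply(W, 1, function(r) sort(r, decreasing = TRUE)[1:2])
  # boundary ground truth: voxels inside the overlap zone of two network
  # supports (far-rim voxels where every network is negligible are
  # transitions of nothing into nothing and do not count)
  boundary <- idx[ord[2, ] >= support_floor]
  boundary <- setdiff(boundary, node_lin)
  # network cores: strong, unambiguous single-network territory
  core <- idx[ord[1, ] >= 0.6 & ord[2, ] <= 0.3 * ord[1, ]]

  jitter_seeds <- sample.int(.Machine$integer.max, n_subjects)
  structure(list(
    geometry = geometry, mask = mask, networks = networks,
    sigma_mm = sigma, centers = centers,
    node_voxels = arrayInd(node_lin, geometry$shape),
    node_lin = node_lin,
    boundary_voxels = boundary,
    core_voxels = core,
    jitter = list(seeds = jitter_seeds, amp_vox = jitter_amp_vox),
    seed = seed), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d networks on %s grid, %d in-mask voxels, %d boundary voxels\n",
              length(x$networks), paste(x$geometry$shape, collapse = "x"),
              sum(x$mask$included), length(x$boundary_voxels)))
  invisible(x)
}

# Inscribed ellipsoid mask (semi-axes 0.48 of each extent).
ellipsoid_mask <- function(geometry) {
  g <- expand.grid(i = seq_len(geometry$shape[1]),
                   j = seq_len(geometry$shape[2]),
                   k = seq_len(geometry$shape[3]))
  w <- voxel_to_world(geometry, as.matrix(g))
  ext <- geometry$shape * geometry$voxel_mm
  ctr <- geometry$origin + ext / 2
  r <- sweep(sweep(w, 2, ctr), 2, 0.48 * ext, "/")
  brain_mask(geometry, array(rowSums(r^2) <= 1, geometry$shape))
}

#' Subject-specific network layouts
#'
#' Applies the subject's smooth random displacement field (amplitude set in
#' [make_phantom()]) to the phantom's network maps, producing the
#' subject-specific spatial layout shared by all of that subject's sessions.
#'
#' @param phantom A [make_phantom()] result.
#' @param subject Subject index (1-based).
#' @return Matrix (in-mask voxels x K) of jittered network weights.
#' @export
subject_networks <- function(phantom, subject) {
  stopifnot(inherits(phantom, "phantom"))
  js <- phantom$jitter
  if (subject < 1 || subject > length(js$seeds))
    stop("subject index out of range for this phantom", call. = FALSE)
  geom <- phantom$geometry
  idx <- which(phantom$mask$included)
  coords <- voxel_to_world(geom, arrayInd(idx, geom$shape))
  if (js$amp_vox > 0) {
    disp <- displacement_field(geom, js$seeds[subject], js$amp_vox)
    coords <- coords + disp[idx, , drop = FALSE]
  }
  K <- length(phantom$networks)
  W <- matrix(0, nrow = length(idx), ncol = K)
  for (k in seq_len(K)) {
    v <- phantom$networks[[k]]$values
    v[!phantom$mask$included] <- 0
    # sample the unjittered map at displaced positions
    W[, k] <- trilinear_sample(v, geom, coords)
  }
  # jitter must not silence a voxel entirely: keep a small floor of the
  # original weights so every in-mask voxel retains positive total weight
  W0 <- vapply(phantom$networks, function(n) n$values[phantom$mask$included],
               numeric(length(idx)))
  pmax(W, 0.02 * W0)
}

# Smooth random displacement field: low-resolution white noise upsampled by
# trilinear interpolation, rescaled so max |disp| = amp_vox * voxel_mm.
displacement_field <- function(geometry, seed, amp_vox) {
  set.seed(seed)
  lowshape <- pmax(2L, ceiling(geometry$shape / 5))
  lowgeom <- volume_geometry(lowshape, geometry$shape * geometry$voxel_mm / lowshape,
                             geometry$origin)
  g <- as.matrix(expand.grid(i = seq_len(geometry$shape[1]),
                             j = seq_len(geometry$shape[2]),
                             k = seq_len(geometry$shape[3])))
  pts <- voxel_to_world(geometry, g)
  disp <- matrix(0, nrow = nrow(pts), ncol = 3)
  for (ax in 1:3) {
    lowfield <- array(stats::rnorm(prod(lowshape)), lowshape)
    d <- trilinear_sample(lowfield, lowgeom, pts)
    m <- max(abs(d))
    if (m > 0) d <- d / m * amp_vox * geometry$voxel_mm[ax]
    disp[, ax] <- d
  }
  disp
}

#' Condition-effect specification
#'
#' Describes the connectivity modulation injected into real-visit sessions:
#' either a scaling of the dominant network's coupling at the target voxels
#' (`coupling_change`, weight multiplied by `1 + delta`) or an admixture of
#' the locally second-strongest network's signal (`boundary_blur`, emulating
#' a loss of specificity at region borders). `delta = 0` is a null study.
#'
#' @param target_voxels Linear voxel indices (inside the phantom mask).
#' @param intervals Interval labels the effect applies to, e.g. `"R1"`.
#' @param kind `"coupling_change"` or `"boundary_blur"`.
#' @param delta Effect magnitude in `[-1, 1]`.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(target_voxels, intervals,
                        kind = c("boundary_blur", "coupling_change"),
                        delta) {
  kind <- match.arg(kind)
  if (!is.numeric(delta) || length(delta) != 1L || abs(delta) > 1)
    stop("delta must be a single value in [-1, 1]", call. = FALSE)
  structure(list(target_voxels = as.integer(target_voxels),
                 intervals = intervals, kind = kind, delta = delta),
            class = "effect_spec")
}

# Band-limited latent signals: white Gaussian noise shaped in the frequency
# domain (hard pass band [low, high] Hz), unit variance per column.
band_limited_signals <- function(n, k, tr, low = 0.01, high = 0.1) {
  x <- matrix(stats::rnorm(n * k), nrow = n, ncol = k)
  f <- stats::mvfft(x)
  j <- seq_len(n) - 1
  freqs <- pmin(j, n - j) / (n * tr)   # folded frequency, exactly symmetric
  keep <- freqs >= low & freqs <= high
  f[!keep, ] <- 0
  s <- Re(stats::mvfft(f, inverse = TRUE)) / n
  matrix(as.numeric(scale(s)), nrow = n)
}

#' Simulate one BOLD session
#'
#' Voxel time series are weighted sums of band-limited (0.01-0.1 Hz) latent
#' network signals, with the weights given by the subject's jittered network
#' maps, plus three nuisance signals (white-matter, CSF and global proxies)
#' and white noise. When `effect` applies (real visit, matching interval),
#' the target voxels' mixing weights are modified as described in
#' [effect_spec()]. Head motion is a random walk in the six rigid-body
#' parameters, independent of condition by default.
#'
#' @param phantom A [make_phantom()] result.
#' @param design A [study_design()].
#' @param subject Subject index.
#' @param visit Visit label (effect applies on the first/"real" visit only).
#' @param interval Interval label.
#' @param effect An [effect_spec()] or `NULL`.
#' @param noise_sd White-noise standard deviation (default 1; latent
#'   signals have unit variance).
#' @param seed Integer seed; the session is bit-reproducible given it.
#' @param motion_sd Per-frame translation random-walk step in mm (rotations
#'   use `motion_sd / 100` rad). Default 0.02.
#' @param nuisance_amp Amplitude of nuisance-signal loadings. Default 0.3.
#' @return An object of class `bold_session`: fields `subject`, `visit`,
#'   `interval`, `data` (4D array), `motion` (n x 6), `nuisance` (n x 3),
#'   `geometry`, `mask`, `tr_s`, `seed`.
#' @export
simulate_session <- function(phantom, design, subject, visit, interval,
                             effect = NULL, noise_sd = 1, seed,
                             motion_sd = 0.02, nuisance_amp = 0.3) {
  stopifnot(inherits(phantom, "phantom"), inherits(design, "study_design"))
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  mask <- phantom$mask
  idx <- which(mask$included)
  if (!is.null(effect) && !all(effect$target_voxels %in% idx))
    stop("effect targets outside the phantom mask", call. = FALSE)

  W <- subject_networks(phantom, subject)
  n <- design$n_volumes
  K <- ncol(W)
  set.seed(seed)
  S <- band_limited_signals(n, K, design$tr_s)

  apply_effect <- !is.null(effect) && effect$delta != 0 &&
    visit == design$visits[1] && interval %in% effect$intervals
  extra <- matrix(0, nrow = length(idx), ncol = K)
  if (apply_effect) {
    rows <- match(effect$target_voxels, idx)
    for (r in rows) {
      o <- order(W[r, ], decreasing = TRUE)
      own <- o[1]; nb <- o[2]
      if (effect$kind == "coupling_change") {
        W[r, own] <- W[r, own] * (1 + effect$delta)
      } else {
        # loss of specificity at the border: the voxel's own-network
        # coupling fades while the neighbouring network's signal is
        # admixed; at delta = 1 the voxel carries both networks equally
        # (the border has blurred across it)
        extra[r, nb] <- extra[r, nb] +
          (effect$delta / 2) * (W[r, own] + W[r, nb])
        W[r, own] <- (1 - effect$delta / 2) * W[r, own]
      }
    }
  }

  Y <- (W + extra) %*% t(S)              # voxels x time

  # nuisance: slow WM/CSF proxies and a global signal with uniform loading
  nuis <- band_limited_signals(n, 3L, design$tr_s, low = 0.005, high = 0.08)
  wmcsf_load <- matrix(stats::runif(length(idx) * 2, 0, nuisance_amp), ncol = 2)
  Y <- Y + wmcsf_load %*% t(nuis[, 1:2]) +
    matrix(nuisance_amp, length(idx), 1) %*% t(nuis[, 3])

  if (noise_sd > 0) Y <- Y + matrix(stats::rnorm(length(Y), 0, noise_sd), nrow(Y))

  data <- array(0, dim = c(phantom$geometry$shape, n))
  flat <- matrix(data, ncol = n)
  flat[idx, ] <- Y
  data <- array(flat, dim = c(phantom$geometry$shape, n))

  steps <- matrix(stats::rnorm(n * 6L, 0,
                               rep(c(motion_sd, motion_sd / 100), each = 3L)[
                                 rep(1:6, each = n)]), nrow = n)
  motion <- apply(steps, 2, cumsum)

  structure(list(subject = subject, visit = visit, interval = interval,
                 data = data, motion = motion, nuisance = nuis,
                 geometry = phantom$geometry, mask = mask,
                 tr_s = design$tr_s, seed = seed),
            class = "bold_session")
}

#' @export
print.bold_session <- function(x, ...) {
  cat(sprintf("<bold_session> subject %s, %s/%s: %s x %d frames (TR %gs)\n",
              x$subject, x$visit, x$interval,
              paste(x$geometry$shape, collapse = "x"), dim(x$data)[4], x$tr_s))
  invisible(x)
}

#' Session manifest for a full study
#'
#' Enumerates every session of the crossover design (plus, optionally, one
#' independent baseline "ica" session per subject used only for mask
#' construction) and derives a reproducible per-session seed from the master
#' seed.
#'
#' @param design A [study_design()].
#' @param seed Master seed.
#' @param ica_visit Include one independent `visit = "ica"` session per
#'   subject? Default `TRUE`.
#' @return A tibble with columns `subject`, `visit`, `interval`, `seed`.
#' @export
study_manifest <- function(design, seed, ica_visit = TRUE) {
  visits <- design$visits
  grid <- expand.grid(interval = design$intervals, visit = visits,
                      subject = seq_len(design$n_subjects),
                      stringsAsFactors = FALSE)[, 3:1]
  if (ica_visit) {
    grid <- rbind(grid, data.frame(subject = seq_len(design$n_subjects),
                                   visit = "ica",
                                   interval = design$intervals[1]))
  }
  set.seed(seed)
  grid$seed <- sample.int(.Machine$integer.max, nrow(grid))
  tibble::as_tibble(grid)
}

#' Generate a full synthetic study
#'
#' Simulates every session in the [study_manifest()]. Sham and "ica" visits
#' never carry the injected effect; a subject's spatial layout (jitter) is
#' identical across all of that subject's sessions. Optionally writes each
#' session as NIfTI plus a 6-column motion text file and a manifest CSV.
#'
#' @param phantom A [make_phantom()] result.
#' @param design A [study_design()].
#' @param effect An [effect_spec()] or `NULL`.
#' @param seed Master seed; per-session seeds are derived from it.
#' @param noise_sd,motion_sd Passed to [simulate_session()].
#' @param ica_visit Include the independent mask-construction visit.
#' @param out_dir If non-`NULL`, write NIfTI/motion/manifest files there.
#' @return List with `sessions` (list of `bold_session`) and `manifest`
#'   (tibble; gains a `path` column when `out_dir` is set).
#' @export
make_study <- function(phantom, design, effect = NULL, seed, noise_sd = 1,
                       motion_sd = 0.02, ica_visit = TRUE, out_dir = NULL) {
  man <- study_manifest(design, seed, ica_visit = ica_visit)
  sessions <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sessions[[i]] <- simulate_session(
      phantom, design, man$subject[i], man$visit[i], man$interval[i],
      effect = effect, noise_sd = noise_sd, seed = man$seed[i],
      motion_sd = motion_sd)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(nrow(man))
    for (i in seq_len(nrow(man))) {
      base <- sprintf("sub-%02d_%s_%s", man$subject[i], man$visit[i],
                      man$interval[i])
      paths[i] <- file.path(out_dir, paste0(base, ".nii.gz"))
      write_volume(sessions[[i]]$data, paths[i], geometry = phantom$geometry)
      write_motion(sessions[[i]]$motion, file.path(out_dir, paste0(base, "_motion.txt")))
    }
    man$path <- paths
    utils::write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(sessions = sessions, manifest = man)
}
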