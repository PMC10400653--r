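#' Preprocessing configuration
#'
#' Temporal-cleanup parameters: the retained frequency band, the spatial
#' smoothing kernel, and the head-motion quality threshold. The band must
#' sit inside the Nyquist interval for the session's repetition time.
#'
#' @param band_hz Length-2 numeric, retained band in Hz. Default
#'   `c(0.01, 0.1)`.
#' @param fwhm_mm Spatial smoothing FWHM in mm. Default 4.
#' @param fd_cutoff_mm Mean-FD threshold above which a session is flagged
#'   as high motion. Default 0.5.
#' @param fd_rotation_radius_mm Radius converting rotations to mm of
#'   displacement. Default 50.
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(band_hz = c(0.01, 0.1), fwhm_mm = 4,
                           fd_cutoff_mm = 0.5, fd_rotation_radius_mm = 50) {
  if (length(band_hz) != 2L || band_hz[1] <= 0 || band_hz[2] <= band_hz[1])
    stop("band_hz must satisfy 0 < low < high", call. = FALSE)
  structure(list(band_hz = band_hz, fwhm_mm = fwhm_mm,
                 fd_cutoff_mm = fd_cutoff_mm,
                 fd_rotation_radius_mm = fd_rotation_radius_mm),
            class = "preproc_config")
}

# time x voxels matrix view of the in-mask series
session_matrix <- function(session) {
  n <- dim(session$data)[4]
  flat <- matrix(session$data, ncol = n)      # voxels x time
  t(flat[session$mask$included, , drop = FALSE])
}

session_with_matrix <- function(session, X) {
  n <- nrow(X)
  flat <- matrix(0, nrow = prod(session$geometry$shape), ncol = n)
  flat[session$mask$included, ] <- t(X)
  session$data <- array(flat, dim = c(session$geometry$shape, n))
  session
}

#' Detrend and band-pass filter a session
#'
#' Removes each voxel's linear trend, then applies a zero-phase
#' frequency-domain filter retaining `band_hz` with hard band edges.
#' The two projections are alternated internally until mutually
#' consistent, so the whole operation is (near-)idempotent. Output voxel
#' means are ~0.
#'
#' @param session A `bold_session`.
#' @param config A [preproc_config()].
#' @return The filtered `bold_session`.
#' @export
detrend_bandpass <- function(session, config = preproc_config()) {
  n <- dim(session$data)[4]
  if (n < 16L) stop("need at least 16 volumes", call. = FALSE)
  nyq <- 1 / (2 * session$tr_s)
  if (config$band_hz[2] > nyq + 1e-12)
    stop(sprintf("band edge %.3g Hz outside Nyquist %.3g Hz",
                 config$band_hz[2], nyq), call. = FALSE)
  X <- session_matrix(session)
  tt <- seq_len(n)
  j <- seq_len(n) - 1
  freqs <- pmin(j, n - j) / (n * session$tr_s)  # exact conjugate symmetry
  # hard band edges: the filter F is an orthogonal projection in frequency
  # space (a taper would keep attenuating transition bins on repeats)
  gain <- as.numeric(freqs >= config$band_hz[1] & freqs <= config$band_hz[2])
  Fop <- function(M) Re(stats::mvfft(stats::mvfft(M) * gain, inverse = TRUE)) / n
  # exact projection onto (band-limited AND trend-free):
  #   P = F - F Q (Q' F Q)^{-1} Q' F,  Q an orthonormal basis of {1, ramp};
  # exactly idempotent, unlike detrend-then-filter applied once
  Q <- qr.Q(qr(cbind(1, tt - mean(tt))))
  FX <- Fop(X)
  FQ <- Fop(Q)
  # directions annihilated by F (e.g. DC) need no correction: F x is
  # already orthogonal to them
  live <- colSums(FQ^2) > 1e-12
  if (any(live)) {
    Qv <- Q[, live, drop = FALSE]; FQv <- FQ[, live, drop = FALSE]
    X <- FX - FQv %*% solve(crossprod(Qv, FQv), crossprod(Qv, FX))
  } else X <- FX
  session_with_matrix(session, X)
}

#' Regress nuisance signals out of a session
#'
#' Ordinary least squares of every voxel's series on the given regressors
#' (an intercept is always added); the voxel series are replaced by the
#' residuals, which are orthogonal to every regressor.
#'
#' @param session A `bold_session`.
#' @param regressors Numeric matrix, time x p (default: the session's own
#'   WM/CSF/global nuisance table).
#' @return The residualized `bold_session`.
#' @export
regress_nuisance <- function(session, regressors = session$nuisance) {
  X <- session_matrix(session)
  n <- nrow(X)
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != n)
    stop("regressor rows must equal volume count", call. = FALSE)
  if (ncol(regressors) >= n) stop("more regressors than time points", call. = FALSE)
  D <- cbind(`(intercept)` = 1, regressors)
  if (is.null(colnames(regressors)))
    colnames(D) <- c("(intercept)", paste0("reg", seq_len(ncol(regressors))))
  q <- qr(D)
  if (q$rank < ncol(D)) {
    bad <- colnames(D)[q$pivot[(q$rank + 1):ncol(D)]]
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X <- X - D %*% solve(crossprod(D), crossprod(D, X))
  session_with_matrix(session, X)
}

#' Framewise displacement from rigid-body motion parameters
#'
#' `FD(t) = sum |d translation_i| + radius * sum |d rotation_j|` over the
#' frame-to-frame differences of the six realignment parameters, with
#' `FD(1) = 0`. Sessions whose mean FD exceeds the cutoff are flagged.
#'
#' @param motion Numeric matrix, frames x 6 (3 translations mm, 3 rotations
#'   rad).
#' @param rotation_radius_mm Sphere radius converting rotation to mm.
#'   Default 50.
#' @param cutoff_mm Mean-FD flag threshold. Default 0.5.
#' @return List with `fd` (per-frame series), `mean_fd`, `flagged`.
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50,
                                   cutoff_mm = 0.5) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion table must have 6 columns", call. = FALSE)
  d <- abs(apply(motion, 2, diff))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, mean_fd = mean(fd), flagged = mean(fd) > cutoff_mm)
}

#' FD report for a set of sessions
#'
#' @param sessions List of `bold_session` objects.
#' @param config A [preproc_config()].
#' @return Tibble with `subject`, `visit`, `interval`, `mean_fd`, `flagged`.
#' @export
fd_report <- function(sessions, config = preproc_config()) {
  rows <- lapply(sessions, function(s) {
    r <- framewise_displacement(s$motion, config$fd_rotation_radius_mm,
                                config$fd_cutoff_mm)
    tibble::tibble(subject = s$subject, visit = s$visit, interval = s$interval,
                   mean_fd = r$mean_fd, flagged = r$flagged)
  })
  do.call(rbind, rows)
}

#' Full temporal preprocessing of a session
#'
#' Nuisance regression, then detrending and band-pass filtering, then
#' (optionally) spatial smoothing of each frame.
#'
#' @param session A `bold_session`.
#' @param config A [preproc_config()].
#' @param smooth Apply spatial smoothing at `config$fwhm_mm`? Default
#'   `FALSE` (the phantom needs no smoothing; enable for rough data).
#' @return The preprocessed `bold_session`.
#' @export
preprocess_session <- function(session, config = preproc_config(),
                               smooth = FALSE) {
  session <- regress_nuisance(session)
  session <- detrend_bandpass(session, config)
  if (smooth && config$fwhm_mm > 0) {
    session$data <- smooth_frames(session$data, session$mask, config$fwhm_mm)
  }
  session
}

# Mask-normalized Gaussian smoothing of every frame of a 4D series at once.
smooth_frames <- function(data, mask, fwhm_mm) {
  w <- array(as.numeric(mask$included), mask$geometry$shape)
  sig_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / mask$geometry$voxel_mm
  num <- data
  num[array(!mask$included, dim(data))] <- 0
  for (ax in 1:3) {
    k <- gauss_kernel_1d(sig_vox[ax])
    if (length(k) == 1L) next
    r <- (length(k) - 1L) / 2L
    acc <- array(0, dim(num))
    for (j in seq_along(k)) {
      off <- c(0L, 0L, 0L); off[ax] <- j - 1L - r
      acc <- acc + k[j] * shift_frames(num, off)
    }
    num <- acc
  }
  den <- separable_gauss(w, sig_vox)
  scale <- ifelse(den > 0, 1 / den, 0)
  out <- num * array(scale, dim(num))
  out[array(!mask$included, dim(out))] <- 0
  out
}

# Shift the first three axes of a 4D array, zero fill.
shift_frames <- function(a, off) {
  d <- dim(a)
  src <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax]) - off[ax]
    i[i < 1L | i > d[ax]] <- NA_integer_
    i
  })
  out <- array(0, d)
  ok1 <- !is.na(src[[1]]); ok2 <- !is.na(src[[2]]); ok3 <- !is.na(src[[3]])
  out[ok1, ok2, ok3, ] <- a[src[[1]][ok1], src[[2]][ok2], src[[3]][ok3], ,
                            drop = FALSE]
  out
}
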