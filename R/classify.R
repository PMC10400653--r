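#' Classifier configuration
#'
#' Linear support-vector machine settings for interval classification:
#' regularization `C = 1`, one-versus-one multiclass voting (ties broken by
#' summed decision values), leave-k-subject-out cross-validation, and
#' subject-level bootstrap for confidence intervals.
#'
#' @param C Soft-margin cost. Default 1.
#' @param leave_out Subjects held out per fold (1, 2 or 3). Default 1.
#' @param n_bootstrap Bootstrap resamples for accuracy CIs. Default 1000.
#' @param ci_level Confidence level. Default 0.95.
#' @param seed RNG seed governing fold order and bootstrap draws.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(C = 1, leave_out = 1L, n_bootstrap = 1000L,
                              ci_level = 0.95, seed = 1L) {
  stopifnot(C > 0, leave_out >= 1)
  structure(list(C = C, leave_out = as.integer(leave_out),
                 n_bootstrap = as.integer(n_bootstrap), ci_level = ci_level,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Sham-corrected map
#'
#' Voxelwise difference (real visit minus sham visit) of two maps of the
#' same subject and interval.
#'
#' @param real_map,sham_map [scalar_map()]s on the same geometry.
#' @return A [scalar_map()] of differences.
#' @export
sham_corrected_map <- function(real_map, sham_map) {
  if (!same_geometry(real_map$geometry, sham_map$geometry))
    stop("geometry mismatch between real and sham maps", call. = FALSE)
  scalar_map(real_map$mask,
             ifelse(real_map$mask$included,
                    real_map$values - sham_map$values, 0))
}

#' Sham-corrected maps for a whole map store
#'
#' @param store A `map_store` as returned by the parcellation stage of
#'   [run_pipeline()]: nested list `store[[kind]][[visit]][[subject]][[interval]]`
#'   of [scalar_map()]s.
#' @param kind `"node_density"` or `"boundary_gradient"`.
#' @return Nested list `corrected[[subject]][[interval]]` of maps.
#' @export
sham_corrected_maps <- function(store, kind) {
  real <- store[[kind]][["real"]]
  sham <- store[[kind]][["sham"]]
  if (is.null(real) || is.null(sham)) stop("missing visit in map store", call. = FALSE)
  lapply(seq_along(real), function(s) {
    stats::setNames(lapply(names(real[[s]]), function(iv) {
      if (is.null(real[[s]][[iv]]) || is.null(sham[[s]][[iv]]))
        stop("missing session map: subject ", s, " interval ", iv, call. = FALSE)
      sham_corrected_map(real[[s]][[iv]], sham[[s]][[iv]])
    }), names(real[[s]]))
  })
}

#' Extract an SVM feature table from sham-corrected maps
#'
#' @param corrected Nested list `corrected[[subject]][[interval]]` of
#'   [scalar_map()]s (from [sham_corrected_maps()]).
#' @param mask A `feature_mask`.
#' @param intervals Interval labels to include (default: all found).
#' @return List with `features` (rows = subject x interval, columns = mask
#'   voxels in linear-index order), `labels` (interval factor), `groups`
#'   (subject ids), `meta` (tibble).
#' @export
extract_features <- function(corrected, mask, intervals = NULL) {
  if (!length(mask$voxels)) stop("empty feature mask", call. = FALSE)
  if (is.null(intervals)) intervals <- names(corrected[[1]])
  rows <- list(); labels <- character(0); groups <- integer(0)
  for (s in seq_along(corrected)) {
    for (iv in intervals) {
      m <- corrected[[s]][[iv]]
      if (is.null(m)) stop("missing map: subject ", s, " interval ", iv,
                           call. = FALSE)
      rows[[length(rows) + 1L]] <- m$values[mask$voxels]
      labels <- c(labels, iv)
      groups <- c(groups, s)
    }
  }
  features <- do.call(rbind, rows)
  colnames(features) <- paste0("v", mask$voxels)
  list(features = features, labels = factor(labels, levels = intervals),
       groups = groups,
       meta = tibble::tibble(subject = groups, interval = labels))
}

# Partition unique groups into folds of ~leave_out groups each, in an order
# drawn from the config seed.
make_folds <- function(groups, leave_out, seed) {
  gu <- unique(groups)
  set.seed(seed)
  gu <- sample(gu)
  n_folds <- max(1L, floor(length(gu) / leave_out))
  split(gu, rep(seq_len(n_folds), length.out = length(gu)))
}

# Standardize train/test with training statistics only.
standardize_fold <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

# One-vs-one multiclass linear SVM: fit all pairs, predict by voting with
# ties broken by summed decision values.
ovo_fit_predict <- function(Xtr, ytr, Xte, C) {
  lev <- levels(droplevels(ytr))
  if (length(lev) < 2L) stop("need at least two classes in training data",
                             call. = FALSE)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  votes <- matrix(0, nrow(Xte), length(lev), dimnames = list(NULL, lev))
  dsums <- matrix(0, nrow(Xte), length(lev), dimnames = list(NULL, lev))
  for (p in pairs) {
    sel <- ytr %in% p
    fit <- e1071::svm(Xtr[sel, , drop = FALSE], droplevels(ytr[sel]),
                      kernel = "linear", cost = C, scale = FALSE)
    pr <- stats::predict(fit, Xte, decision.values = TRUE)
    dv <- attr(pr, "decision.values")[, 1]
    pos <- colnames(attr(pr, "decision.values"))  # "A/B": dv > 0 -> A
    ab <- strsplit(pos, "/")[[1]]
    winner <- ifelse(dv > 0, ab[1], ab[2])
    for (cls in p) {
      votes[, cls] <- votes[, cls] + (winner == cls)
      sgn <- if (cls == ab[1]) 1 else -1
      dsums[, cls] <- dsums[, cls] + sgn * dv
    }
  }
  vapply(seq_len(nrow(Xte)), function(i) {
    v <- votes[i, ]
    top <- which(v == max(v))
    if (length(top) > 1L) top <- top[which.max(dsums[i, top])]
    lev[top]
  }, character(1))
}

#' Group cross-validated accuracy
#'
#' Leave-k-subject-out cross-validation: folds partition subjects, all rows
#' of a held-out subject are tested together, and features are standardized
#' per fold using training statistics only. Multiclass prediction is
#' one-vs-one voting.
#'
#' @param features Numeric matrix (rows = observations).
#' @param labels Factor of class labels.
#' @param groups Subject id per row.
#' @param config A [classifier_config()].
#' @return List with `accuracy` (pooled over all test rows), `fold_accuracy`,
#'   `predictions`.
#' @export
cv_accuracy <- function(features, labels, groups, config = classifier_config()) {
  folds <- make_folds(groups, config$leave_out, config$seed)
  preds <- rep(NA_character_, length(labels))
  fold_acc <- numeric(length(folds))
  for (f in seq_along(folds)) {
    test_rows <- groups %in% folds[[f]]
    ytr <- droplevels(labels[!test_rows])
    if (length(unique(ytr)) < length(levels(droplevels(labels))))
      stop("a class is absent from a training fold", call. = FALSE)
    sf <- standardize_fold(features[!test_rows, , drop = FALSE],
                           features[test_rows, , drop = FALSE])
    preds[test_rows] <- ovo_fit_predict(sf$train, ytr, sf$test, config$C)
    fold_acc[f] <- mean(preds[test_rows] == as.character(labels[test_rows]))
  }
  list(accuracy = mean(preds == as.character(labels)),
       fold_accuracy = fold_acc, predictions = preds)
}

# Bootstrap CV accuracies: resample subjects with replacement; duplicate
# subjects remain grouped (each copy is its own CV group).
bootstrap_accuracies <- function(features, labels, groups, config) {
  gu <- unique(groups)
  accs <- numeric(config$n_bootstrap)
  for (b in seq_len(config$n_bootstrap)) {
    set.seed(config$seed + 7919L * b)
    draw <- sample(gu, length(gu), replace = TRUE)
    rows <- integer(0); g2 <- integer(0)
    for (i in seq_along(draw)) {
      r <- which(groups == draw[i])
      rows <- c(rows, r)
      g2 <- c(g2, rep(i, length(r)))
    }
    cfg <- config
    cfg$seed <- config$seed + b
    accs[b] <- tryCatch(
      cv_accuracy(features[rows, , drop = FALSE], labels[rows], g2,
                  cfg)$accuracy,
      error = function(e) NA_real_)
  }
  accs
}

bootstrap_ci <- function(features, labels, groups, config) {
  if (config$n_bootstrap < 1L) return(c(NA_real_, NA_real_))
  accs <- bootstrap_accuracies(features, labels, groups, config)
  a <- (1 - config$ci_level) / 2
  stats::quantile(accs, c(a, 1 - a), na.rm = TRUE, names = FALSE)
}

#' Accuracy curve over a mask-threshold sweep
#'
#' For every threshold of the grid matching `kind`, rebuilds the feature
#' mask, re-extracts features and reruns the full group CV from scratch;
#' optionally adds subject-level bootstrap confidence intervals. Reports
#' the global maximum of the mean-accuracy curve.
#'
#' @param corrected Sham-corrected maps (see [sham_corrected_maps()]).
#' @param components A `component_set` for mask construction.
#' @param kind `"node"` (percentile-overlay mask) or `"boundary"`
#'   (watershed mask).
#' @param config A [classifier_config()].
#' @param mask_cfg A [mask_config()].
#' @param intervals Label subset (default all).
#' @param bootstrap Compute CIs? Default TRUE.
#' @return An `accuracy_curve`: tibble with `threshold`, `n_voxels`,
#'   `accuracy`, `ci_low`, `ci_high`; attributes `best` (row index of the
#'   global maximum), `best_mask`, `chance`.
#' @export
threshold_sweep <- function(corrected, components, kind = c("node", "boundary"),
                            config = classifier_config(),
                            mask_cfg = mask_config(), intervals = NULL,
                            bootstrap = TRUE) {
  kind <- match.arg(kind)
  grid <- if (kind == "node") mask_cfg$node_grid else mask_cfg$watershed_grid
  rows <- list(); masks <- list()
  for (i in seq_along(grid)) {
    thr <- grid[i]
    fm <- if (kind == "node") node_mask_from_ics(components, thr)
          else boundary_mask_watershed(components, thr, mask_cfg)
    if (!length(fm$voxels)) {
      rows[[i]] <- tibble::tibble(threshold = thr, n_voxels = 0L,
                                  accuracy = NA_real_, ci_low = NA_real_,
                                  ci_high = NA_real_)
      masks[[i]] <- fm
      next
    }
    fx <- extract_features(corrected, fm, intervals)
    acc <- cv_accuracy(fx$features, fx$labels, fx$groups, config)$accuracy
    if (bootstrap && config$n_bootstrap >= 1L) {
      ba <- bootstrap_accuracies(fx$features, fx$labels, fx$groups, config)
      a <- (1 - config$ci_level) / 2
      ci <- stats::quantile(ba, c(a, 1 - a), na.rm = TRUE, names = FALSE)
      bmean <- mean(ba, na.rm = TRUE)
    } else {
      ci <- c(NA_real_, NA_real_)
      bmean <- NA_real_
    }
    rows[[i]] <- tibble::tibble(threshold = thr,
                                n_voxels = length(fm$voxels),
                                accuracy = acc, boot_mean = bmean,
                                ci_low = ci[1], ci_high = ci[2])
    masks[[i]] <- fm
  }
  curve <- do.call(rbind, rows)
  if (all(is.na(curve$accuracy))) stop("all thresholds gave empty masks",
                                       call. = FALSE)
  # the reported best is the global maximum of the mean-across-bootstraps
  # accuracy curve when bootstrapping, else of the point-estimate curve;
  # exact ties go to the most inclusive (largest-voxel-set) mask, i.e. the
  # full extent of voxels consistent with the maximal accuracy
  score <- if (bootstrap && !all(is.na(curve$boot_mean))) curve$boot_mean
           else curve$accuracy
  best <- which(score == max(score, na.rm = TRUE))
  best <- best[which.max(curve$n_voxels[best])]
  structure(curve,
            class = c("accuracy_curve", class(curve)),
            best = best, best_mask = masks[[best]],
            chance = 1 / length(levels(droplevels(
              factor(if (is.null(intervals)) names(corrected[[1]])
                     else intervals)))))
}

#' Pairwise interval classification
#'
#' Binary group-CV classification of one interval pair: pooled accuracy,
#' ROC AUC from decision values pooled over folds, and the mean signed
#' voxel-weight vector across folds mapped back to a volume.
#'
#' @param corrected Sham-corrected maps.
#' @param mask A `feature_mask`.
#' @param pair Character vector of two interval labels.
#' @param config A [classifier_config()].
#' @return A `classification_result`: list with `pair`, `accuracy`,
#'   `ci` (if bootstrapped), `auc`, `weight_map` ([scalar_map()]),
#'   `n_voxels`.
#' @export
pairwise_classify <- function(corrected, mask, pair,
                              config = classifier_config(),
                              bootstrap = FALSE) {
  stopifnot(length(pair) == 2L)
  fx <- extract_features(corrected, mask, intervals = pair)
  y <- droplevels(fx$labels)
  folds <- make_folds(fx$groups, config$leave_out, config$seed)
  preds <- rep(NA_character_, length(y))
  dvals <- rep(NA_real_, length(y))
  wsum <- numeric(ncol(fx$features))
  for (f in seq_along(folds)) {
    te <- fx$groups %in% folds[[f]]
    sf <- standardize_fold(fx$features[!te, , drop = FALSE],
                           fx$features[te, , drop = FALSE])
    fit <- e1071::svm(sf$train, droplevels(y[!te]), kernel = "linear",
                      cost = config$C, scale = FALSE)
    pr <- stats::predict(fit, sf$test, decision.values = TRUE)
    dv <- attr(pr, "decision.values")[, 1]
    ab <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]]
    # orient decision values so positive means the SECOND label of `pair`
    sgn <- if (ab[1] == pair[2]) 1 else -1
    preds[te] <- as.character(pr)
    dvals[te] <- sgn * dv
    w <- crossprod(fit$coefs, fit$SV)[1, ]
    wsum <- wsum + sgn * w
  }
  acc <- mean(preds == as.character(y))
  auc <- pooled_auc(dvals, y == pair[2])
  wmean <- wsum / length(folds)
  wmap <- scalar_map(mask$mask,
                     replace(rep(0, prod(mask$mask$geometry$shape)),
                             mask$voxels, wmean)[
                               which(mask$mask$included)])
  ci <- if (bootstrap) bootstrap_ci(fx$features, y, fx$groups, config)
        else c(NA_real_, NA_real_)
  structure(list(pair = pair, accuracy = acc, ci = ci, auc = auc,
                 weight_map = wmap, n_voxels = length(mask$voxels)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s vs %s: accuracy %.3f, AUC %.3f (%d voxels)\n",
              x$pair[1], x$pair[2], x$accuracy, x$auc, x$n_voxels))
  invisible(x)
}

# Rank-based AUC of decision values against a binary truth.
pooled_auc <- function(scores, positive) {
  ok <- !is.na(scores)
  scores <- scores[ok]; positive <- positive[ok]
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Head-motion control classification
#'
#' Pairwise interval classification using each session's mean framewise
#' displacement as the only feature, for real, sham and real-minus-sham
#' conditions. With condition-independent motion this sits at chance,
#' confirming that map-based classification is not driven by motion.
#'
#' @param sessions List of `bold_session`s (the full crossover study).
#' @param config A [classifier_config()].
#' @param rotation_radius_mm FD rotation radius. Default 50.
#' @return Tibble: `condition`, `pair`, `accuracy`.
#' @export
motion_control <- function(sessions, config = classifier_config(),
                           rotation_radius_mm = 50) {
  fd <- fd_report(sessions,
                  preproc_config(fd_rotation_radius_mm = rotation_radius_mm))
  fd <- fd[fd$visit %in% c("real", "sham"), ]
  intervals <- sort(unique(fd$interval))
  conds <- list(
    real = function(s, iv) fd$mean_fd[fd$subject == s & fd$visit == "real" &
                                        fd$interval == iv],
    sham = function(s, iv) fd$mean_fd[fd$subject == s & fd$visit == "sham" &
                                        fd$interval == iv],
    `real-sham` = function(s, iv)
      fd$mean_fd[fd$subject == s & fd$visit == "real" & fd$interval == iv] -
      fd$mean_fd[fd$subject == s & fd$visit == "sham" & fd$interval == iv])
  subjects <- sort(unique(fd$subject))
  out <- list()
  for (cn in names(conds)) {
    X <- outer(subjects, intervals,
               Vectorize(function(s, iv) conds[[cn]](s, iv)))
    for (p in utils::combn(intervals, 2, simplify = FALSE)) {
      i1 <- match(p[1], intervals); i2 <- match(p[2], intervals)
      feats <- matrix(c(X[, i1], X[, i2]), ncol = 1)
      labels <- factor(rep(p, each = length(subjects)), levels = p)
      groups <- rep(subjects, 2)
      acc <- cv_accuracy(feats, labels, groups, config)$accuracy
      out[[length(out) + 1L]] <- tibble::tibble(
        condition = cn, pair = paste(p, collapse = " vs "), accuracy = acc)
    }
  }
  do.call(rbind, out)
}
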