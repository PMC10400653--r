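# Small synthetic feature problems exercise the CV/SVM machinery directly.

make_problem <- function(n_subj = 8, classes = c("R0", "R1"), m = 6,
                         effect = 2, seed = 1) {
  set.seed(seed)
  rows <- n_subj * length(classes)
  X <- matrix(rnorm(rows * m), rows, m)
  labels <- factor(rep(classes, times = n_subj), levels = classes)
  groups <- rep(seq_len(n_subj), each = length(classes))
  for (k in seq_along(classes))
    X[labels == classes[k], 1:2] <- X[labels == classes[k], 1:2] + effect * k
  list(X = X, labels = labels, groups = groups)
}

test_that("perfectly separable features give accuracy 1 and AUC 1", {
  p <- make_problem(effect = 10)
  cfg <- classifier_config(seed = 3)
  r <- cv_accuracy(p$X, p$labels, p$groups, cfg)
  expect_equal(r$accuracy, 1)
  expect_true(all(r$fold_accuracy == 1))
  # every subject appears in exactly one test fold at leave-one-out
  folds <- nodebound:::make_folds(p$groups, 1, cfg$seed)
  expect_setequal(unlist(folds), unique(p$groups))
  expect_length(folds, length(unique(p$groups)))
})

test_that("shuffled labels classify at chance within binomial noise", {
  set.seed(42)
  accs <- replicate(10, {
    p <- make_problem(n_subj = 10, classes = c("R0", "R1"), effect = 3,
                      seed = sample.int(1e6, 1))
    # decouple labels from rows: features no longer predict the label
    perm <- sample(length(p$labels))
    cv_accuracy(p$X[perm, ], p$labels, p$groups[perm],
                classifier_config(seed = 7))$accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("four classes give six pairs and multiclass ties resolve by decision sums", {
  p <- make_problem(n_subj = 6, classes = c("R0", "R1", "R2", "R3"),
                    effect = 6, seed = 9)
  cfg <- classifier_config(seed = 5)
  r <- cv_accuracy(p$X, p$labels, p$groups, cfg)
  expect_gt(r$accuracy, 0.9)
  expect_length(utils::combn(levels(p$labels), 2, simplify = FALSE), 6)
  # a class missing from training errors out
  bad <- p$labels
  bad[p$groups != 1] <- "R0"
  expect_error(cv_accuracy(p$X, factor(bad, levels = levels(p$labels)),
                           p$groups, cfg), "absent")
})

test_that("bootstrap CI brackets the mean and shrinks with more subjects", {
  accs <- lapply(c(8, 16), function(ns) {
    p <- make_problem(n_subj = ns, effect = 1.2, seed = 11)
    cfg <- classifier_config(seed = 2, n_bootstrap = 60)
    ci <- nodebound:::bootstrap_ci(p$X, p$labels, p$groups, cfg)
    acc <- cv_accuracy(p$X, p$labels, p$groups, cfg)$accuracy
    list(ci = ci, acc = acc)
  })
  for (a in accs) {
    expect_lte(a$ci[1], a$ci[2])
  }
  w1 <- diff(accs[[1]]$ci); w2 <- diff(accs[[2]]$ci)
  expect_lt(w2, w1 + 0.05)
})

test_that("sham correction subtracts voxelwise and checks geometry", {
  g <- volume_geometry(c(4, 4, 4), 3)
  m <- brain_mask(g, array(TRUE, c(4, 4, 4)))
  set.seed(1)
  a <- scalar_map(m, array(rnorm(64), c(4, 4, 4)))
  b <- scalar_map(m, array(rnorm(64), c(4, 4, 4)))
  d <- sham_corrected_map(a, b)
  expect_equal(map_values(d), map_values(a) - map_values(b))
  expect_true(all(map_values(sham_corrected_map(a, a)) == 0))
  c_shift <- scalar_map(m, a$values + 3)
  expect_true(all(abs(map_values(sham_corrected_map(c_shift, a)) - 3) < 1e-12))
  g2 <- volume_geometry(c(4, 4, 4), 2)
  m2 <- brain_mask(g2, array(TRUE, c(4, 4, 4)))
  expect_error(sham_corrected_map(a, scalar_map(m2, array(0, c(4, 4, 4)))),
               "geometry")
})

test_that("extract_features lays out masks in linear-index order", {
  g <- volume_geometry(c(4, 4, 2), 3)
  m <- brain_mask(g, array(TRUE, c(4, 4, 2)))
  set.seed(2)
  corrected <- lapply(1:3, function(s) {
    list(R0 = scalar_map(m, array(rnorm(32), c(4, 4, 2))),
         R1 = scalar_map(m, array(rnorm(32), c(4, 4, 2))))
  })
  fm <- structure(list(kind = "node", threshold = 50,
                       voxels = c(3L, 10L, 17L), mask = m),
                  class = "feature_mask")
  fx <- extract_features(corrected, fm)
  expect_equal(dim(fx$features), c(6L, 3L))
  expect_equal(unname(fx$features[1, 2]), corrected[[1]]$R0$values[10])
  expect_equal(unname(fx$features[4, 3]), corrected[[2]]$R1$values[17])
  expect_equal(as.character(fx$labels), rep(c("R0", "R1"), 3))
  expect_equal(fx$groups, rep(1:3, each = 2))
  expect_error(extract_features(corrected, structure(list(voxels = integer(0)),
                                                     class = "feature_mask")),
               "empty")
})

test_that("pairwise classification: separation, AUC, weight antisymmetry", {
  g <- volume_geometry(c(4, 4, 2), 3)
  m <- brain_mask(g, array(TRUE, c(4, 4, 2)))
  set.seed(3)
  corrected <- lapply(1:8, function(s) {
    base <- array(rnorm(32, sd = 0.1), c(4, 4, 2))
    r1 <- base
    r1[1:2, 1, 1] <- r1[1:2, 1, 1] + 5     # strong separable shift
    list(R0 = scalar_map(m, base), R1 = scalar_map(m, r1))
  })
  fm <- structure(list(kind = "node", threshold = 50,
                       voxels = 1:6, mask = m), class = "feature_mask")
  cfg <- classifier_config(seed = 4)
  r01 <- pairwise_classify(corrected, fm, c("R0", "R1"), cfg)
  expect_equal(r01$accuracy, 1)
  expect_equal(r01$auc, 1)
  r10 <- pairwise_classify(corrected, fm, c("R1", "R0"), cfg)
  expect_equal(map_values(r10$weight_map), -map_values(r01$weight_map),
               tolerance = 0.01)   # solver tolerance limits exactness
  # the informative voxels carry the largest |weights|
  w <- r01$weight_map$values[fm$voxels]
  expect_true(all(abs(w[1:2]) > abs(w[3:6])))
})

test_that("motion control uses one feature and stays at chance for null motion", {
  geom <- volume_geometry(c(8, 8, 8), 3)
  ph <- make_phantom(geom, K = 2, seed = 5)
  des <- study_design(n_subjects = 8, n_volumes = 24)
  st <- make_study(ph, des, seed = 33, ica_visit = FALSE)
  tab <- motion_control(st$sessions, classifier_config(seed = 6))
  expect_equal(nrow(tab), 3 * 6)          # 3 conditions x 6 interval pairs
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  # condition-independent motion: mean accuracy near 0.5
  expect_lt(abs(mean(tab$accuracy) - 0.5), 0.15)

  # motion coupled to one interval becomes detectable
  st2 <- st
  for (i in seq_along(st2$sessions)) {
    s <- st2$sessions[[i]]
    if (s$interval == "R1") {
      s$motion <- s$motion + cumsum(rep(0.08, nrow(s$motion))) %o% rep(1, 6)
      st2$sessions[[i]] <- s
    }
  }
  tab2 <- motion_control(st2$sessions, classifier_config(seed = 6))
  r1rows <- grepl("R1", tab2$pair) & tab2$condition == "real"
  expect_gt(mean(tab2$accuracy[r1rows]), 0.7)
})
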