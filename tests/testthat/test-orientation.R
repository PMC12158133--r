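test_that("orientation features have the fixed 12-slot layout", {
  f <- pose_to_frame(pose_state(), noise_sd = 0)
  feats <- extract_orientation_features(f)
  expect_length(feats, 12)
  expect_named(feats, c("ls_x", "ls_y", "rs_x", "rs_y", "lh_x", "lh_y",
                        "rh_x", "rh_y", "bb_cx", "bb_cy", "bb_w", "bb_h"))
  # symmetric frontal frame: shoulder ys equal, xs symmetric about bbox cx
  expect_equal(feats["ls_y"], feats["rs_y"], ignore_attr = TRUE)
  expect_equal((feats["ls_x"] + feats["rs_x"]) / 2, feats["bb_cx"],
               ignore_attr = TRUE, tolerance = 1e-9)
  # profile frame: shoulders project to the same x
  fp <- pose_to_frame(pose_state(yaw_deg = 90), noise_sd = 0)
  fe <- extract_orientation_features(fp)
  expect_lt(abs(fe["ls_x"] - fe["rs_x"]), 1e-6)
  # missing keypoint is a named error
  bad <- frame_with(list(left_shoulder = c(0.4, 0.3)))
  expect_error(extract_orientation_features(bad), "right_shoulder")
})

test_that("stratified split is exact, disjoint and seed-stable", {
  labels <- factor(rep(c("Frontal", "Turned", "Profile"), c(40, 30, 30)))
  sp <- split_dataset(labels, seed = 42)
  expect_length(sp$test, 20)
  expect_length(sp$train, 80)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  # per-class test counts within one of 20%
  for (l in levels(labels)) {
    n_l <- sum(labels == l)
    expect_lte(abs(sum(labels[sp$test] == l) - 0.2 * n_l), 1)
  }
  expect_identical(split_dataset(labels, seed = 42), sp)
  expect_false(identical(split_dataset(labels, seed = 43)$test, sp$test))
  expect_error(split_dataset(factor(c("a", "b", "b"))), "at least 2")
})

test_that("standardizer centers and scales with training statistics only", {
  # two-point case: mean 1, population sd 1, transformed {-1, +1}
  expect_equal(as.vector(apply_standardizer(fit_standardizer(matrix(c(0, 2))),
                                            matrix(c(0, 2)))),
               c(-1, 1))
  set.seed(61)
  X <- matrix(rnorm(200, 5, 3), 50)
  s <- fit_standardizer(X)
  Z <- apply_standardizer(s, X)
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  expect_true(all(abs(colMeans(Z^2) - 1) < 1e-9))  # unit population variance
  # leakage: transforming other data never changes the standardizer
  before <- s
  invisible(apply_standardizer(s, matrix(rnorm(40), 10)))
  expect_identical(s, before)
  # constant features drop with a warning
  Xc <- cbind(X, 7)
  expect_warning(sc <- fit_standardizer(Xc), "constant")
  expect_equal(ncol(apply_standardizer(sc, Xc)), 4)
})

test_that("PCA reduction is orthogonal with non-increasing variance", {
  set.seed(71)
  X <- matrix(rnorm(300), 50) %*% diag(c(3, 2, 1, 0.5, 0.2, 0.1))
  r <- reduce_dimensionality(X, n_components = 3)
  G <- crossprod(r$rotation)
  expect_equal(G, diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(diff(r$sdev) <= 1e-12))
  # eigen-decomposition oracle for the explained variances
  ev <- sort(eigen(cov(X), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(r$sdev^2, ev, tolerance = 1e-9)
  # full basis reconstructs exactly
  rf <- reduce_dimensionality(X, n_components = 6)
  Xrec <- rf$scores %*% t(rf$rotation) + matrix(rf$center, 50, 6, byrow = TRUE)
  expect_equal(Xrec, X, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(reduce_dimensionality(X, 7), "exceeds")
})

test_that("training pipeline is deterministic and leak-free", {
  ds <- generate_orientation_dataset(180, config = default_config(), seed = 81)
  X <- orientation_feature_matrix(ds$frames)
  sp <- split_dataset(ds$labels, seed = 81)
  r1 <- train_and_compare(X, ds$labels, sp, algorithms = c("DT", "NB", "SVM"), seed = 81)
  r2 <- train_and_compare(X, ds$labels, sp, algorithms = c("DT", "NB", "SVM"), seed = 81)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$selected, r2$selected)
  # standardizer depends on the training partition only
  mu_expected <- colMeans(X[sp$train, ])
  expect_equal(r1$standardizer$mean, mu_expected, tolerance = 1e-12)
})

test_that("permuted labels drive every classifier to chance", {
  ds <- generate_orientation_dataset(300, config = default_config(), seed = 91)
  X <- orientation_feature_matrix(ds$frames)
  set.seed(91)
  perm <- factor(sample(as.character(ds$labels)), levels = orientation_labels())
  sp <- split_dataset(perm, seed = 91)
  rep <- train_and_compare(X, perm, sp, seed = 91)
  # binomial 99.9% interval around 1/3 for the 60-sample test set (the
  # wider level keeps the six correlated per-classifier checks jointly safe)
  half <- 3.29 * sqrt((1 / 3) * (2 / 3) / length(sp$test))
  for (alg in names(rep$accuracy)) {
    expect_gt(rep$accuracy[alg], 1 / 3 - half - 1e-9)
    expect_lt(rep$accuracy[alg], 1 / 3 + half + 1e-9)
  }
})

test_that("ties select the first algorithm in canonical order", {
  # zero-noise data: DT and RF (and others) all reach accuracy 1.0
  ds <- generate_orientation_dataset(150, config = default_config(noise_sd = 0),
                                     seed = 101)
  X <- orientation_feature_matrix(ds$frames)
  sp <- split_dataset(ds$labels, seed = 101)
  rep <- suppressWarnings(
    train_and_compare(X, ds$labels, sp, algorithms = c("DT", "RF"), seed = 101)
  )
  expect_equal(unname(rep$accuracy["DT"]), unname(rep$accuracy["RF"]))
  expect_identical(rep$selected, "DT")
})

test_that("fitted reports predict orientation deterministically", {
  ds <- generate_orientation_dataset(180, config = default_config(), seed = 111)
  X <- orientation_feature_matrix(ds$frames)
  sp <- split_dataset(ds$labels, seed = 111)
  rep <- train_and_compare(X, ds$labels, sp, algorithms = c("DT", "SVM"), seed = 111)
  frontal <- pose_to_frame(pose_state(yaw_deg = 5), noise_sd = 0)
  profile <- pose_to_frame(pose_state(yaw_deg = 88), noise_sd = 0)
  expect_identical(predict_orientation(rep, frontal), "Frontal")
  expect_identical(predict_orientation(rep, profile), "Profile")
  expect_identical(predict_orientation(rep, frontal), predict_orientation(rep, frontal))
  # majority vote over a sequence
  seq <- generate_sequence(trajectory_spec(list(yaw_deg = 80), duration_ms = 400, fps = 25),
                           noise_sd = 0.01, seed = 111)$sequence
  expect_identical(sequence_orientation(rep, seq), "Profile")
  expect_error(predict_orientation(list(), frontal), "fitted")
})
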