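#' Extract orientation features from a frame
#'
#' The 12-number feature vector feeding the orientation classifiers:
#' left/right shoulder (x, y), left/right hip (x, y), and the person
#' bounding box (cx, cy, w, h), in that fixed order. With
#' `bbox_frame = TRUE` the keypoint coordinates are re-expressed relative
#' to the bounding box before extraction.
#'
#' @param frame A [keypoint_frame()]; shoulders and hips must be visible.
#' @param bbox_frame Express keypoints in the bbox frame (off by default).
#' @return Named numeric vector of length 12.
#' @export
extract_orientation_features <- function(frame, bbox_frame = FALSE) {
  need <- c("left_shoulder", "right_shoulder", "left_hip", "right_hip")
  for (nm in need) {
    if (frame$kpts[nm, "v"] == 0) {
      stop("required keypoint not visible: ", nm, call. = FALSE)
    }
  }
  pts <- frame$kpts[need, c("x", "y")]
  if (bbox_frame) {
    pts[, "x"] <- (pts[, "x"] - (frame$bbox[1] - frame$bbox[3] / 2)) / max(frame$bbox[3], 1e-9)
    pts[, "y"] <- (pts[, "y"] - (frame$bbox[2] - frame$bbox[4] / 2)) / max(frame$bbox[4], 1e-9)
  }
  stats::setNames(
    c(t(pts), frame$bbox),
    c("ls_x", "ls_y", "rs_x", "rs_y", "lh_x", "lh_y", "rh_x", "rh_y",
      "bb_cx", "bb_cy", "bb_w", "bb_h")
  )
}

#' Feature matrix for a set of frames
#'
#' @param frames List of [keypoint_frame()] objects.
#' @inheritParams extract_orientation_features
#' @return Numeric matrix, one row per frame.
#' @export
orientation_feature_matrix <- function(frames, bbox_frame = FALSE) {
  t(vapply(frames, extract_orientation_features, numeric(12), bbox_frame = bbox_frame))
}

#' Stratified train/test split
#'
#' Random, seed-reproducible split holding out `test_fraction` of the data,
#' stratified by class so per-class test proportions stay within one sample
#' of the requested fraction.
#'
#' @param labels Factor of class labels, one per sample.
#' @param test_fraction Fraction held out (default 0.2).
#' @param seed Integer seed; identical seed, identical split.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(labels, test_fraction = 0.2, seed = 42L) {
  labels <- factor(labels)
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("every class needs at least 2 samples; short classes: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  test <- integer(0)
  for (l in levels(labels)) {
    idx <- which(labels == l)
    n_test <- round(length(idx) * test_fraction)
    n_test <- min(max(n_test, 1L), length(idx) - 1L)
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Feature standardizer
#'
#' Learns per-feature mean and standard deviation from the training set and
#' re-expresses features as z-scores. The population standard deviation
#' (denominator n) is used, so the transformed training set has exactly
#' zero mean and unit population variance per feature. Constant features
#' (sd = 0) are dropped with a warning. Applying the standardizer to
#' held-out data uses the training statistics only.
#'
#' @param X Training feature matrix.
#' @return Object of class `standardizer`.
#' @export
fit_standardizer <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 training samples", call. = FALSE)
  mu <- colMeans(X)
  sd <- sqrt(colMeans(sweep(X, 2, mu)^2))
  keep <- sd > 0
  if (!all(keep)) {
    warning("dropping constant features: ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
  }
  structure(list(mean = mu[keep], sd = sd[keep], keep = which(keep)),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param s A fitted `standardizer`.
#' @param newdata Feature matrix (or single feature vector) to transform.
#' @export
apply_standardizer <- function(s, newdata) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1,
                                         dimnames = list(NULL, names(newdata)))
       else as.matrix(newdata)
  X <- X[, s$keep, drop = FALSE]
  sweep(sweep(X, 2, s$mean), 2, s$sd, "/")
}

#' Principal-component reduction (optional, off by default)
#'
#' Variance-ordered orthogonal projection of the features. Provided for
#' parity with the full pipeline but disabled by default, since it degraded
#' orientation accuracy.
#'
#' @param X Feature matrix (should be standardized first).
#' @param n_components Number of components to keep.
#' @return List with `scores`, `rotation`, `center`, `sdev`.
#' @export
reduce_dimensionality <- function(X, n_components = 3) {
  X <- as.matrix(X)
  if (n_components > ncol(X)) stop("n_components exceeds feature count", call. = FALSE)
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       rotation = p$rotation[, seq_len(n_components), drop = FALSE],
       center = p$center, sdev = p$sdev)
}

.canonical_algorithms <- c("LR", "DT", "RF", "NB", "KNN", "SVM")
.scaled_algorithms <- c("LR", "KNN", "SVM")

#' Train and compare the orientation classifiers
#'
#' Fits the six standard classifiers (logistic regression LR, decision tree
#' DT, random forest RF, naive Bayes NB, k-nearest neighbours KNN, support
#' vector machine SVM) on the training partition, evaluates accuracy on the
#' untouched test partition, and selects the best performer. Scale-sensitive
#' algorithms (LR, KNN, SVM) receive features standardized with
#' training-set statistics; tree-based models and NB get raw features.
#' Ties in accuracy resolve toward the first algorithm in the canonical
#' order LR, DT, RF, NB, KNN, SVM. An algorithm that errors is recorded
#' with accuracy `NaN` and excluded from selection.
#'
#' @param X Feature matrix for all samples.
#' @param labels Factor of orientation labels.
#' @param split A [split_dataset()] result.
#' @param algorithms Subset of the canonical algorithm names.
#' @param seed Seed for the stochastic fits (random forest).
#' @return Object of class `classifier_report`: per-algorithm accuracy,
#'   the selected algorithm, fitted models and the standardizer.
#' @export
train_and_compare <- function(X, labels, split,
                              algorithms = .canonical_algorithms, seed = 42L) {
  algorithms <- match.arg(algorithms, .canonical_algorithms, several.ok = TRUE)
  algorithms <- .canonical_algorithms[.canonical_algorithms %in% algorithms]
  X <- as.matrix(X)
  labels <- factor(labels)
  Xtr <- X[split$train, , drop = FALSE]; ytr <- droplevels(labels[split$train])
  Xte <- X[split$test, , drop = FALSE]; yte <- labels[split$test]
  std <- fit_standardizer(Xtr)
  Xtr_s <- apply_standardizer(std, Xtr)
  Xte_s <- apply_standardizer(std, Xte)
  fitters <- list(
    LR = function() .fit_lr(Xtr_s, ytr),
    DT = function() fit_cart(Xtr, ytr),
    RF = function() fit_random_forest(Xtr, ytr),
    NB = function() fit_gaussian_nb(Xtr, ytr),
    KNN = function() .fit_knn(Xtr_s, ytr),
    SVM = function() fit_svm(Xtr_s, ytr)
  )
  models <- list()
  accuracy <- stats::setNames(rep(NaN, length(algorithms)), algorithms)
  for (alg in algorithms) {
    if (!is.null(seed)) set.seed(seed)
    res <- tryCatch({
      m <- fitters[[alg]]()
      te <- if (alg %in% .scaled_algorithms) Xte_s else Xte
      pred <- predict(m, te)
      list(model = m, acc = mean(as.character(pred) == as.character(yte)))
    }, error = function(e) {
      warning(sprintf("classifier %s failed: %s", alg, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      models[[alg]] <- res$model
      accuracy[alg] <- res$acc
    }
  }
  if (all(is.nan(accuracy))) stop("all classifiers failed", call. = FALSE)
  ok <- which(!is.nan(accuracy))
  selected <- names(accuracy)[ok[which.max(accuracy[ok])]]
  structure(
    list(accuracy = accuracy, selected = selected, models = models,
         standardizer = std, levels = levels(labels)),
    class = "classifier_report"
  )
}

#' @method print classifier_report
#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report>\n")
  for (alg in names(x$accuracy)) {
    cat(sprintf("  %-4s accuracy %.4f%s\n", alg, x$accuracy[alg],
                if (alg == x$selected) "  <- selected" else ""))
  }
  invisible(x)
}

#' Predict the orientation of a frame
#'
#' Applies the selected model from a fitted [train_and_compare()] report
#' (standardizing features when the model requires it) to one frame.
#'
#' @param report A `classifier_report`.
#' @param frame A [keypoint_frame()].
#' @return One of [orientation_labels()] as character.
#' @export
predict_orientation <- function(report, frame) {
  if (!inherits(report, "classifier_report") || is.null(report$models[[report$selected]])) {
    stop("report does not carry a fitted model", call. = FALSE)
  }
  feats <- extract_orientation_features(frame)
  X <- matrix(feats, nrow = 1, dimnames = list(NULL, names(feats)))
  if (report$selected %in% .scaled_algorithms) {
    X <- apply_standardizer(report$standardizer, X)
  }
  as.character(predict(report$models[[report$selected]], X))
}

#' Sequence-level orientation by majority vote
#'
#' Classifies every frame and returns the modal label (ties resolve toward
#' the canonical label order Frontal, Turned, Profile).
#'
#' @param report A `classifier_report`.
#' @param seq A [motion_sequence()].
#' @return One of [orientation_labels()].
#' @export
sequence_orientation <- function(report, seq) {
  preds <- vapply(seq$frames, function(f) predict_orientation(report, f), character(1))
  counts <- table(factor(preds, levels = orientation_labels()))
  names(counts)[which.max(counts)]
}
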