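#' Minimal classifier toolkit
#'
#' The orientation stage compares six standard classifiers. Logistic
#' regression and k-nearest neighbours are delegated to \pkg{glmnet} and
#' \pkg{FNN}; the remaining four (Gaussian naive Bayes, CART decision tree,
#' random forest, RBF-kernel support vector machine) are implemented here
#' at their conventional defaults, since no implementation is available in
#' the dependency set. All fits are deterministic given the R random seed.
#'
#' @name classifier_toolkit
#' @keywords internal
NULL

# ---- Gaussian naive Bayes -------------------------------------------------

#' Gaussian naive Bayes classifier
#'
#' Class-conditional independent Gaussians per feature with variance
#' smoothing (1e-9 of the largest feature variance, the conventional
#' default).
#'
#' @param X Numeric matrix (rows = samples).
#' @param y Factor of class labels.
#' @return Object of class `kinescore_nb` with a `predict` method.
#' @export
fit_gaussian_nb <- function(X, y) {
  X <- as.matrix(X); y <- factor(y)
  lev <- levels(y)
  eps <- 1e-9 * max(apply(X, 2, stats::var))
  mu <- do.call(rbind, lapply(lev, function(l) colMeans(X[y == l, , drop = FALSE])))
  va <- do.call(rbind, lapply(lev, function(l) {
    apply(X[y == l, , drop = FALSE], 2, stats::var)
  })) + eps
  prior <- as.numeric(table(y)[lev]) / length(y)
  structure(list(levels = lev, mu = mu, var = va, prior = prior),
            class = "kinescore_nb")
}

#' @export
predict.kinescore_nb <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  ll <- vapply(seq_along(object$levels), function(k) {
    m <- matrix(object$mu[k, ], nrow(X), ncol(X), byrow = TRUE)
    v <- matrix(object$var[k, ], nrow(X), ncol(X), byrow = TRUE)
    rowSums(-0.5 * log(2 * pi * v) - (X - m)^2 / (2 * v)) + log(object$prior[k])
  }, numeric(nrow(X)))
  ll <- matrix(ll, nrow = nrow(X))
  factor(object$levels[max.col(ll, ties.method = "first")], levels = object$levels)
}

# ---- CART decision tree ---------------------------------------------------

.gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# best (feature, threshold) by Gini impurity decrease over candidate
# features; zero-gain splits are admissible (nodes are grown until pure, as
# in the usual library defaults), ties resolve to the first feature and the
# lowest threshold
.best_split <- function(X, yi, nlev, feats) {
  n <- length(yi)
  best <- list(gain = -Inf)
  parent <- .gini(tabulate(yi, nlev))
  for (j in feats) {
    ord <- order(X[, j])
    xs <- X[ord, j]
    ys <- yi[ord]
    left <- integer(nlev)
    right <- tabulate(ys, nlev)
    for (i in seq_len(n - 1)) {
      left[ys[i]] <- left[ys[i]] + 1L
      right[ys[i]] <- right[ys[i]] - 1L
      if (xs[i + 1] <= xs[i] + 1e-12) next
      g <- parent - (i * .gini(left) + (n - i) * .gini(right)) / n
      if (g > best$gain + 1e-12) {
        best <- list(gain = g, feat = j, thr = (xs[i] + xs[i + 1]) / 2)
      }
    }
  }
  if (is.finite(best$gain)) best else NULL
}

.grow_tree <- function(X, yi, nlev, mtry, min_split, depth, max_depth) {
  counts <- tabulate(yi, nlev)
  leaf <- list(leaf = TRUE, class = which.max(counts))
  if (length(yi) < min_split || depth >= max_depth || .gini(counts) == 0) return(leaf)
  feats <- if (mtry < ncol(X)) sort(sample.int(ncol(X), mtry)) else seq_len(ncol(X))
  sp <- .best_split(X, yi, nlev, feats)
  if (is.null(sp) && mtry < ncol(X)) {
    sp <- .best_split(X, yi, nlev, seq_len(ncol(X)))  # fall back to all features
  }
  if (is.null(sp)) return(leaf)
  go <- X[, sp$feat] <= sp$thr
  list(
    leaf = FALSE, feat = sp$feat, thr = sp$thr,
    left = .grow_tree(X[go, , drop = FALSE], yi[go], nlev, mtry, min_split,
                      depth + 1, max_depth),
    right = .grow_tree(X[!go, , drop = FALSE], yi[!go], nlev, mtry, min_split,
                       depth + 1, max_depth)
  )
}

.tree_predict_idx <- function(node, X, idx, out) {
  if (node$leaf) {
    out[idx] <- node$class
    return(out)
  }
  go <- X[idx, node$feat] <= node$thr
  if (any(go)) out <- .tree_predict_idx(node$left, X, idx[go], out)
  if (any(!go)) out <- .tree_predict_idx(node$right, X, idx[!go], out)
  out
}

#' CART decision tree classifier
#'
#' Greedy binary splits minimizing Gini impurity, grown until nodes are
#' pure, too small, or at maximum depth (no pruning, matching the common
#' library defaults).
#'
#' @param X Numeric matrix.
#' @param y Factor of class labels.
#' @param mtry Number of features considered per split (all by default;
#'   used by the random forest).
#' @param min_split Minimum node size eligible for splitting.
#' @param max_depth Depth cap.
#' @return Object of class `kinescore_tree` with a `predict` method.
#' @export
fit_cart <- function(X, y, mtry = ncol(X), min_split = 2, max_depth = 30) {
  X <- as.matrix(X); y <- factor(y)
  root <- .grow_tree(X, as.integer(y), nlevels(y), mtry, min_split, 0, max_depth)
  structure(list(root = root, levels = levels(y)), class = "kinescore_tree")
}

#' @export
predict.kinescore_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  idx <- .tree_predict_idx(object$root, X, seq_len(nrow(X)), integer(nrow(X)))
  factor(object$levels[idx], levels = object$levels)
}

# ---- random forest --------------------------------------------------------

#' Random forest classifier
#'
#' Bootstrap-aggregated CART trees with `floor(sqrt(p))` features sampled
#' per split and majority voting; ties break toward the first class level.
#' Uses the current R random stream; seed with `set.seed()`.
#'
#' @inheritParams fit_cart
#' @param n_tree Number of trees.
#' @return Object of class `kinescore_rf` with a `predict` method.
#' @export
fit_random_forest <- function(X, y, n_tree = 100, mtry = NULL, max_depth = 30) {
  X <- as.matrix(X); y <- factor(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- lapply(seq_len(n_tree), function(b) {
    bs <- sample.int(nrow(X), replace = TRUE)
    fit_cart(X[bs, , drop = FALSE], y[bs], mtry = mtry, max_depth = max_depth)
  })
  structure(list(trees = trees, levels = levels(y)), class = "kinescore_rf")
}

#' @export
predict.kinescore_rf <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  votes <- matrix(0L, nrow(X), length(object$levels))
  for (tr in object$trees) {
    p <- as.integer(predict(tr, X))
    votes[cbind(seq_len(nrow(X)), p)] <- votes[cbind(seq_len(nrow(X)), p)] + 1L
  }
  factor(object$levels[max.col(votes, ties.method = "first")], levels = object$levels)
}

# ---- support vector machine ----------------------------------------------

.rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  exp(-gamma * (outer(an, bn, "+") - 2 * tcrossprod(A, B)))
}

# soft-margin dual for one binary problem, solved with quadprog
.svm_binary <- function(K, ysign, C) {
  n <- length(ysign)
  Dmat <- (ysign %o% ysign) * K
  diag(Dmat) <- diag(Dmat) + 1e-8
  sol <- quadprog::solve.QP(
    Dmat = Dmat, dvec = rep(1, n),
    Amat = cbind(ysign, diag(n), -diag(n)),
    bvec = c(0, rep(0, n), rep(-C, n)), meq = 1
  )
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- which(alpha > 1e-8)
  f_no_b <- as.numeric(K[, sv, drop = FALSE] %*% (alpha[sv] * ysign[sv]))
  margin <- sv[alpha[sv] < C - 1e-8]
  b <- if (length(margin)) mean(ysign[margin] - f_no_b[margin])
       else mean(ysign[sv] - f_no_b[sv])
  list(alpha = alpha[sv], ysign = ysign[sv], sv = sv, b = b)
}

#' Support vector machine classifier (RBF kernel, one-vs-one)
#'
#' C-support vector classification with a radial basis function kernel at
#' the conventional defaults (`C = 1`, `gamma = 1 / (p * var(X))`), the
#' dual quadratic program solved exactly with \pkg{quadprog}; multiclass by
#' one-vs-one voting with ties broken toward the first class level.
#'
#' @param X Numeric matrix (should be standardized).
#' @param y Factor of class labels.
#' @param C Box constraint.
#' @param gamma Kernel width; `NULL` uses `1 / (p * var(X))`.
#' @return Object of class `kinescore_svm` with a `predict` method.
#' @export
fit_svm <- function(X, y, C = 1, gamma = NULL) {
  X <- as.matrix(X); y <- factor(y)
  if (is.null(gamma)) gamma <- 1 / (ncol(X) * stats::var(as.vector(X)))
  lev <- levels(y)
  pairs <- utils::combn(seq_along(lev), 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    sel <- which(y %in% lev[pr])
    Xi <- X[sel, , drop = FALSE]
    ys <- ifelse(y[sel] == lev[pr[1]], 1, -1)
    Ki <- .rbf_kernel(Xi, Xi, gamma)
    m <- .svm_binary(Ki, ys, C)
    list(pair = pr, X = Xi[m$sv, , drop = FALSE],
         coef = m$alpha * m$ysign, b = m$b)
  })
  structure(list(levels = lev, gamma = gamma, models = models),
            class = "kinescore_svm")
}

#' @export
predict.kinescore_svm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  votes <- matrix(0L, nrow(X), length(object$levels))
  for (m in object$models) {
    f <- as.numeric(.rbf_kernel(X, m$X, object$gamma) %*% m$coef) + m$b
    win <- ifelse(f >= 0, m$pair[1], m$pair[2])
    votes[cbind(seq_len(nrow(X)), win)] <- votes[cbind(seq_len(nrow(X)), win)] + 1L
  }
  factor(object$levels[max.col(votes, ties.method = "first")], levels = object$levels)
}

# ---- delegated classifiers ------------------------------------------------

# multinomial ridge logistic regression via glmnet at light regularization
.fit_lr <- function(X, y) {
  fit <- glmnet::glmnet(as.matrix(X), y, family = "multinomial", alpha = 0,
                        lambda = 10^seq(0, -4, length.out = 20),
                        standardize = FALSE)
  structure(list(fit = fit, levels = levels(y)), class = "kinescore_lr")
}

#' @export
predict.kinescore_lr <- function(object, newdata, ...) {
  p <- predict(object$fit, as.matrix(newdata), s = 1e-4, type = "class")
  factor(as.character(p), levels = object$levels)
}

# k-nearest neighbours (k = 5) via FNN; stores the training set
.fit_knn <- function(X, y, k = 5) {
  structure(list(X = as.matrix(X), y = factor(y), k = k), class = "kinescore_knn")
}

#' @export
predict.kinescore_knn <- function(object, newdata, ...) {
  FNN::knn(object$X, as.matrix(newdata), object$y, k = object$k)
}
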