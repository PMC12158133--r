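# shared fixtures and independent oracles, built in code at test time

# a frame with only the named keypoints visible, others absent
frame_with <- function(points, t_ms = 0L, bbox = c(0.5, 0.5, 1, 1)) {
  kpts <- matrix(0, 17, 3, dimnames = list(coco_schema(), c("x", "y", "v")))
  for (nm in names(points)) {
    kpts[nm, ] <- c(points[[nm]], 2)
  }
  keypoint_frame(kpts, bbox = bbox, t_ms = t_ms)
}

# random valid YOLO-pose record values
random_record <- function() {
  kpts <- cbind(stats::runif(17), stats::runif(17), sample(0:2, 17, replace = TRUE))
  list(class_id = 0L, bbox = stats::runif(4), kpts = kpts)
}

# brute-force envelope over every corner of every annotation box
oracle_envelope <- function(annotations) {
  corners <- do.call(rbind, lapply(annotations, function(a) {
    b <- a$box
    rbind(c(b[1], b[2]), c(b[1], b[4]), c(b[3], b[2]), c(b[3], b[4]))
  }))
  c(min(corners[, 1]), min(corners[, 2]), max(corners[, 1]), max(corners[, 2]))
}

# independent finite-difference oracle: explicit difference quotients
oracle_fd <- function(t_ms, y) {
  t <- t_ms / 1000
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- if (i == 1) (y[2] - y[1]) / (t[2] - t[1])
    else if (i == n) (y[n] - y[n - 1]) / (t[n] - t[n - 1])
    else (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  }
  out
}

# independent time-in-range oracle: loop over intervals, left-sample rule
oracle_time_in_ranges <- function(t_ms, angle, breaks) {
  k <- length(breaks) - 1
  out <- numeric(k)
  for (i in seq_along(t_ms)[-length(t_ms)]) {
    a <- angle[i]
    ridx <- k  # last range closed above
    for (j in seq_len(k)) {
      if (a >= breaks[j] && a < breaks[j + 1]) {
        ridx <- j
        break
      }
    }
    out[ridx] <- out[ridx] + (t_ms[i + 1] - t_ms[i])
  }
  out
}

# independent sway oracle: direct RMS deviation from the centroid
oracle_rms <- function(xy) {
  ctr <- colMeans(xy)
  sqrt(mean((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2))
}

# maximum absolute difference between a computed trace and its ground truth
trace_error <- function(est, truth) {
  stopifnot(nrow(est$samples) > 0)
  idx <- match(est$samples$t_ms, truth$samples$t_ms)
  max(abs(est$samples$angle_deg - truth$samples$angle_deg[idx]))
}
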