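#' Construct a keypoint frame
#'
#' One time-stamped pose observation: a 17x3 keypoint matrix (columns `x`,
#' `y`, `v`), a person bounding box and a timestamp in milliseconds.
#' Coordinates are normalized to the image (`[0,1]`, origin top-left, y
#' increasing downward). Visibility `v` follows the COCO convention:
#' 0 = absent (x, y ignored downstream), 1 = occluded, 2 = visible.
#'
#' @param kpts Numeric 17x3 matrix; row names are set to [coco_schema()].
#' @param bbox Numeric length-4 vector `(cx, cy, w, h)`, normalized.
#' @param t_ms Non-negative integer timestamp in milliseconds.
#' @return Object of class `keypoint_frame`.
#' @export
keypoint_frame <- function(kpts, bbox = c(0.5, 0.5, 1, 1), t_ms = 0L) {
  kpts <- as.matrix(kpts)
  if (!all(dim(kpts) == c(17L, 3L))) {
    stop("kpts must be a 17x3 matrix (x, y, visibility)", call. = FALSE)
  }
  dimnames(kpts) <- list(coco_schema(), c("x", "y", "v"))
  if (!all(kpts[, "v"] %in% c(0, 1, 2))) {
    stop("visibility flags must be in {0, 1, 2}", call. = FALSE)
  }
  vis <- kpts[, "v"] > 0
  xy <- kpts[vis, c("x", "y"), drop = FALSE]
  if (length(xy) && (any(xy < 0) || any(xy > 1))) {
    stop("visible keypoint coordinates must lie in [0, 1]", call. = FALSE)
  }
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4 || any(bbox < 0) || any(bbox > 1)) {
    stop("bbox must be (cx, cy, w, h) in [0, 1]", call. = FALSE)
  }
  t_ms <- as.integer(round(t_ms))
  if (is.na(t_ms) || t_ms < 0) stop("t_ms must be a non-negative integer", call. = FALSE)
  structure(list(kpts = kpts, bbox = bbox, t_ms = t_ms), class = "keypoint_frame")
}

#' Construct a motion sequence
#'
#' An ordered, validated list of keypoint frames with strictly increasing
#' millisecond timestamps plus session metadata.
#'
#' @param frames List of [keypoint_frame()] objects.
#' @param with_weight Logical; whether the exercise was performed under
#'   additional load.
#' @param subject_id Opaque subject identifier.
#' @return Object of class `motion_sequence`.
#' @export
motion_sequence <- function(frames, with_weight = FALSE, subject_id = "anon") {
  if (length(frames) == 0) stop("motion sequence must contain at least one frame", call. = FALSE)
  ok <- vapply(frames, inherits, logical(1), what = "keypoint_frame")
  if (!all(ok)) stop("all frames must be keypoint_frame objects", call. = FALSE)
  ts <- vapply(frames, function(f) f$t_ms, numeric(1))
  ord <- order(ts)
  frames <- frames[ord]
  ts <- ts[ord]
  bad <- which(diff(ts) <= 0)
  if (length(bad)) {
    stop("timestamps must be strictly increasing; violations at frame indices ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  structure(
    list(frames = frames, with_weight = isTRUE(with_weight), subject_id = subject_id),
    class = "motion_sequence"
  )
}

#' @export
length.motion_sequence <- function(x) length(x$frames)

#' @method print motion_sequence
#' @export
print.motion_sequence <- function(x, ...) {
  ts <- timestamps(x)
  cat(sprintf("<motion_sequence> %d frames, %d..%d ms, with_weight=%s, subject=%s\n",
              length(x$frames), ts[1], ts[length(ts)], x$with_weight, x$subject_id))
  invisible(x)
}

#' Frame timestamps of a motion sequence
#' @param seq A `motion_sequence`.
#' @return Integer vector of milliseconds.
#' @export
timestamps <- function(seq) {
  vapply(seq$frames, function(f) f$t_ms, integer(1))
}

#' Parse a YOLO-pose text record
#'
#' A single-person pose record is one whitespace-separated line of 56
#' numbers: class id, bounding box (cx, cy, w, h), then (x, y, visibility)
#' for each of the 17 keypoints, all coordinates normalized to the image.
#'
#' @param line Character scalar, one record.
#' @return List with `class_id`, `bbox` (cx, cy, w, h) and `kpts` (17x3
#'   matrix).
#' @export
#' @examples
#' rec <- parse_yolo_pose_record(paste(c(0, rep(0, 55)), collapse = " "))
#' rec$class_id
parse_yolo_pose_record <- function(line) {
  toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  if (length(toks) != 56L) {
    stop(sprintf("malformed YOLO-pose record: expected 56 tokens, got %d", length(toks)),
         call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals)) {
    stop("malformed YOLO-pose record: non-numeric token at position ",
         which(is.na(vals))[1], call. = FALSE)
  }
  coords <- vals[-1]
  # visibility flags (every 3rd keypoint token) are exempt from the [0,1] check
  vis_idx <- 4 + seq(3, 51, by = 3)
  coord_idx <- setdiff(seq_along(coords), vis_idx)
  out_of_range <- coord_idx[coords[coord_idx] < 0 | coords[coord_idx] > 1]
  if (length(out_of_range)) {
    stop("coordinate outside [0, 1] at token index ", out_of_range[1] + 1L, call. = FALSE)
  }
  kpts <- matrix(coords[-(1:4)], ncol = 3, byrow = TRUE,
                 dimnames = list(coco_schema(), c("x", "y", "v")))
  list(class_id = as.integer(vals[1]), bbox = vals[2:5], kpts = kpts)
}

#' Format a YOLO-pose text record
#'
#' Inverse of [parse_yolo_pose_record()]: emits 56 whitespace-separated
#' tokens with 6 decimal places.
#'
#' @param class_id Integer class id.
#' @param bbox Numeric `(cx, cy, w, h)`.
#' @param kpts 17x3 keypoint matrix.
#' @return Character scalar.
#' @export
format_yolo_pose_record <- function(class_id, bbox, kpts) {
  kpts <- as.matrix(kpts)
  stopifnot(length(bbox) == 4, all(dim(kpts) == c(17, 3)))
  vals <- c(bbox, as.vector(t(kpts)))
  paste(c(as.character(as.integer(class_id)), sprintf("%.6f", vals)), collapse = " ")
}

.frame_to_ndjson <- function(frame) {
  jsonlite::toJSON(
    list(
      t_ms = frame$t_ms,
      bbox = round(frame$bbox, 6),
      kpts = round(unname(frame$kpts), 6)
    ),
    auto_unbox = TRUE, digits = NA
  )
}

.frame_from_ndjson <- function(line) {
  obj <- jsonlite::fromJSON(line)
  keypoint_frame(matrix(unlist(obj$kpts), ncol = 3, byrow = !is.matrix(obj$kpts)),
                 bbox = obj$bbox, t_ms = obj$t_ms)
}

#' Read a motion sequence from disk
#'
#' Two container formats are supported. `"ndjson"` is the package's internal
#' format: one JSON object per line with fields `t_ms`, `bbox` and `kpts`.
#' `"yolo_dir"` is a directory of per-frame YOLO-pose `.txt` files plus a
#' `timestamps.txt` sidecar listing `filename<TAB>t_ms` per frame.
#'
#' @param path File (ndjson) or directory (yolo_dir).
#' @param format `"ndjson"` or `"yolo_dir"`.
#' @param with_weight,subject_id Session metadata.
#' @return A [motion_sequence()].
#' @export
read_sequence <- function(path, format = c("ndjson", "yolo_dir"),
                          with_weight = FALSE, subject_id = "anon") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  frames <- if (format == "ndjson") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty sequence file: ", path, call. = FALSE)
    lapply(lines, .frame_from_ndjson)
  } else {
    sidecar <- file.path(path, "timestamps.txt")
    if (!file.exists(sidecar)) stop("missing timestamp sidecar: ", sidecar, call. = FALSE)
    tab <- utils::read.table(sidecar, header = FALSE, sep = "\t",
                             col.names = c("file", "t_ms"),
                             colClasses = c("character", "integer"))
    if (!nrow(tab)) stop("empty timestamp sidecar", call. = FALSE)
    lapply(seq_len(nrow(tab)), function(i) {
      rec <- parse_yolo_pose_record(readLines(file.path(path, tab$file[i]))[1])
      keypoint_frame(rec$kpts, bbox = rec$bbox, t_ms = tab$t_ms[i])
    })
  }
  motion_sequence(frames, with_weight = with_weight, subject_id = subject_id)
}

#' Write a motion sequence to disk
#'
#' @inheritParams read_sequence
#' @param seq A `motion_sequence`.
#' @return The path, invisibly.
#' @export
write_sequence <- function(seq, path, format = c("ndjson", "yolo_dir")) {
  format <- match.arg(format)
  if (format == "ndjson") {
    writeLines(vapply(seq$frames, .frame_to_ndjson, character(1)), path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- sprintf("frame_%06d.txt", seq_along(seq$frames))
    for (i in seq_along(seq$frames)) {
      f <- seq$frames[[i]]
      writeLines(format_yolo_pose_record(0L, f$bbox, f$kpts), file.path(path, files[i]))
    }
    utils::write.table(
      data.frame(file = files, t_ms = timestamps(seq)),
      file.path(path, "timestamps.txt"),
      sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}

#' Mirror a frame or sequence left-right
#'
#' Reflects all keypoints about the vertical image midline (`x -> 1 - x`)
#' and swaps left/right landmark labels, producing the pose of the mirrored
#' subject. Used for asymmetry analysis and for the mirror-symmetry
#' properties of the angle computations.
#'
#' @param frame A `keypoint_frame`.
#' @return The mirrored object of the same class.
#' @export
mirror_frame <- function(frame) {
  kpts <- frame$kpts
  pairs <- .kp_mirror_pairs()
  for (i in seq_len(nrow(pairs))) {
    tmp <- kpts[pairs[i, 1], ]
    kpts[pairs[i, 1], ] <- kpts[pairs[i, 2], ]
    kpts[pairs[i, 2], ] <- tmp
  }
  kpts[, "x"] <- ifelse(kpts[, "v"] > 0, 1 - kpts[, "x"], kpts[, "x"])
  bbox <- frame$bbox
  bbox[1] <- 1 - bbox[1]
  keypoint_frame(kpts, bbox = bbox, t_ms = frame$t_ms)
}

#' @rdname mirror_frame
#' @param seq A `motion_sequence`.
#' @export
mirror_sequence <- function(seq) {
  motion_sequence(lapply(seq$frames, mirror_frame),
                  with_weight = seq$with_weight, subject_id = seq$subject_id)
}
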