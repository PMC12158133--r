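#' Body-segment annotation
#'
#' One CVAT-style annotation for a single body segment: the segment class
#' (five limbs plus trunk), its bounding box in pixel coordinates and
#' optionally the keypoints annotated inside it, in the class's canonical
#' order.
#'
#' Canonical keypoint order per class: `head` = nose, left eye, right eye,
#' left ear, right ear; `left_arm`/`right_arm` = shoulder, elbow, wrist;
#' `left_leg`/`right_leg` = hip, knee, ankle; `trunk` keypoints are accepted
#' but discarded on conversion (shoulders and hips bound the trunk already).
#'
#' @param segment_class One of `head`, `left_arm`, `right_arm`, `left_leg`,
#'   `right_leg`, `trunk`.
#' @param box Numeric `(xmin, ymin, xmax, ymax)` in pixels.
#' @param keypoints Optional Nx2 matrix of pixel coordinates in canonical
#'   order.
#' @return Object of class `segment_annotation`.
#' @export
segment_annotation <- function(segment_class, box, keypoints = NULL) {
  classes <- c("head", "left_arm", "right_arm", "left_leg", "right_leg", "trunk")
  if (!segment_class %in% classes) {
    stop("segment_class must be one of: ", paste(classes, collapse = ", "), call. = FALSE)
  }
  box <- as.numeric(box)
  if (length(box) != 4 || box[1] > box[3] || box[2] > box[4]) {
    stop("box must be (xmin, ymin, xmax, ymax) with min <= max", call. = FALSE)
  }
  if (!is.null(keypoints)) {
    keypoints <- matrix(as.numeric(keypoints), ncol = 2)
  }
  structure(list(segment_class = segment_class, box = box, keypoints = keypoints),
            class = "segment_annotation")
}

# schema slot indices (1-based) owned by each segment class
.segment_slots <- function(segment_class) {
  switch(segment_class,
    head = 1:5,
    left_arm = c(6L, 8L, 10L),
    right_arm = c(7L, 9L, 11L),
    left_leg = c(12L, 14L, 16L),
    right_leg = c(13L, 15L, 17L),
    trunk = integer(0)
  )
}

#' Convert per-segment CVAT annotations to a single YOLO-pose record
#'
#' Groups the six per-segment annotations of one person into a single
#' "person" bounding box (the min/max envelope of all segment boxes) and a
#' single 17-slot keypoint set, normalized to the square target image.
#' Trunk keypoints are discarded: the shoulder and hip keypoints bound the
#' trunk. Schema slots with no annotated keypoint get visibility 0.
#'
#' @param annotations List of [segment_annotation()] objects, at most one
#'   per segment class.
#' @param image_width_px,image_height_px Source image size in pixels.
#' @param target_size_px Side of the square output image (default 640);
#'   coordinates are emitted normalized, so this only documents the resize
#'   target.
#' @return List with `bbox` (cx, cy, w, h normalized) and `kpts` (17x3
#'   matrix, visibility 2 for filled slots).
#' @export
convert_cvat_to_yolo <- function(annotations, image_width_px, image_height_px,
                                 target_size_px = 640) {
  if (length(annotations) == 0) stop("no annotations supplied", call. = FALSE)
  classes <- vapply(annotations, function(a) a$segment_class, character(1))
  dup <- unique(classes[duplicated(classes)])
  if (length(dup)) {
    stop("duplicate segment class: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  boxes <- do.call(rbind, lapply(annotations, function(a) a$box))
  xmin <- min(boxes[, 1]); ymin <- min(boxes[, 2])
  xmax <- max(boxes[, 3]); ymax <- max(boxes[, 4])
  # normalize: resize W x H -> S x S then divide by S == divide by W (or H)
  nx <- function(x) pmin(pmax(x / image_width_px, 0), 1)
  ny <- function(y) pmin(pmax(y / image_height_px, 0), 1)
  bbox <- c(
    cx = nx((xmin + xmax) / 2), cy = ny((ymin + ymax) / 2),
    w = nx(xmax) - nx(xmin), h = ny(ymax) - ny(ymin)
  )
  kpts <- matrix(0, 17, 3, dimnames = list(coco_schema(), c("x", "y", "v")))
  for (a in annotations) {
    slots <- .segment_slots(a$segment_class)
    if (is.null(a$keypoints) || length(slots) == 0) next
    n <- min(nrow(a$keypoints), length(slots))
    for (i in seq_len(n)) {
      kpts[slots[i], ] <- c(nx(a$keypoints[i, 1]), ny(a$keypoints[i, 2]), 2)
    }
  }
  list(bbox = unname(bbox), kpts = kpts)
}

#' Read segment annotations from a CVAT JSON export
#'
#' Parses the CVAT job-export dialect: a document (or list of documents)
#' carrying a `shapes` array where each shape has `label`, `type`
#' (`rectangle` or `points`), flat `points` and a `frame` index. Extra
#' fields are ignored. For each frame, the rectangle shape of a label
#' supplies the segment box and the points shape supplies its keypoints.
#'
#' @param path Path to the CVAT JSON file.
#' @return Named list: one entry per frame id, each a list of
#'   [segment_annotation()] objects.
#' @export
read_cvat_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(doc$shapes)) doc <- list(doc)
  shapes <- list()
  for (job in doc) {
    shapes <- c(shapes, job$shapes)
  }
  if (!length(shapes)) stop("no shapes found in CVAT document", call. = FALSE)
  frames <- list()
  for (s in shapes) {
    fid <- as.character(s$frame %||% 0)
    lab <- s$label
    pts <- as.numeric(unlist(s$points))
    ent <- frames[[fid]][[lab]] %||% list(box = NULL, keypoints = NULL)
    if (identical(s$type, "rectangle")) {
      ent$box <- pts[1:4]
    } else {
      ent$keypoints <- matrix(pts, ncol = 2, byrow = TRUE)
    }
    if (is.null(frames[[fid]])) frames[[fid]] <- list()
    frames[[fid]][[lab]] <- ent
  }
  lapply(frames, function(labs) {
    anns <- list()
    for (lab in names(labs)) {
      ent <- labs[[lab]]
      box <- ent$box
      if (is.null(box)) {
        # points-only label: use the keypoint envelope as its box
        box <- c(min(ent$keypoints[, 1]), min(ent$keypoints[, 2]),
                 max(ent$keypoints[, 1]), max(ent$keypoints[, 2]))
      }
      anns[[length(anns) + 1L]] <- segment_annotation(lab, box, ent$keypoints)
    }
    anns
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
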