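#' COCO-17 keypoint schema
#'
#' The fixed, ordered names of the 17 body landmarks used throughout the
#' package, in the standard COCO ordering (index 0 = Nose ... index 16 =
#' Right Ankle). All keypoint matrices use these names as row names and this
#' order for both I/O and computation.
#'
#' @return Character vector of length 17.
#' @export
#' @examples
#' coco_schema()[1:5]
coco_schema <- function() {
  c(
    "nose", "left_eye", "right_eye", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_hip", "right_hip",
    "left_knee", "right_knee", "left_ankle", "right_ankle"
  )
}

# left/right partner table used for mirroring and asymmetry analysis
.kp_mirror_pairs <- function() {
  rbind(
    c("left_eye", "right_eye"), c("left_ear", "right_ear"),
    c("left_shoulder", "right_shoulder"), c("left_elbow", "right_elbow"),
    c("left_wrist", "right_wrist"), c("left_hip", "right_hip"),
    c("left_knee", "right_knee"), c("left_ankle", "right_ankle")
  )
}

#' Mobility parameter codes
#'
#' Metadata for the 17 scored mobility parameters: the angle code, the body
#' part it belongs to (head: 5 codes, arms/legs/torso: 4 each), how the code
#' is derived from the underlying signed or per-side angle, and the angular
#' span analysed for it.
#'
#' Codes: lateral head tilt left/right (LHTL, LHTR), head rotation left/right
#' (HRL, HRR), frontal head tilt (FHT), wrist-shoulder angle per arm (WSAL,
#' WSAR), lateral elevation of the extended arm per side (AELL, AELR),
#' hip-ankle angle per leg (HAAL, HAAR), lateral elevation of the extended
#' leg per side (LELI, LELR), lateral trunk tilt left/right (LTTL, LTTR),
#' frontal trunk inclination forward/backward (FTIF, FTIB).
#'
#' @return A data.frame with columns `code`, `part`, `source`, `polarity`,
#'   `span_max`.
#' @export
parameter_codes <- function() {
  df <- rbind(
    data.frame(code = "LHTL", part = "Head",  source = "head_tilt",  polarity = "pos",  span_max = 90),
    data.frame(code = "LHTR", part = "Head",  source = "head_tilt",  polarity = "neg",  span_max = 90),
    data.frame(code = "HRL",  part = "Head",  source = "head_rot",   polarity = "pos",  span_max = 90),
    data.frame(code = "HRR",  part = "Head",  source = "head_rot",   polarity = "neg",  span_max = 90),
    data.frame(code = "FHT",  part = "Head",  source = "head_pitch", polarity = "abs",  span_max = 90),
    data.frame(code = "WSAL", part = "Arms",  source = "wsa",        polarity = "left", span_max = 180),
    data.frame(code = "WSAR", part = "Arms",  source = "wsa",        polarity = "right", span_max = 180),
    data.frame(code = "AELL", part = "Arms",  source = "ael",        polarity = "left", span_max = 90),
    data.frame(code = "AELR", part = "Arms",  source = "ael",        polarity = "right", span_max = 90),
    data.frame(code = "HAAL", part = "Legs",  source = "haa",        polarity = "left", span_max = 90),
    data.frame(code = "HAAR", part = "Legs",  source = "haa",        polarity = "right", span_max = 90),
    data.frame(code = "LELI", part = "Legs",  source = "lel",        polarity = "left", span_max = 90),
    data.frame(code = "LELR", part = "Legs",  source = "lel",        polarity = "right", span_max = 90),
    data.frame(code = "LTTL", part = "Torso", source = "trunk_tilt", polarity = "pos",  span_max = 90),
    data.frame(code = "LTTR", part = "Torso", source = "trunk_tilt", polarity = "neg",  span_max = 90),
    data.frame(code = "FTIF", part = "Torso", source = "trunk_pitch", polarity = "pos", span_max = 90),
    data.frame(code = "FTIB", part = "Torso", source = "trunk_pitch", polarity = "neg", span_max = 90)
  )
  rownames(df) <- df$code
  df
}

#' Range scheme for one parameter code
#'
#' Each code is scored over three contiguous angular ranges mapped to the
#' three score bands 0-25, 25-50, 50-75. Head, leg, torso codes and arm
#' lateral elevation use ranges 0-30/30-60/60-90 degrees; the wrist-shoulder
#' angle uses 0-60/60-120/120-180 degrees. Ranges are half-open `[lo, hi)`
#' with the last range closed, so a boundary angle belongs to the upper
#' range.
#'
#' @param code One of the 17 codes from [parameter_codes()].
#' @return An object of class `range_scheme` with elements `code`, `breaks`
#'   (length 4), `score_bands` (3x2 matrix) and `ceiling` (75).
#' @export
#' @examples
#' range_scheme("WSAL")$breaks
range_scheme <- function(code) {
  codes <- parameter_codes()
  if (!code %in% codes$code) {
    stop("unknown parameter code: ", code, call. = FALSE)
  }
  span <- codes[code, "span_max"]
  breaks <- span * c(0, 1, 2, 3) / 3
  structure(
    list(
      code = code,
      breaks = breaks,
      score_bands = cbind(lo = c(0, 25, 50), hi = c(25, 50, 75)),
      ceiling = 75
    ),
    class = "range_scheme"
  )
}

#' Body-part normalization specs
#'
#' Which codes contribute to each body part's normalized score and the
#' normalization denominator: Head 375 (5 codes x 75), Arms/Legs/Torso 300
#' (4 x 75), and the whole-body denominator (default 1275 = 17 x 75; the
#' alternative printed value 1575 can be selected through
#' [default_config()]'s `body_denominator`).
#'
#' @param part One of `"Head"`, `"Arms"`, `"Legs"`, `"Torso"`, `"Body"`.
#' @param body_denominator Denominator used for the `"Body"` part.
#' @return List with `part`, `codes`, `denominator`.
#' @export
body_part_spec <- function(part = c("Head", "Arms", "Legs", "Torso", "Body"),
                           body_denominator = 1275) {
  part <- match.arg(part)
  codes <- parameter_codes()
  if (part == "Body") {
    member <- codes$code
    denom <- body_denominator
  } else {
    member <- codes$code[codes$part == part]
    denom <- length(member) * 75
  }
  list(part = part, codes = member, denominator = denom)
}

#' Orientation labels
#'
#' The closed vocabulary of gross body orientations relative to the camera.
#' @return Character vector `c("Frontal", "Turned", "Profile")`.
#' @export
orientation_labels <- function() c("Frontal", "Turned", "Profile")

#' Orientation gating table
#'
#' Which parameter codes are computable for a given body orientation.
#' Frontal enables all frontal-plane codes (head tilt/rotation, arm and leg
#' elevation, lateral trunk tilt); Profile enables the sagittal codes
#' (frontal head tilt, frontal trunk inclination) plus wrist-shoulder and
#' hip-ankle angles; Turned enables the Frontal set but results are flagged
#' lower-confidence.
#'
#' @param orientation One of [orientation_labels()].
#' @return List with `codes` (character vector of enabled codes) and
#'   `confidence` (`"high"` or `"low"`).
#' @export
orientation_gating <- function(orientation) {
  orientation <- match.arg(orientation, orientation_labels())
  codes <- parameter_codes()$code
  frontal_set <- setdiff(codes, c("FHT", "FTIF", "FTIB"))
  switch(orientation,
    Frontal = list(codes = frontal_set, confidence = "high"),
    Turned  = list(codes = frontal_set, confidence = "low"),
    Profile = list(
      codes = c("FHT", "FTIF", "FTIB", "WSAL", "WSAR", "HAAL", "HAAR"),
      confidence = "high"
    )
  )
}

#' Default pipeline configuration
#'
#' All tunable knobs in one list: the yaw bands that define the three
#' orientation classes for the synthetic generator (degrees, with deliberate
#' gaps between classes), keypoint noise, frame rate, scoring options and
#' feature-extraction options. Values can be overridden via `...` and the
#' whole object round-trips through YAML with [read_config()] /
#' [write_config()].
#'
#' @param ... Named overrides of any default entry.
#' @return A list of class `kinescore_config`.
#' @export
#' @examples
#' cfg <- default_config(noise_sd = 0)
#' cfg$yaw_bands$Profile
default_config <- function(...) {
  cfg <- list(
    yaw_bands = list(
      Frontal = c(0, 15),
      Turned = c(25, 60),
      Profile = c(70, 90)
    ),
    noise_sd = 0.01,          # keypoint jitter sd, fraction of image width
    fps = 25,
    smoothing_ms = 0,         # moving-average width for traces; 0 = off
    band_constant_scores = FALSE,
    body_denominator = 1275,  # 17 codes x 75; set 1575 for the printed variant
    renormalize_gated = FALSE, # drop not-assessed codes from denominators
    bbox_frame_features = FALSE, # express keypoint features in bbox frame
    use_pca = FALSE,
    pca_components = 3
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "), call. = FALSE)
    cfg[names(over)] <- over
  }
  for (b in cfg$yaw_bands) {
    if (length(b) != 2 || b[1] > b[2]) stop("yaw band must be [lo, hi]", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(cfg, class = "kinescore_config")
}

#' Read / write a configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns a `kinescore_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$yaw_bands <- lapply(raw$yaw_bands, as.numeric)
  do.call(default_config, raw)
}

#' @rdname read_config
#' @param config A `kinescore_config` object.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  yaml::write_yaml(out, path)
  invisible(path)
}
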