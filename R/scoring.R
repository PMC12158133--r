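#' Classify an angle into its motion range
#'
#' Returns the 0-based index (0, 1 or 2) of the range containing the angle
#' under the code's scheme. Ranges are half-open `[lo, hi)` with the last
#' range closed, so a boundary angle belongs to the upper range (30 deg is
#' in 30-60) and the span maximum belongs to the last range. Angles outside
#' the span are clamped with a warning.
#'
#' @param angle_deg Angle in degrees (vectorized).
#' @param scheme A [range_scheme()].
#' @return Integer vector of 0-based range indices.
#' @export
#' @examples
#' classify_range(45, range_scheme("LHTL"))  # 1
classify_range <- function(angle_deg, scheme) {
  breaks <- scheme$breaks
  if (any(angle_deg < breaks[1] - 1e-9 | angle_deg > breaks[length(breaks)] + 1e-9)) {
    warning("angle outside the scheme span; clamped", call. = FALSE)
    angle_deg <- pmin(pmax(angle_deg, breaks[1]), breaks[length(breaks)])
  }
  .range_index(angle_deg, breaks) - 1L
}

#' Traffic-light status from visited ranges
#'
#' Green when the parameter moved through all three defined ranges, orange
#' when it moved through two, red when it stayed in a single range (or was
#' never assessed). Precedence green > orange > red.
#'
#' @param ranges_visited Integer set of visited 0-based range indices.
#' @return `"green"`, `"orange"` or `"red"`.
#' @export
traffic_light <- function(ranges_visited) {
  k <- length(unique(ranges_visited))
  if (k >= 3) "green" else if (k == 2) "orange" else "red"
}

#' Score one parameter
#'
#' The running score Pi for a parameter is driven by the maximum angle
#' achieved so far: with the maximum in range `k` (0-based, bounds
#' `[lo_k, hi_k)`), `Pi = 25 k + 25 (theta_max - lo_k) / (hi_k - lo_k)`,
#' a continuous monotone mapping onto the score bands 0-25 / 25-50 / 50-75.
#' With `band_constant = TRUE`, Pi steps to the band upper bound instead.
#' Pi is non-decreasing over the trace and capped at 75. Ranges visited
#' accumulate the ranges of the instantaneous angle, feeding the
#' traffic-light status. An invalid (orientation-gated or empty) trace
#' scores 0, red, flagged not-assessed.
#'
#' @param x A [parameter_trace()] or [summarize_kinematics()] result.
#' @param scheme A [range_scheme()] (defaults to the code's own).
#' @param band_constant Use the step mapping instead of the piecewise
#'   linear one.
#' @return Object of class `parameter_score` with fields `code`, `Pi`,
#'   `ranges_visited`, `traffic`, `history`, `not_assessed`,
#'   `max_angle_deg`.
#' @export
score_parameter <- function(x, scheme = NULL, band_constant = FALSE) {
  trace <- if (inherits(x, "kinematic_summary")) x$trace else x
  stopifnot(inherits(trace, "parameter_trace"))
  if (is.null(scheme)) scheme <- range_scheme(trace$code)
  if (!trace$valid || nrow(trace$samples) == 0) {
    return(structure(
      list(code = trace$code, Pi = 0, ranges_visited = integer(0),
           traffic = "red", history = data.frame(t_ms = integer(0), Pi = numeric(0)),
           not_assessed = TRUE, max_angle_deg = NA_real_,
           reason = trace$reason %||% "no samples"),
      class = "parameter_score"
    ))
  }
  s <- trace$samples
  run_max <- cummax(s$angle_deg)
  k <- classify_range(run_max, scheme)
  lo <- scheme$breaks[k + 1L]
  hi <- scheme$breaks[k + 2L]
  Pi <- if (band_constant) 25 * (k + 1) else 25 * k + 25 * (run_max - lo) / (hi - lo)
  Pi <- pmin(Pi, scheme$ceiling)
  visited <- sort(unique(classify_range(s$angle_deg, scheme)))
  structure(
    list(code = trace$code, Pi = Pi[length(Pi)], ranges_visited = visited,
         traffic = traffic_light(visited),
         history = data.frame(t_ms = s$t_ms, Pi = Pi),
         not_assessed = FALSE, max_angle_deg = max(s$angle_deg)),
    class = "parameter_score"
  )
}

#' @method print parameter_score
#' @export
print.parameter_score <- function(x, ...) {
  cat(sprintf("<parameter_score %s> Pi=%.2f traffic=%s ranges={%s}%s\n",
              x$code, x$Pi, x$traffic, paste(x$ranges_visited, collapse = ","),
              if (x$not_assessed) " (not assessed)" else ""))
  invisible(x)
}

#' Normalized body-part score
#'
#' Sum of the member parameters' Pi divided by the part's normalization
#' denominator (Head 375, Arms/Legs/Torso 300), in `[0, 1]`.
#'
#' @param scores Named list of [score_parameter()] results (by code).
#' @param spec A [body_part_spec()].
#' @param renormalize Drop not-assessed codes from the denominator.
#' @return Numeric scalar in `[0, 1]`.
#' @export
part_score <- function(scores, spec, renormalize = FALSE) {
  missing_codes <- setdiff(spec$codes, names(scores))
  if (length(missing_codes)) {
    stop("missing parameter scores for: ", paste(missing_codes, collapse = ", "),
         call. = FALSE)
  }
  member <- scores[spec$codes]
  denom <- spec$denominator
  if (renormalize) {
    assessed <- !vapply(member, function(s) isTRUE(s$not_assessed), logical(1))
    if (!any(assessed)) return(0)
    denom <- denom * sum(assessed) / length(member)
    member <- member[assessed]
  }
  val <- sum(vapply(member, function(s) s$Pi, numeric(1))) / denom
  if (val > 1 + 1e-9) {
    warning("part score exceeds 1; clipped", call. = FALSE)
    val <- 1
  }
  val
}

#' Global mobility score
#'
#' Sum of all 17 Pi divided by the whole-body denominator (default 1275 =
#' 17 x 75; the alternative printed denominator 1575 is selectable through
#' the config).
#'
#' @inheritParams part_score
#' @param body_denominator Whole-body denominator.
#' @return Numeric scalar.
#' @export
global_score <- function(scores, body_denominator = 1275, renormalize = FALSE) {
  part_score(scores, body_part_spec("Body", body_denominator = body_denominator),
             renormalize = renormalize)
}
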