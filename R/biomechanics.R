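#' Parameter trace
#'
#' The time series of one mobility parameter code, in degrees. Angles are
#' magnitudes (>= 0) within the code's physical span; signed raw angles are
#' split into left/right (or forward/backward) code pairs upstream. A trace
#' that cannot be computed under the current orientation carries
#' `valid = FALSE` and no samples.
#'
#' @param code One of the 17 codes from [parameter_codes()].
#' @param t_ms Strictly increasing integer timestamps.
#' @param angle_deg Angles in `[0, span]` for the code.
#' @param valid Whether the code is computable in this session.
#' @param confidence `"high"` or `"low"` (Turned orientation).
#' @param reason Optional reason when `valid = FALSE`.
#' @return Object of class `parameter_trace`.
#' @export
parameter_trace <- function(code, t_ms = integer(0), angle_deg = numeric(0),
                            valid = TRUE, confidence = "high", reason = NULL) {
  codes <- parameter_codes()
  if (!code %in% codes$code) stop("unknown parameter code: ", code, call. = FALSE)
  span <- codes[code, "span_max"]
  t_ms <- as.integer(round(t_ms))
  if (length(t_ms) > 1 && any(diff(t_ms) <= 0)) {
    stop("trace timestamps must be strictly increasing", call. = FALSE)
  }
  angle_deg <- as.numeric(angle_deg)
  if (length(angle_deg) != length(t_ms)) stop("t_ms and angle_deg lengths differ", call. = FALSE)
  if (length(angle_deg) && (min(angle_deg) < -1e-9 || max(angle_deg) > span + 1e-9)) {
    stop(sprintf("angle outside [0, %g] for code %s", span, code), call. = FALSE)
  }
  angle_deg <- pmin(pmax(angle_deg, 0), span)
  structure(
    list(code = code, samples = data.frame(t_ms = t_ms, angle_deg = angle_deg),
         valid = isTRUE(valid), confidence = confidence, reason = reason),
    class = "parameter_trace"
  )
}

#' @method print parameter_trace
#' @export
print.parameter_trace <- function(x, ...) {
  cat(sprintf("<parameter_trace %s> %d samples, valid=%s, confidence=%s\n",
              x$code, nrow(x$samples), x$valid, x$confidence))
  invisible(x)
}

#' Inclination of a segment against an image axis
#'
#' Unsigned angle in `[0, 180]` degrees between the directed segment
#' `p -> q` and the given axis, computed in the y-up mathematical frame
#' (image y points down, so the vertical axis means "up").
#'
#' @param p,q Points `c(x, y)` in normalized image coordinates.
#' @param axis `"vertical"` or `"horizontal"`.
#' @return Degrees in `[0, 180]`.
#' @export
#' @examples
#' segment_inclination(c(0.5, 0.9), c(0.5, 0.1), "vertical")  # 0
segment_inclination <- function(p, q, axis = c("vertical", "horizontal")) {
  axis <- match.arg(axis)
  v <- c(q[1] - p[1], -(q[2] - p[2]))
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("coincident points: segment direction undefined", call. = FALSE)
  ref <- if (axis == "vertical") c(0, 1) else c(1, 0)
  acos(pmin(pmax(sum(v * ref) / n, -1), 1)) / .d2r
}

# ---- internal per-frame geometry -----------------------------------------

.kp <- function(frame, name) {
  row <- frame$kpts[name, ]
  if (row["v"] == 0) return(NULL)
  unname(row[c("x", "y")])
}

# signed angle of the direction p -> q against horizontal, y-up, degrees
.line_angle <- function(p, q) atan2(-(q[2] - p[2]), q[1] - p[1]) / .d2r

.wrap90 <- function(a) {
  a <- (a + 180) %% 360 - 180
  if (a > 90) a <- a - 180
  if (a <= -90) a <- a + 180
  a
}

.midpoint <- function(a, b) (a + b) / 2

# unsigned angle between two vectors, degrees in [0, 180]
.vec_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) return(NA_real_)
  acos(pmin(pmax(sum(u * v) / (nu * nv), -1), 1)) / .d2r
}

# raw signed/per-side angle sources for one frame; NA when not computable
.frame_angles <- function(frame) {
  out <- c(head_tilt = NA_real_, head_rot = NA_real_, head_pitch = NA_real_,
           wsa_left = NA_real_, wsa_right = NA_real_,
           ael_left = NA_real_, ael_right = NA_real_,
           haa_left = NA_real_, haa_right = NA_real_,
           trunk_tilt = NA_real_, trunk_pitch = NA_real_)
  ls <- .kp(frame, "left_shoulder"); rs <- .kp(frame, "right_shoulder")
  lh <- .kp(frame, "left_hip"); rh <- .kp(frame, "right_hip")
  le <- .kp(frame, "left_ear"); re <- .kp(frame, "right_ear")
  ley <- .kp(frame, "left_eye"); rey <- .kp(frame, "right_eye")
  nose <- .kp(frame, "nose")
  mid_sh <- if (!is.null(ls) && !is.null(rs)) .midpoint(ls, rs)
  mid_hip <- if (!is.null(lh) && !is.null(rh)) .midpoint(lh, rh)

  # facing direction in profile view: the nose leads the mid-shoulder point
  facing <- if (!is.null(nose) && !is.null(mid_sh)) {
    f <- sign(nose[1] - mid_sh[1])
    if (f == 0) 1 else f
  } else 1

  # lateral head tilt: inter-ear (fallback inter-eye) line vs shoulder line;
  # positive when the left ear drops (tilt toward the subject's left)
  head_line <- if (!is.null(le) && !is.null(re)) list(re, le)
               else if (!is.null(ley) && !is.null(rey)) list(rey, ley)
  if (!is.null(head_line) && !is.null(ls) && !is.null(rs)) {
    out["head_tilt"] <- -.wrap90(.line_angle(head_line[[1]], head_line[[2]]) -
                                   .line_angle(rs, ls))
  }

  # head rotation: nose offset from the mid-ear point, normalized by the
  # projected inter-ear distance; exact inverse of a circular head model
  # (the tilt-compensation factor cos(tilt) removes the lateral-tilt
  # foreshortening of the nose offset)
  if (!is.null(le) && !is.null(re) && !is.null(nose)) {
    d <- sqrt(sum((le - re)^2))
    ct <- cos((if (is.na(out["head_tilt"])) 0 else out["head_tilt"]) * .d2r)
    if (d > 1e-9 && abs(ct) > 1e-6) {
      out["head_rot"] <- atan(2 * (nose[1] - .midpoint(le, re)[1]) / (d * ct)) / .d2r
    }
  }

  # trunk axis
  if (!is.null(mid_sh) && !is.null(mid_hip)) {
    d <- c(mid_sh[1] - mid_hip[1], -(mid_sh[2] - mid_hip[2]))
    out["trunk_tilt"] <- atan2(d[1], d[2]) / .d2r
    out["trunk_pitch"] <- facing * atan2(d[1], d[2]) / .d2r
    for (side in c("left", "right")) {
      sh <- .kp(frame, paste0(side, "_shoulder"))
      wr <- .kp(frame, paste0(side, "_wrist"))
      el <- .kp(frame, paste0(side, "_elbow"))
      if (!is.null(sh) && !is.null(wr)) {
        down <- c(mid_hip[1] - mid_sh[1], -(mid_hip[2] - mid_sh[2]))
        arm <- c(wr[1] - sh[1], -(wr[2] - sh[2]))
        wsa <- .vec_angle(arm, down)
        out[paste0("wsa_", side)] <- wsa
        # lateral arm elevation requires an extended (straight) elbow
        if (!is.null(el)) {
          straightness <- .vec_angle(sh - el, wr - el)
          if (!is.na(straightness) && straightness >= 165) {
            out[paste0("ael_", side)] <- min(wsa, 90)
          }
        }
      }
    }
  }

  # frontal head tilt (profile): mid-ear -> nose vs horizontal, taken
  # relative to the trunk axis so trunk inclination does not leak in
  if (!is.null(le) && !is.null(re) && !is.null(nose)) {
    total <- -facing * .wrap90(.line_angle(.midpoint(le, re), nose))
    trunk <- if (is.na(out["trunk_pitch"])) 0 else out["trunk_pitch"]
    out["head_pitch"] <- total - trunk
  }

  for (side in c("left", "right")) {
    hp <- .kp(frame, paste0(side, "_hip"))
    an <- .kp(frame, paste0(side, "_ankle"))
    if (!is.null(hp) && !is.null(an)) {
      leg <- c(an[1] - hp[1], -(an[2] - hp[2]))
      out[paste0("haa_", side)] <- min(.vec_angle(leg, c(0, -1)), 90)
    }
  }
  out
}

# which raw source and transform feed each code
.code_sample <- function(code, raw) {
  switch(code,
    LHTL = max(raw["head_tilt"], 0), LHTR = max(-raw["head_tilt"], 0),
    HRL = max(raw["head_rot"], 0), HRR = max(-raw["head_rot"], 0),
    FHT = abs(raw["head_pitch"]),
    WSAL = raw["wsa_left"], WSAR = raw["wsa_right"],
    AELL = raw["ael_left"], AELR = raw["ael_right"],
    HAAL = raw["haa_left"], HAAR = raw["haa_right"],
    LELI = raw["haa_left"], LELR = raw["haa_right"],
    LTTL = max(raw["trunk_tilt"], 0), LTTR = max(-raw["trunk_tilt"], 0),
    FTIF = max(raw["trunk_pitch"], 0), FTIB = max(-raw["trunk_pitch"], 0)
  )
}

#' Compute all parameter traces for a sequence
#'
#' Applies the per-frame angle constructions and assembles one
#' [parameter_trace()] per code. Codes not computable under the given
#' orientation are returned with `valid = FALSE` and no samples (Frontal
#' and Turned enable the frontal-plane codes, Profile the sagittal set plus
#' wrist-shoulder and hip-ankle angles); Turned traces are flagged
#' `confidence = "low"`. Frames whose required keypoints are missing are
#' skipped for the affected codes; signed sources feed the positive side's
#' code while the opposite code records 0, so both codes of a pair stay
#' defined at every sampled instant.
#'
#' @param seq A [motion_sequence()].
#' @param orientation One of [orientation_labels()].
#' @param config A [default_config()]; `smoothing_ms > 0` applies a
#'   centered moving average to each trace.
#' @return Named list of 17 [parameter_trace()] objects.
#' @export
compute_parameter_traces <- function(seq, orientation, config = default_config()) {
  orientation <- match.arg(orientation, orientation_labels())
  gate <- orientation_gating(orientation)
  ts <- timestamps(seq)
  raws <- t(vapply(seq$frames, .frame_angles, numeric(11)))
  codes <- parameter_codes()$code
  traces <- list()
  for (code in codes) {
    if (!code %in% gate$codes) {
      traces[[code]] <- parameter_trace(code, valid = FALSE,
                                        confidence = gate$confidence,
                                        reason = paste0("not computable in ",
                                                        orientation, " orientation"))
      next
    }
    vals <- vapply(seq_len(nrow(raws)), function(i) .code_sample(code, raws[i, ]),
                   numeric(1))
    keep <- !is.na(vals)
    if (!any(keep)) {
      traces[[code]] <- parameter_trace(code, valid = FALSE,
                                        confidence = gate$confidence,
                                        reason = "required keypoints never visible")
      next
    }
    v <- vals[keep]
    if (config$smoothing_ms > 0 && sum(keep) > 2) {
      halfw <- config$smoothing_ms / 2
      tt <- ts[keep]
      v <- vapply(seq_along(v), function(i) {
        mean(v[abs(tt - tt[i]) <= halfw])
      }, numeric(1))
    }
    span <- parameter_codes()[code, "span_max"]
    traces[[code]] <- parameter_trace(code, ts[keep], pmin(pmax(v, 0), span),
                                      confidence = gate$confidence)
  }
  traces
}

#' Angular velocity and acceleration of a trace
#'
#' Time derivatives by finite differences: central differences on interior
#' points and one-sided differences at the ends, in degrees per second.
#' Acceleration applies the same operator to the velocity series
#' (deg/s^2). Traces that are too short return an empty series with a
#' warning.
#'
#' @param trace A [parameter_trace()].
#' @return A data.frame with columns `t_ms` and `value`.
#' @export
angular_velocity <- function(trace) {
  s <- trace$samples
  if (nrow(s) < 2) {
    warning("trace too short for velocity (need >= 2 samples)", call. = FALSE)
    return(data.frame(t_ms = integer(0), value = numeric(0)))
  }
  data.frame(t_ms = s$t_ms, value = .fd(s$t_ms, s$angle_deg))
}

#' @rdname angular_velocity
#' @export
angular_acceleration <- function(trace) {
  s <- trace$samples
  if (nrow(s) < 3) {
    warning("trace too short for acceleration (need >= 3 samples)", call. = FALSE)
    return(data.frame(t_ms = integer(0), value = numeric(0)))
  }
  v <- .fd(s$t_ms, s$angle_deg)
  data.frame(t_ms = s$t_ms, value = .fd(s$t_ms, v))
}

# finite differences: central interior, one-sided ends; x in ms -> per second
.fd <- function(t_ms, y) {
  n <- length(y)
  t <- t_ms / 1000
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}

#' Time spent inside each angular range
#'
#' Assigns each inter-sample interval's duration to the range containing
#' its left sample (ranges are half-open `[lo, hi)`, last range closed), so
#' the per-range durations always sum to the trace duration.
#'
#' @param trace A [parameter_trace()].
#' @param ranges A [range_scheme()], or a numeric breaks vector of length
#'   `k + 1`, or a list of `c(lo, hi)` intervals that must be contiguous
#'   and cover the code's span.
#' @return Named numeric vector of durations in ms, one per range.
#' @export
time_in_ranges <- function(trace, ranges = range_scheme(trace$code)) {
  breaks <- .as_breaks(ranges, span = parameter_codes()[trace$code, "span_max"])
  s <- trace$samples
  k <- length(breaks) - 1
  out <- stats::setNames(numeric(k),
                         paste0(format(breaks[-length(breaks)]), "-", format(breaks[-1])))
  if (nrow(s) < 2) return(out)
  idx <- .range_index(s$angle_deg, breaks)
  dt <- diff(s$t_ms)
  for (i in seq_len(nrow(s) - 1)) out[idx[i]] <- out[idx[i]] + dt[i]
  out
}

.as_breaks <- function(ranges, span) {
  if (inherits(ranges, "range_scheme")) return(ranges$breaks)
  if (is.numeric(ranges) && is.null(dim(ranges))) {
    breaks <- ranges
  } else {
    if (is.list(ranges)) ranges <- do.call(rbind, ranges)
    ranges <- matrix(as.numeric(ranges), ncol = 2)
    ord <- order(ranges[, 1])
    ranges <- ranges[ord, , drop = FALSE]
    if (any(abs(ranges[-1, 1] - ranges[-nrow(ranges), 2]) > 1e-9)) {
      stop("ranges must be contiguous (no gaps or overlaps)", call. = FALSE)
    }
    breaks <- c(ranges[, 1], ranges[nrow(ranges), 2])
  }
  if (is.unsorted(breaks, strictly = TRUE)) stop("range breaks must be increasing", call. = FALSE)
  if (!missing(span) && (abs(breaks[1]) > 1e-9 || abs(breaks[length(breaks)] - span) > 1e-9)) {
    stop(sprintf("ranges must cover the code's span [0, %g]", span), call. = FALSE)
  }
  breaks
}

# half-open [lo, hi) assignment, last range closed
.range_index <- function(angle, breaks) {
  idx <- findInterval(angle, breaks, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), length(breaks) - 1L)
}

#' Postural sway
#'
#' Splits the sequence into consecutive windows of `window_ms` and reports,
#' per window, the root-mean-square Euclidean deviation of the mid-hip
#' point from its window mean, in normalized image units. A window longer
#' than the whole sequence degrades to a single whole-sequence window with
#' a warning; windows holding fewer than 2 frames report `NA`.
#'
#' @param seq A [motion_sequence()].
#' @param window_ms Window length in milliseconds.
#' @return Data.frame with `t_start_ms`, `t_end_ms`, `n`, `rms`.
#' @export
positional_stability <- function(seq, window_ms = 1000) {
  ts <- timestamps(seq)
  mid <- t(vapply(seq$frames, function(f) {
    lh <- .kp(f, "left_hip"); rh <- .kp(f, "right_hip")
    if (is.null(lh) && is.null(rh)) return(c(NA_real_, NA_real_))
    if (is.null(lh)) return(rh)
    if (is.null(rh)) return(lh)
    .midpoint(lh, rh)
  }, numeric(2)))
  span <- ts[length(ts)] - ts[1]
  if (window_ms > span) {
    warning("window longer than sequence; using a single whole-sequence window",
            call. = FALSE)
    window_ms <- span + 1
  }
  starts <- seq(ts[1], ts[length(ts)], by = window_ms)
  res <- lapply(starts, function(s0) {
    inw <- which(ts >= s0 & ts < s0 + window_ms)
    if (!length(inw)) return(NULL)
    pts <- mid[inw, , drop = FALSE]
    pts <- pts[stats::complete.cases(pts), , drop = FALSE]
    rms <- if (nrow(pts) < 2) NA_real_ else {
      ctr <- colMeans(pts)
      sqrt(mean((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2))
    }
    data.frame(t_start_ms = s0, t_end_ms = s0 + window_ms, n = length(inw), rms = rms)
  })
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}

#' Kinematic summary of one trace
#'
#' Bundles the quantities the scoring layer consumes: maximum angle,
#' velocity and acceleration series, and time-in-range durations under the
#' code's range scheme.
#'
#' @param trace A [parameter_trace()].
#' @param scheme A [range_scheme()] (defaults to the code's own).
#' @return List of class `kinematic_summary`.
#' @export
summarize_kinematics <- function(trace, scheme = range_scheme(trace$code)) {
  if (!trace$valid || nrow(trace$samples) == 0) {
    return(structure(
      list(code = trace$code, valid = FALSE, max_angle_deg = NA_real_,
           velocity = NULL, acceleration = NULL, time_in_range_ms = NULL,
           trace = trace),
      class = "kinematic_summary"
    ))
  }
  structure(
    list(
      code = trace$code, valid = TRUE,
      max_angle_deg = max(trace$samples$angle_deg),
      velocity = suppressWarnings(angular_velocity(trace)),
      acceleration = suppressWarnings(angular_acceleration(trace)),
      time_in_range_ms = time_in_ranges(trace, scheme),
      trace = trace
    ),
    class = "kinematic_summary"
  )
}
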