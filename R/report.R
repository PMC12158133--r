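#' Live mobility report
#'
#' A mobility report accumulates keypoint frames for a session, keeps a
#' running score per parameter code, and can be rendered at any time;
#' [finalize_report()] freezes the last updated scores as the final
#' evaluation. Feeding the frames in several batches or in one batch
#' produces identical finalized reports.
#'
#' @param orientation One of [orientation_labels()] (typically from
#'   [sequence_orientation()]).
#' @param config A [default_config()].
#' @param with_weight Session flag: exercise performed under load.
#' @param subject_id Opaque identifier.
#' @return Object of class `mobility_report` (unfinalized).
#' @export
mobility_report <- function(orientation, config = default_config(),
                            with_weight = FALSE, subject_id = "anon") {
  orientation <- match.arg(orientation, orientation_labels())
  structure(
    list(orientation = orientation, config = config, with_weight = with_weight,
         subject_id = subject_id, frames = list(), finalized = FALSE),
    class = "mobility_report"
  )
}

#' Update a report with new frames
#'
#' Appends a batch of frames (later than everything already seen) to the
#' session. An empty batch is a no-op; updating a finalized report is an
#' error.
#'
#' @param report A [mobility_report()].
#' @param frames A [motion_sequence()] or list of [keypoint_frame()]
#'   objects.
#' @return The updated report.
#' @export
update_report <- function(report, frames) {
  stopifnot(inherits(report, "mobility_report"))
  if (report$finalized) stop("cannot update a finalized report", call. = FALSE)
  if (inherits(frames, "motion_sequence")) frames <- frames$frames
  if (length(frames) == 0) return(report)
  new_ts <- vapply(frames, function(f) f$t_ms, integer(1))
  if (length(report$frames)) {
    last <- report$frames[[length(report$frames)]]$t_ms
    if (min(new_ts) <= last) {
      stop("batch timestamps must follow the frames already recorded", call. = FALSE)
    }
  }
  if (length(frames) > 1 && any(diff(sort(new_ts)) <= 0)) {
    stop("duplicate timestamps in batch", call. = FALSE)
  }
  report$frames <- c(report$frames, frames[order(new_ts)])
  report
}

# score every code from the accumulated frames
.report_scores <- function(report) {
  cfg <- report$config
  traces <- if (length(report$frames)) {
    compute_parameter_traces(
      motion_sequence(report$frames, with_weight = report$with_weight,
                      subject_id = report$subject_id),
      report$orientation, cfg
    )
  } else {
    stats::setNames(
      lapply(parameter_codes()$code, parameter_trace,
             valid = FALSE, reason = "no frames recorded"),
      parameter_codes()$code
    )
  }
  scores <- lapply(traces, score_parameter,
                   band_constant = isTRUE(cfg$band_constant_scores))
  list(traces = traces, scores = scores)
}

#' Finalize a report
#'
#' Freezes the last updated scores as the final evaluation; any later
#' update is an error.
#'
#' @param report A [mobility_report()].
#' @return The finalized, immutable report.
#' @export
finalize_report <- function(report) {
  stopifnot(inherits(report, "mobility_report"))
  if (report$finalized) return(report)
  report$final <- .report_scores(report)
  report$finalized <- TRUE
  report
}

# assemble the full report structure (used by render and accessors)
.report_body <- function(report) {
  res <- if (report$finalized) report$final else .report_scores(report)
  scores <- res$scores
  cfg <- report$config
  renorm <- isTRUE(cfg$renormalize_gated)
  parts <- c("Head", "Arms", "Legs", "Torso")
  part_scores <- stats::setNames(
    lapply(parts, function(p) part_score(scores, body_part_spec(p), renormalize = renorm)),
    parts
  )
  per_code <- lapply(scores, function(s) {
    tr <- res$traces[[s$code]]
    tir <- if (tr$valid && nrow(tr$samples) > 1) {
      as.list(time_in_ranges(tr))
    } else NULL
    list(Pi = round(s$Pi, 6), traffic = s$traffic,
         ranges_visited = s$ranges_visited,
         max_angle_deg = if (is.na(s$max_angle_deg)) NULL else round(s$max_angle_deg, 6),
         not_assessed = s$not_assessed,
         time_in_range_ms = tir)
  })
  list(
    subject_id = report$subject_id,
    orientation = report$orientation,
    with_weight = report$with_weight,
    finalized = report$finalized,
    n_frames = length(report$frames),
    parameters = per_code,
    part_scores = lapply(part_scores, round, digits = 6),
    global_score = round(global_score(scores, body_denominator = cfg$body_denominator,
                                      renormalize = renorm), 6),
    clinical_scales = map_to_clinical_scales(scores)
  )
}

#' Render a report
#'
#' Deterministic serialization of the report: orientation, per-code score,
#' traffic light, ranges visited and time-in-range, part scores, global
#' score and the clinical-scale sub-reports. `"json"` returns a JSON
#' string; `"text"` a human-readable character vector with traffic-light
#' tags matching the per-code traffic fields one-to-one.
#'
#' @param report A [mobility_report()] (live or finalized).
#' @param format `"json"` or `"text"`.
#' @return Character scalar (json) or character vector (text).
#' @export
render_report <- function(report, format = c("json", "text")) {
  format <- match.arg(format)
  body <- .report_body(report)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA,
                                         null = "null")))
  }
  lines <- c(
    sprintf("Mobility report for %s%s", body$subject_id,
            if (body$finalized) " (final)" else " (live)"),
    sprintf("Orientation: %s | with weight: %s | frames: %d",
            body$orientation, body$with_weight, body$n_frames),
    "",
    sprintf("%-6s %8s %-8s %-10s %s", "code", "Pi", "traffic", "ranges", "")
  )
  for (code in names(body$parameters)) {
    p <- body$parameters[[code]]
    lines <- c(lines, sprintf(
      "%-6s %8.2f [%s]%s %-10s %s",
      code, p$Pi, toupper(p$traffic),
      strrep(" ", 8 - nchar(p$traffic) - 2),
      paste(p$ranges_visited, collapse = ","),
      if (p$not_assessed) "not assessed" else ""
    ))
  }
  lines <- c(lines, "", "Part scores:")
  for (p in names(body$part_scores)) {
    lines <- c(lines, sprintf("  %-6s %.3f", p, body$part_scores[[p]]))
  }
  lines <- c(lines, sprintf("Global score: %.3f", body$global_score), "",
             "Clinical scales:")
  for (nm in names(body$clinical_scales)) {
    sc <- body$clinical_scales[[nm]]
    lines <- c(lines, sprintf(
      "  %s: aggregate %.3f from {%s}%s", nm,
      if (is.na(sc$aggregate_score)) 0 else sc$aggregate_score,
      paste(sc$contributing_codes, collapse = ","),
      if (length(sc$missing_inputs)) {
        paste0("; missing: ", paste(sc$missing_inputs, collapse = ", "))
      } else ""
    ))
  }
  lines
}
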