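# mapping of pipeline outputs onto standardized clinical assessment scales:
# which parameter codes and kinematic quantities inform each scale, which
# required inputs the pipeline cannot provide, and which of the five common
# clinical dimensions (strength, stability, mobility, pain, coordination)
# each scale covers
.clinical_scale_table <- function() {
  dim5 <- function(st, sb, mo, pa, co) {
    c(strength = st, stability = sb, mobility = mo, pain = pa, coordination = co)
  }
  list(
    `Motor Index` = list(
      purpose = "Evaluate motor strength and mobility",
      codes = c("WSAL", "WSAR", "HAAL", "HAAR"),
      quantities = c("time_in_range"),
      missing = character(0),
      dimensions = dim5(TRUE, FALSE, FALSE, FALSE, FALSE)
    ),
    `Modified Ashworth Scale` = list(
      purpose = "Measure muscle resistance to passive movement and stiffness",
      codes = c("WSAL", "WSAR", "HAAL", "HAAR"),
      quantities = c("angular_velocity", "trajectory", "with_weight"),
      missing = c("facial expressions of pain"),
      dimensions = dim5(TRUE, FALSE, FALSE, FALSE, FALSE)
    ),
    `Berg Balance Scale` = list(
      purpose = "Assess balance and postural control",
      codes = c("LHTL", "LHTR", "HRL", "HRR", "FHT", "LTTL", "LTTR", "FTIF", "FTIB"),
      quantities = c("postural_stability"),
      missing = character(0),
      dimensions = dim5(FALSE, TRUE, TRUE, FALSE, FALSE)
    ),
    `Functional Ambulation Classification` = list(
      purpose = "Assess independence during gait and limb coordination",
      codes = c("HAAL", "HAAR", "LELI", "LELR"),
      quantities = c("postural_stability"),
      missing = c("gait phase segmentation and timing"),
      dimensions = dim5(FALSE, TRUE, TRUE, FALSE, FALSE)
    ),
    `Catherine Bergego Scale` = list(
      purpose = "Evaluate neglect and affected limb usage",
      codes = c("WSAL", "WSAR", "AELL", "AELR", "HAAL", "HAAR", "LELI", "LELR"),
      quantities = c("left_right_asymmetry", "keypoint_monitoring"),
      missing = character(0),
      dimensions = dim5(FALSE, TRUE, TRUE, FALSE, TRUE)
    ),
    `Barthel Index` = list(
      purpose = "Assess ability to perform activities of daily living",
      codes = c("LTTL", "LTTR", "FTIF", "FTIB"),
      quantities = c("time_in_range", "postural_stability"),
      missing = character(0),
      dimensions = dim5(TRUE, TRUE, TRUE, FALSE, FALSE)
    ),
    `Lawton and Brody Scale` = list(
      purpose = "Assess instrumental activities of daily living",
      codes = c("LTTL", "LTTR", "FTIF", "FTIB"),
      quantities = c("time_in_range", "postural_stability"),
      missing = character(0),
      dimensions = dim5(FALSE, TRUE, TRUE, FALSE, FALSE)
    ),
    `Disability Rating Scale` = list(
      purpose = "Evaluate disability severity and recovery prognosis",
      codes = parameter_codes()$code,
      quantities = c("time_in_range", "postural_stability"),
      missing = character(0),
      dimensions = dim5(FALSE, TRUE, TRUE, FALSE, FALSE)
    ),
    `NIH Stroke Scale` = list(
      purpose = "Evaluate stroke severity",
      codes = c("WSAL", "WSAR", "AELL", "AELR", "HAAL", "HAAR", "LELI", "LELR",
                "LTTL", "LTTR", "FTIF", "FTIB"),
      quantities = c("postural_stability"),
      missing = c("facial expressions"),
      dimensions = dim5(TRUE, TRUE, TRUE, TRUE, TRUE)
    )
  )
}

#' Map parameter scores onto clinical assessment scales
#'
#' Builds one structured sub-report per supported clinical scale: the
#' contributing parameter codes and kinematic quantities the pipeline can
#' supply, required inputs it cannot (listed as missing rather than
#' imputed, e.g. facial pain cues), the five-dimension coverage flags
#' (strength / stability / mobility / pain / coordination), and the
#' aggregate of the contributing normalized scores
#' (`sum(Pi) / (75 * n_codes)`). No scale points (e.g. a Berg 0-56 total)
#' are produced: the mapping identifies which quantities inform each scale,
#' it does not define a conversion formula.
#'
#' @param scores Named list of [score_parameter()] results for all 17
#'   codes.
#' @return Named list of sub-reports.
#' @export
map_to_clinical_scales <- function(scores) {
  lapply(.clinical_scale_table(), function(sc) {
    contributing <- intersect(sc$codes, names(scores))
    pis <- vapply(scores[contributing], function(s) s$Pi, numeric(1))
    assessed <- !vapply(scores[contributing], function(s) isTRUE(s$not_assessed),
                        logical(1))
    list(
      purpose = sc$purpose,
      contributing_codes = contributing,
      assessed_codes = contributing[assessed],
      quantities = sc$quantities,
      missing_inputs = sc$missing,
      dimensions = sc$dimensions,
      aggregate_score = if (length(contributing)) {
        sum(pis) / (75 * length(contributing))
      } else NA_real_
    )
  })
}
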