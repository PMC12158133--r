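test_that("range classification follows the half-open convention", {
  head <- range_scheme("LHTL")
  expect_identical(classify_range(45, head), 1L)
  expect_identical(classify_range(30, head), 1L)  # boundary -> upper range
  expect_identical(classify_range(90, head), 2L)  # last range closed
  expect_identical(classify_range(0, head), 0L)
  wsa <- range_scheme("WSAL")
  expect_identical(classify_range(c(59.9, 60, 120, 180), wsa), c(0L, 1L, 2L, 2L))
  expect_warning(k <- classify_range(95, head), "clamped")
  expect_identical(k, 2L)
})

test_that("parameter scores map the running maximum angle onto 0-75", {
  mk <- function(angles, dt = 100) {
    parameter_trace("LHTL", seq_along(angles) * dt, angles)
  }
  expect_equal(score_parameter(mk(c(0, 50, 90)))$Pi, 75)
  expect_equal(score_parameter(mk(c(0, 0)))$Pi, 0)
  expect_equal(score_parameter(mk(c(10, 45, 20)))$Pi, 25 + 25 * (45 - 30) / 30) # 37.5
  # running max keeps Pi non-decreasing even when the angle drops
  s <- score_parameter(mk(c(10, 70, 10, 80, 5)))
  expect_true(all(diff(s$history$Pi) >= 0))
  expect_equal(s$Pi, 25 * 2 + 25 * (80 - 60) / 30)
  # instantaneous angles touched only the outer ranges
  expect_setequal(s$ranges_visited, c(0L, 2L))
  expect_identical(s$traffic, "orange")
  # band-constant variant steps to the band ceiling
  expect_equal(score_parameter(mk(c(10, 45, 20)), band_constant = TRUE)$Pi, 50)
  # property: bounds and monotonicity on seeded random traces
  set.seed(151)
  for (i in 1:25) {
    tr <- mk(runif(sample(3:30, 1), 0, 90))
    sc <- score_parameter(tr)
    expect_true(all(sc$history$Pi >= 0 & sc$history$Pi <= 75))
    expect_true(all(diff(sc$history$Pi) >= -1e-12))
  }
  # invalid trace: zero, red, flagged
  gated <- parameter_trace("FHT", valid = FALSE, reason = "gated")
  sg <- score_parameter(gated)
  expect_equal(sg$Pi, 0)
  expect_identical(sg$traffic, "red")
  expect_true(sg$not_assessed)
})

test_that("traffic light follows the three-range truth table", {
  expect_identical(traffic_light(c(0, 1, 2)), "green")
  expect_identical(traffic_light(c(0, 1)), "orange")
  expect_identical(traffic_light(c(1, 2)), "orange")
  expect_identical(traffic_light(1), "red")
  expect_identical(traffic_light(integer(0)), "red")
  # consistency: green implies the top range was entered, so Pi >= 50
  tr <- parameter_trace("LHTL", c(0, 100, 200), c(10, 40, 70))
  s <- score_parameter(tr)
  expect_identical(s$traffic, "green")
  expect_gte(s$Pi, 50)
})

test_that("part and global scores normalize as specified", {
  max_trace <- function(code) {
    span <- parameter_codes()[code, "span_max"]
    parameter_trace(code, c(0, 1000), c(0, span))
  }
  all_codes <- parameter_codes()$code
  full <- lapply(all_codes, function(cd) score_parameter(max_trace(cd)))
  names(full) <- all_codes
  for (part in c("Head", "Arms", "Legs", "Torso")) {
    expect_equal(part_score(full, body_part_spec(part)), 1.0)
  }
  expect_equal(global_score(full), 1.0)

  zero <- lapply(all_codes, function(cd) {
    score_parameter(parameter_trace(cd, c(0, 1000), c(0, 0)))
  })
  names(zero) <- all_codes
  expect_equal(part_score(zero, body_part_spec("Head")), 0)
  expect_equal(global_score(zero), 0)

  # worked head example: {75, 37.5, 0, 0, 0} -> 112.5 / 375 = 0.3
  head_scores <- zero
  head_scores$LHTL <- score_parameter(parameter_trace("LHTL", c(0, 1), c(0, 90)))
  head_scores$LHTR <- score_parameter(parameter_trace("LHTR", c(0, 1), c(0, 45)))
  expect_equal(part_score(head_scores, body_part_spec("Head")), 112.5 / 375)

  # coherence oracle: global numerator equals the sum of part numerators
  set.seed(161)
  rand <- lapply(all_codes, function(cd) {
    span <- parameter_codes()[cd, "span_max"]
    score_parameter(parameter_trace(cd, c(0, 500, 1000), runif(3, 0, span)))
  })
  names(rand) <- all_codes
  num <- sum(vapply(rand, function(s) s$Pi, numeric(1)))
  parts <- vapply(c("Head", "Arms", "Legs", "Torso"), function(p) {
    sp <- body_part_spec(p)
    part_score(rand, sp) * sp$denominator
  }, numeric(1))
  expect_equal(sum(parts), num, tolerance = 1e-9)
  expect_equal(global_score(rand), num / 1275, tolerance = 1e-12)
  # the printed alternative denominator is selectable
  expect_equal(global_score(rand, body_denominator = 1575), num / 1575)
  expect_error(part_score(rand[-1], body_part_spec("Head")), "missing")
})

test_that("reports are batch-invariant and freeze on finalize", {
  res <- generate_sequence(
    trajectory_spec(list(head_tilt_deg = rbind(c(0, 0), c(2000, 80)),
                         arm_abduction_left_deg = rbind(c(0, 0), c(2000, 120))),
                    duration_ms = 2000, fps = 10),
    noise_sd = 0.005, seed = 171
  )
  frames <- res$sequence$frames

  one <- mobility_report("Frontal")
  one <- update_report(one, frames)
  one <- finalize_report(one)

  two <- mobility_report("Frontal")
  two <- update_report(two, frames[1:7])
  two <- update_report(two, list())          # empty update is a no-op
  two <- update_report(two, frames[8:20])
  two <- finalize_report(two)

  expect_identical(render_report(one, "json"), render_report(two, "json"))
  expect_identical(render_report(one, "json"), render_report(one, "json"))

  expect_error(update_report(one, frames), "finalized")
  expect_error(update_report(mobility_report("Frontal"),
                             c(frames[5], frames[3])), NA)  # sorts within batch
  rev_rep <- update_report(mobility_report("Frontal"), frames[5])
  expect_error(update_report(rev_rep, frames[3]), "follow")
})

test_that("rendered text mirrors the traffic fields one-to-one", {
  res <- generate_sequence(
    trajectory_spec(list(trunk_tilt_deg = rbind(c(0, 0), c(1000, 70))),
                    duration_ms = 1000, fps = 10),
    noise_sd = 0, seed = 181
  )
  rep <- finalize_report(update_report(mobility_report("Frontal"), res$sequence))
  body <- jsonlite::fromJSON(render_report(rep, "json"))
  txt <- render_report(rep, "text")
  for (code in names(body$parameters)) {
    ln <- grep(paste0("^", code, " "), txt, value = TRUE)
    expect_length(ln, 1)
    expect_match(ln, toupper(body$parameters[[code]]$traffic), fixed = TRUE)
  }
  expect_identical(body$parameters$LTTL$traffic, "green")
  expect_true(body$parameters$FHT$not_assessed)
})

test_that("clinical sub-reports map codes, dimensions and missing inputs", {
  codes <- parameter_codes()$code
  scores <- lapply(codes, function(cd) {
    score_parameter(parameter_trace(cd, c(0, 1000),
                                    c(0, parameter_codes()[cd, "span_max"])))
  })
  names(scores) <- codes
  scales <- map_to_clinical_scales(scores)
  expect_length(scales, 9)  # 8 table rows; Barthel / Lawton-Brody split in two

  mi <- scales[["Motor Index"]]
  expect_setequal(mi$contributing_codes, c("WSAL", "WSAR", "HAAL", "HAAR"))
  expect_true("time_in_range" %in% mi$quantities)
  expect_equal(mi$aggregate_score, 1.0)

  barthel <- scales[["Barthel Index"]]
  expect_false(barthel$dimensions[["pain"]])
  expect_true(barthel$dimensions[["strength"]])

  mas <- scales[["Modified Ashworth Scale"]]
  expect_true("facial expressions of pain" %in% mas$missing_inputs)
  nihss <- scales[["NIH Stroke Scale"]]
  expect_true(all(nihss$dimensions))
})
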