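test_that("segment_inclination matches hand trigonometry", {
  expect_equal(segment_inclination(c(0.5, 0.9), c(0.5, 0.1), "vertical"), 0)
  expect_equal(segment_inclination(c(0.2, 0.5), c(0.8, 0.5), "vertical"), 90)
  # p=(0,0) q=(1,1) in image coords points down-right: arctangent oracle
  # gives 45 deg off horizontal, hence 135 off the (upward) vertical
  expect_equal(segment_inclination(c(0, 0), c(1, 1), "horizontal"),
               atan(1) / (pi / 180))
  expect_equal(segment_inclination(c(0, 0), c(1, 1), "vertical"), 180 - 45)
  expect_error(segment_inclination(c(0.3, 0.3), c(0.3, 0.3)), "coincident")
})

test_that("noise-free trajectories are recovered within 1 degree at yaw 0", {
  schedules <- list(
    list(head_tilt_deg = rbind(c(0, 0), c(2000, 40))),
    list(head_rot_deg = rbind(c(0, -50), c(2000, 50))),
    list(arm_abduction_left_deg = rbind(c(0, 0), c(2000, 170))),
    list(arm_abduction_right_deg = 90),
    list(leg_abduction_left_deg = rbind(c(0, 0), c(2000, 80))),
    list(trunk_tilt_deg = rbind(c(0, -30), c(2000, 30)))
  )
  for (sched in schedules) {
    res <- generate_sequence(trajectory_spec(sched, duration_ms = 2000, fps = 25),
                             noise_sd = 0, seed = 1)
    traces <- compute_parameter_traces(res$sequence, "Frontal")
    for (code in names(traces)) {
      tr <- traces[[code]]
      if (!tr$valid || nrow(tr$samples) == 0) next
      expect_lt(trace_error(tr, res$ground_truth[[code]]), 1)
    }
  }
  # sagittal codes in profile view
  prof <- generate_sequence(
    trajectory_spec(list(yaw_deg = 90, head_pitch_deg = rbind(c(0, 0), c(2000, 40)),
                         trunk_pitch_deg = rbind(c(0, -25), c(2000, 25))),
                    duration_ms = 2000, fps = 25),
    noise_sd = 0, seed = 1
  )
  ptr <- compute_parameter_traces(prof$sequence, "Profile")
  for (code in c("FHT", "FTIF", "FTIB")) {
    expect_lt(trace_error(ptr[[code]], prof$ground_truth[[code]]), 1)
  }
})

test_that("ramps recover exactly: LHTL rises while LHTR stays 0; AEL caps at 90", {
  res <- generate_sequence(
    trajectory_spec(list(head_tilt_deg = rbind(c(0, 0), c(2000, 40))),
                    duration_ms = 2000, fps = 25),
    noise_sd = 0, seed = 1
  )
  tr <- compute_parameter_traces(res$sequence, "Frontal")
  expect_equal(tr$LHTL$samples$angle_deg[1], 0, tolerance = 1e-6)
  # last frame sits at 1960 ms on the 0 -> 40 deg / 2000 ms ramp
  expect_equal(max(tr$LHTL$samples$angle_deg), 40 * 1960 / 2000, tolerance = 1e-6)
  expect_true(all(tr$LHTR$samples$angle_deg == 0))

  arm <- generate_sequence(
    trajectory_spec(list(arm_abduction_left_deg = 90), duration_ms = 1000, fps = 10),
    noise_sd = 0, seed = 1
  )
  atr <- compute_parameter_traces(arm$sequence, "Frontal")
  expect_equal(atr$WSAL$samples$angle_deg, rep(90, 10), tolerance = 1e-6)
  expect_equal(atr$AELL$samples$angle_deg, rep(90, 10), tolerance = 1e-6)
  # above 90 the WSA keeps rising but AEL stays capped
  arm2 <- generate_sequence(
    trajectory_spec(list(arm_abduction_left_deg = 150), duration_ms = 500, fps = 10),
    noise_sd = 0, seed = 1
  )
  atr2 <- compute_parameter_traces(arm2$sequence, "Frontal")
  expect_equal(max(atr2$WSAL$samples$angle_deg), 150, tolerance = 1e-6)
  expect_equal(max(atr2$AELL$samples$angle_deg), 90)
})

test_that("orientation gating invalidates out-of-plane codes", {
  seq <- generate_sequence(trajectory_spec(list(), duration_ms = 200, fps = 25),
                           noise_sd = 0, seed = 1)$sequence
  prof <- compute_parameter_traces(seq, "Profile")
  expect_false(prof$LHTL$valid)
  expect_false(prof$LHTR$valid)
  expect_equal(nrow(prof$LHTL$samples), 0)
  expect_match(prof$LHTL$reason, "Profile")
  front <- compute_parameter_traces(seq, "Frontal")
  expect_false(front$FHT$valid)
  expect_true(front$LHTL$valid)
  turned <- compute_parameter_traces(seq, "Turned")
  expect_true(turned$LHTL$valid)
  expect_identical(turned$LHTL$confidence, "low")
})

test_that("mirroring a sequence swaps left/right code traces exactly", {
  res <- generate_sequence(
    trajectory_spec(list(head_tilt_deg = rbind(c(0, -30), c(1000, 30)),
                         arm_abduction_left_deg = 45,
                         leg_abduction_right_deg = 20),
                    duration_ms = 1000, fps = 10),
    noise_sd = 0, seed = 1
  )
  tr <- compute_parameter_traces(res$sequence, "Frontal")
  trm <- compute_parameter_traces(mirror_sequence(res$sequence), "Frontal")
  swaps <- list(c("LHTL", "LHTR"), c("HRL", "HRR"), c("WSAL", "WSAR"),
                c("AELL", "AELR"), c("HAAL", "HAAR"), c("LELI", "LELR"),
                c("LTTL", "LTTR"))
  for (pair in swaps) {
    expect_equal(tr[[pair[1]]]$samples$angle_deg, trm[[pair[2]]]$samples$angle_deg,
                 tolerance = 1e-9)
    expect_equal(tr[[pair[2]]]$samples$angle_deg, trm[[pair[1]]]$samples$angle_deg,
                 tolerance = 1e-9)
  }
})

test_that("angular derivatives match the finite-difference oracle", {
  const <- parameter_trace("LHTL", seq(0, 900, by = 100), rep(20, 10))
  expect_true(all(angular_velocity(const)$value == 0))

  # linear ramp 0 -> 90 over 3000 ms: 30 deg/s everywhere
  ramp <- parameter_trace("WSAL", seq(0, 3000, by = 100), seq(0, 90, length.out = 31))
  v <- angular_velocity(ramp)
  expect_equal(v$value, rep(30, 31), tolerance = 1e-9)
  a <- angular_acceleration(ramp)
  expect_equal(a$value, rep(0, 31), tolerance = 1e-9)

  # seeded random trace vs the independent difference-quotient oracle
  set.seed(121)
  t_ms <- cumsum(sample(20:80, 40, replace = TRUE))
  y <- cumsum(rnorm(40, sd = 2))
  y <- abs(y) / max(abs(y)) * 80
  tr <- parameter_trace("LTTL", t_ms, y)
  expect_equal(angular_velocity(tr)$value, oracle_fd(t_ms, y), tolerance = 1e-9)
  expect_equal(angular_acceleration(tr)$value,
               oracle_fd(t_ms, oracle_fd(t_ms, y)), tolerance = 1e-9)

  # time reversal negates the reversed velocity series
  tr_rev <- parameter_trace("LTTL", max(t_ms) - rev(t_ms), rev(y))
  expect_equal(angular_velocity(tr_rev)$value, -rev(angular_velocity(tr)$value),
               tolerance = 1e-9)

  short <- parameter_trace("LHTL", 0L, 5)
  expect_warning(v0 <- angular_velocity(short), "too short")
  expect_equal(nrow(v0), 0)
})

test_that("time-in-range conserves duration and matches the brute-force oracle", {
  sch <- range_scheme("LHTL")
  tr <- parameter_trace("LHTL", c(0, 2000), c(45, 45))
  expect_equal(unname(time_in_ranges(tr, sch)), c(0, 2000, 0))

  tr2 <- parameter_trace("LHTL", c(0, 1000, 2000), c(10, 70, 70))
  expect_equal(unname(time_in_ranges(tr2, sch)), c(1000, 0, 1000))

  set.seed(131)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    t_ms <- cumsum(sample(10:100, n, replace = TRUE))
    ang <- runif(n, 0, 90)
    trc <- parameter_trace("HAAL", t_ms, ang)
    got <- time_in_ranges(trc, sch)
    expect_equal(unname(got), oracle_time_in_ranges(t_ms, ang, sch$breaks))
    expect_equal(sum(got), t_ms[n] - t_ms[1])  # conservation
  }

  expect_error(time_in_ranges(tr, list(c(0, 30), c(40, 90))), "contiguous")
  expect_error(time_in_ranges(tr, c(0, 30, 60)), "cover")
})

test_that("postural stability reports windowed RMS sway", {
  mk <- function(xs, dt = 40) {
    motion_sequence(lapply(seq_along(xs), function(i) {
      frame_with(list(left_hip = c(xs[i] - 0.05, 0.55),
                      right_hip = c(xs[i] + 0.05, 0.55)),
                 t_ms = (i - 1) * dt)
    }))
  }
  # static: zero sway
  st <- positional_stability(mk(rep(0.5, 30)), window_ms = 400)
  expect_true(all(st$rms == 0))

  # sinusoid of amplitude a: RMS = a / sqrt(2) over full-period windows
  a <- 0.03
  n_per <- 20
  xs <- 0.5 + a * sin(2 * pi * (0:(2 * n_per - 1)) / n_per)
  sin_seq <- mk(xs, dt = 50)  # period 1000 ms, two periods
  ss <- positional_stability(sin_seq, window_ms = 1000)
  expect_equal(ss$rms, rep(a / sqrt(2), nrow(ss)), tolerance = 1e-9)

  # seeded jitter vs the direct-formula oracle (single window)
  set.seed(141)
  xj <- 0.5 + rnorm(25, sd = 0.01)
  jseq <- mk(xj)
  expect_warning(sj <- positional_stability(jseq, window_ms = 10000), "single")
  expect_equal(sj$rms, oracle_rms(cbind(xj, rep(0.55, 25))), tolerance = 1e-9)
})

test_that("kinematic summaries bundle the scoring inputs", {
  res <- generate_sequence(
    trajectory_spec(list(head_tilt_deg = rbind(c(0, 0), c(1000, 80))),
                    duration_ms = 1000, fps = 25),
    noise_sd = 0, seed = 1
  )
  tr <- compute_parameter_traces(res$sequence, "Frontal")$LHTL
  ks <- summarize_kinematics(tr)
  expect_equal(ks$max_angle_deg, max(tr$samples$angle_deg))
  expect_equal(sum(ks$time_in_range_ms),
               max(tr$samples$t_ms) - min(tr$samples$t_ms))
  gated <- parameter_trace("FHT", valid = FALSE, reason = "gated")
  ksg <- summarize_kinematics(gated)
  expect_false(ksg$valid)
  expect_true(is.na(ksg$max_angle_deg))
})
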