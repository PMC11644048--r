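test_that("protocol generation is balanced and seed-reproducible", {
  p15 <- generate_protocol(protocol_spec("unimpaired_15", order_seed = 1))
  expect_equal(nrow(p15), 15L)
  expect_true(all(table(p15$finger) == 3L))
  p30 <- generate_protocol(protocol_spec("stroke_30", order_seed = 7))
  expect_equal(nrow(p30), 30L)
  expect_true(all(table(p30$finger) == 6L))
  # same seed twice: identical; the target_index matches the session level
  expect_identical(p15, generate_protocol(protocol_spec("unimpaired_15",
                                                        order_seed = 1)))
  pip <- generate_protocol(protocol_spec("stroke_30", level = "PIP",
                                         order_seed = 2))
  lvl <- landmark_level("PIP")$indices
  expect_equal(pip$target_index, unname(lvl[pip$finger]))
  expect_error(protocol_spec("unimpaired_15", n_trials = 16),
               "not divisible|must equal")
})

test_that("each finger leads the protocol with frequency about 1/5", {
  firsts <- vapply(1:400, function(s)
    generate_protocol(protocol_spec("unimpaired_15", order_seed = s))$finger[1],
    character(1))
  freq <- table(firsts) / length(firsts)
  expect_equal(length(freq), 5L)
  expect_true(all(freq > 0.13 & freq < 0.28))  # 1/5 +/- sampling error
})

test_that("protocol generation leaves the global RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_protocol(protocol_spec("stroke_30", order_seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("start trigger is the first frame inside the circle", {
  # fingertip walks right along y = 100, entering the circle on the way
  n <- 60
  frames <- lapply(seq_len(n), function(i) {
    pts <- cbind(matrix(5, 21, 2), 0)
    pts[9, 1:2] <- c(10 * i, 100)
    landmark_frame((i - 1) / 30, "pointing", "right", pts)
  })
  st <- frame_stream(frames, fps = 30)
  gate <- start_gate(circle_center_px = c(420, 100), circle_radius_px = 15)
  hit <- detect_start(st, gate)
  expect_true(hit$triggered)
  expect_equal(hit$frame, 41L)            # first i with |10 i - 420| <= 15
  expect_equal(hit$t_trigger, 40 / 30)
  expect_equal(hit$t_go, 40 / 30 + 3)

  far <- start_gate(circle_center_px = c(10000, 10000), circle_radius_px = 5)
  miss <- detect_start(st, far)
  expect_false(miss$triggered)
  expect_true(is.na(miss$t_trigger))

  at0 <- start_gate(circle_center_px = c(10, 100), circle_radius_px = 5)
  expect_equal(detect_start(st, at0)$t_trigger, 0)  # already inside at frame 1
})

test_that("stop detection satisfies the documented two-criterion rule", {
  crit <- stop_criteria()  # 15 cm, 2 s / 60 samples at 30 fps, SD < 5 cm
  expect_equal(crit$window_samples, 60L)

  # constant at 0: stops at the first full window
  expect_equal(detect_stop(rep(0, 120), crit),
               list(index = 60L, reason = "stopped"))
  # constant at 20 cm: zero SD but proximity fails
  expect_equal(detect_stop(rep(20, 120), crit)$reason, "never")
  # shorter than the window: flagged, not an error
  expect_equal(detect_stop(rep(0, 30), crit)$reason, "too_short")

  # ramp 40 -> 10 over 60 samples then flat at 10: check against brute force
  x <- c(seq(40, 10, length.out = 60), rep(10, 60))
  got <- detect_stop(x, crit)
  expect_equal(got$index, bf_detect_stop(x, crit))
  expect_true(x[got$index] <= 15)
})

test_that("stop detection equals the brute-force windowed-SD scan", {
  crit_small <- stop_criteria(window_seconds = 1, fps = 30)
  for (seed in 1:150) {
    x <- random_error_series(seed)
    expect_identical(detect_stop(x, crit_small)$index,
                     bf_detect_stop(x, crit_small),
                     info = paste("seed", seed))
  }
})

test_that("raising the SD threshold never delays the stop", {
  for (seed in 1:40) {
    x <- random_error_series(seed)
    idx <- vapply(c(1, 2, 5, 10), function(thr) {
      out <- detect_stop(x, stop_criteria(sd_threshold_cm = thr,
                                          window_seconds = 1, fps = 30))$index
      if (is.na(out)) Inf else as.numeric(out)
    }, numeric(1))
    d <- diff(idx)  # NaN = never stopped at either threshold: not a delay
    expect_true(all(d <= 0 | is.nan(d)), info = paste("seed", seed))
  }
})

test_that("occlusion polygon covers every landmark", {
  st <- render_stream(pointing_scenario(), seed = 4)
  fr <- get_frame(st, "target", 10)
  poly <- occlusion_polygon(fr, margin_px = 10)
  expect_true(all(points_in_polygon(poly, fr$pts[, 1:2], strict = TRUE)))
  # margin 0: hull vertices are landmark points
  poly0 <- occlusion_polygon(fr, margin_px = 0)
  for (i in seq_len(nrow(poly0))) {
    d <- sqrt(rowSums((fr$pts[, 1:2] - matrix(poly0[i, ], 21, 2,
                                              byrow = TRUE))^2))
    expect_lt(min(d), 1e-9)
  }
  expect_true(all(points_in_polygon(poly0, fr$pts[, 1:2])))
})

test_that("collinear landmarks fall back to a padded bounding box", {
  pts <- cbind(seq(10, 210, by = 10), seq(5, 105, by = 5), 0)  # one line
  fr <- landmark_frame(0, "target", "left", pts)
  poly <- occlusion_polygon(fr, margin_px = 3)
  expect_equal(nrow(poly), 4L)
  expect_true(all(points_in_polygon(poly, pts[, 1:2], strict = TRUE)))
})

test_that("manual correction annotations override and validate", {
  x <- c(seq(30, 6, length.out = 20), rep(6, 40), seq(6, 0, length.out = 10),
         rep(0, 50))
  expect_equal(truncate_correction(x, stop_index = 80, annotation = 50),
               list(index = 50L, mode = "manual"))
  expect_error(truncate_correction(x, stop_index = 80, annotation = 90),
               "after the detected stop")
  # heuristic off by default: stop index unchanged, flagged "none"
  expect_equal(truncate_correction(x, stop_index = 80),
               list(index = 80L, mode = "none"))
})

test_that("the plateau heuristic truncates before a late correction", {
  crit <- stop_criteria(sd_threshold_cm = 1, window_seconds = 2, fps = 30)
  # approach to 6 cm, a 1 s plateau, then a step correction down to 0
  x <- c(seq(30, 6, length.out = 15), rep(6, 30), rep(0, 60))
  stop_idx <- detect_stop(x, crit)$index
  got <- truncate_correction(x, stop_idx, heuristic = TRUE, criteria = crit)
  expect_equal(got$mode, "heuristic")
  expect_true(got$index >= 16 && got$index <= 45)   # inside the 6 cm plateau
  expect_equal(x[got$index], 6)
  # equals the brute-force plateau finder
  oracle <- bf_truncate(x, stop_idx, crit)
  expect_equal(got$index, oracle$index)

  # monotone-then-flat series with no correction: unchanged
  y <- c(seq(30, 2, length.out = 30), rep(2, 90))
  sy <- detect_stop(y, crit)$index
  expect_equal(truncate_correction(y, sy, heuristic = TRUE, criteria = crit),
               list(index = sy, mode = "none"))
})

test_that("the plateau heuristic matches its brute-force oracle on random series", {
  crit <- stop_criteria(sd_threshold_cm = 2, window_seconds = 1, fps = 30)
  for (seed in 101:140) {
    x <- random_error_series(seed)
    stp <- detect_stop(x, crit)$index
    if (is.na(stp)) stp <- length(x)
    got <- truncate_correction(x, stp, heuristic = TRUE, criteria = crit)
    oracle <- bf_truncate(x, stp, crit)
    expect_equal(got$index, oracle$index, info = paste("seed", seed))
    expect_equal(got$mode, oracle$mode, info = paste("seed", seed))
  }
})

test_that("score_trial produces a complete per-trial record", {
  prof <- calibration_profile(54.84, source = "measured_photo")
  st <- render_stream(pointing_scenario(bias_cm = c(3, 0), tremor_sd_cm = 0),
                      seed = 2)
  res <- score_trial(st, 8, prof)
  expect_equal(res$final_error_cm, 3.0, tolerance = 1e-9)
  expect_equal(res$stop_reason, "stopped")
  expect_equal(res$truncation, "none")
  expect_equal(res$n_gap_frames, 0L)
  expect_equal(res$level, "TIP")

  # a trial that never settles inside the radius yields a flagged NA
  far <- render_stream(pointing_scenario(bias_cm = c(40, 0), tremor_sd_cm = 0),
                       seed = 2)
  res_far <- score_trial(far, 8, prof)
  expect_true(is.na(res_far$final_error_cm))
  expect_equal(res_far$stop_reason, "never")
})
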