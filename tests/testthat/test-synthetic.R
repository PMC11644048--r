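prof_default <- calibration_profile(54.84, source = "measured_photo")

test_that("the template reproduces the configured metric hand size", {
  for (hs in c(49.87, 54.84, 60)) {
    tpl <- hand_template(handsize_cm = hs)
    expect_equal(hand_size_px(tpl$pts_cm), hs)
  }
  tpl_pip <- hand_template(handsize_cm = 50, level = "PIP")
  expect_equal(hand_size_px(tpl_pip$pts_cm, level = "PIP"), 50)
})

test_that("the scored error recovers the constructed endpoint truth", {
  # exact hit: zero bias, zero noise
  hit <- render_stream(pointing_scenario(tremor_sd_cm = 0), seed = 1)
  expect_lt(score_trial(hit, 8, prof_default)$final_error_cm, 1e-9)
  # pure bias
  b <- render_stream(pointing_scenario(bias_cm = c(3, 0), tremor_sd_cm = 0),
                     seed = 1)
  expect_equal(score_trial(b, 8, prof_default)$final_error_cm, 3.0,
               tolerance = 1e-9)
  # bias + noise: matches the realised truth stored in the metadata
  bn <- render_stream(pointing_scenario(bias_cm = c(1, -2), noise_sd_cm = 1,
                                        tremor_sd_cm = 0), seed = 8)
  expect_equal(score_trial(bn, 8, prof_default)$final_error_cm,
               bn$metadata$truth_error_cm, tolerance = 1e-9)
  # other target fingers and levels resolve to the right landmark
  pip <- render_stream(pointing_scenario(target_finger = "ring", level = "PIP",
                                         bias_cm = c(0, 2), tremor_sd_cm = 0),
                       template = hand_template(54.84, level = "PIP"), seed = 2)
  prof_pip <- calibration_profile(54.84, source = "measured_photo",
                                  level = "PIP")
  expect_equal(score_trial(pip, 14, prof_pip)$final_error_cm, 2.0,
               tolerance = 1e-9)
})

test_that("halving the camera scale mid-trial leaves the cm series unchanged", {
  sc_fix <- pointing_scenario(bias_cm = c(4, 1), tremor_sd_cm = 0)
  sc_drift <- pointing_scenario(bias_cm = c(4, 1), tremor_sd_cm = 0,
                                camera_scale = 10, camera_scale_end = 5)
  fixed <- render_stream(sc_fix, seed = 3)
  drift <- render_stream(sc_drift, seed = 3)
  s_fix <- build_error_series(fixed, 8, prof_default, smooth_k = 1)
  s_drift <- build_error_series(drift, 8, prof_default, smooth_k = 1)
  expect_equal(s_drift$error_cm, s_fix$error_cm, tolerance = 1e-9)
  n <- length(s_fix$error_px)
  expect_equal(s_drift$error_px[n] / s_fix$error_px[n], 0.5, tolerance = 1e-9)
  expect_equal(s_drift$handsize_px[n] / s_fix$handsize_px[n], 0.5,
               tolerance = 1e-9)
})

test_that("measured pixel hand size over camera scale returns the template size", {
  for (seed in 1:5) {
    scale <- runif(1, 4, 20)
    st <- render_stream(pointing_scenario(camera_scale = scale,
                                          tremor_sd_cm = 0), seed = seed)
    hs_px <- hand_size_px(get_frame(st, "target", 1))
    expect_equal(hs_px / scale, 54.84, tolerance = 1e-9)
  }
})

test_that("fake-hand sessions use the 60 cm cardboard hand", {
  st <- render_fake_hand_session(camera_scale = 12)
  fr <- get_frame(st, "target", 1)
  # calibration on the rendered fake hand recovers 60 cm given true px/cm
  expect_equal(hand_size_px(fr) / 12, 60, tolerance = 1e-9)
  # static and tremor-free
  expect_equal(st$hands$target$pts[1, , ], st$hands$target$pts[10, , ])
  # round-trips like any other valid stream
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_stream(st, path)
  expect_streams_equal(read_stream(path), st, tol = 1e-9)

  # pointing at the fake hand with bias b scores |b|
  sc <- pointing_scenario(bias_cm = c(0, 2.5))
  pt <- render_fake_hand_session(scenario = sc, seed = 5)
  prof_fake <- calibration_profile(source = "fake_hand")
  expect_equal(score_trial(pt, 8, prof_fake)$final_error_cm, 2.5,
               tolerance = 1e-9)
})

test_that("rendered streams survive the write/read round trip", {
  st <- render_stream(pointing_scenario(noise_sd_cm = 1), seed = 17)
  for (ext in c(".jsonl", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_stream(st, path)
    expect_streams_equal(read_stream(path), st, tol = 1e-9)
  }
})

test_that("a correction scenario triggers the plateau heuristic", {
  sc <- pointing_scenario(bias_cm = c(6, 0), tremor_sd_cm = 0, hold_s = 3.5,
                          correction = list(delay_s = 0.5, duration_s = 0.3,
                                            to_cm = c(0, 0)))
  st <- render_stream(sc, seed = 1)
  series <- build_error_series(st, 8, prof_default)
  crit <- stop_criteria(sd_threshold_cm = 1)
  stp <- detect_stop(series, crit)
  trunc <- truncate_correction(series, stp$index, heuristic = TRUE,
                               criteria = crit)
  expect_equal(trunc$mode, "heuristic")
  # truncation lands on or just after the pre-correction plateau: the scored
  # error reflects the biased first endpoint, not the corrected one
  expect_gt(final_error(series, trunc$index), 4)
  expect_lt(final_error(series, stp$index), 1)
})

test_that("cohorts are reproducible and groups separate by noise level", {
  groups <- list(low = list(n = 2, noise_sd_cm = 1, n_trials = 2),
                 high = list(n = 2, noise_sd_cm = 3, n_trials = 2))
  a <- render_cohort(groups, seed = 5)
  b <- render_cohort(groups, seed = 5)
  expect_identical(a$truth, b$truth)
  expect_streams_equal(a$streams$low[[1]][[1]], b$streams$low[[1]][[1]])

  empty <- render_cohort(list(none = list(n = 0, noise_sd_cm = 1)), seed = 1)
  expect_equal(nrow(empty$truth), 0L)
  expect_length(empty$streams$none, 0L)

  # scored group means order by the generating noise SD across seeds
  correct <- vapply(1:6, function(seed) {
    co <- render_cohort(list(low = list(n = 6, noise_sd_cm = 1, n_trials = 3),
                             high = list(n = 6, noise_sd_cm = 3, n_trials = 3)),
                        seed = seed)
    means <- vapply(c("low", "high"), function(g) {
      errs <- unlist(lapply(co$streams[[g]], function(p)
        vapply(p, function(st)
          score_trial(st, 8, prof_default)$final_error_cm, numeric(1))))
      mean(errs, na.rm = TRUE)
    }, numeric(1))
    means["high"] > means["low"]
  }, logical(1))
  expect_true(all(correct))
})

test_that("a shared latent deficit couples the two assessments", {
  sim <- simulate_validity_cohort(n = 16, shared = 0.8, seed = 2)
  expect_equal(nrow(sim$participants), 16L)
  expect_gt(sim$validity$r, 0)
  expect_identical(sim, simulate_validity_cohort(n = 16, shared = 0.8, seed = 2))

  # more shared variance, stronger correlation (averaged over seeds)
  r_at <- function(shared) mean(vapply(1:12, function(s)
    simulate_validity_cohort(n = 16, shared = shared, seed = s)$validity$r,
    numeric(1)))
  expect_gt(r_at(0.9), r_at(0.1))
})
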