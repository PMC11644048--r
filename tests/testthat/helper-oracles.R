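# Brute-force oracles and fixture builders, independent of the package's
# vectorised implementations.

# O(n*w) stop-detector scan: population SD of every trailing window.
bf_detect_stop <- function(x, criteria) {
  w <- criteria$window_samples
  n <- length(x)
  if (n < w) return(NA_integer_)
  for (i in w:n) {
    win <- x[(i - w + 1L):i]
    s <- sqrt(mean((win - mean(win))^2))
    if (x[i] <= criteria$proximity_radius_cm && s < criteria$sd_threshold_cm)
      return(i)
  }
  NA_integer_
}

# Brute-force correction-plateau finder mirroring the documented heuristic:
# last index of the first trailing-SD-stable run before renewed movement.
bf_truncate <- function(x, stop_index, criteria, plateau_seconds = 0.3) {
  w <- max(2L, as.integer(round(plateau_seconds * criteria$fps)))
  x <- x[seq_len(stop_index)]
  stable <- logical(stop_index)
  for (i in seq_len(stop_index)) {
    if (i < w) next
    win <- x[(i - w + 1L):i]
    stable[i] <- sqrt(mean((win - mean(win))^2)) < criteria$sd_threshold_cm
  }
  if (!any(stable)) return(list(index = stop_index, mode = "none"))
  first <- which(stable)[1L]
  run_end <- first
  while (run_end < stop_index && stable[run_end + 1L]) run_end <- run_end + 1L
  if (run_end < stop_index) list(index = run_end, mode = "heuristic")
  else list(index = stop_index, mode = "none")
}

# Random centimeter error series mixing approach ramps, plateaus and noise,
# exercising both stopping and non-stopping cases.
random_error_series <- function(seed) {
  set.seed(seed)
  n <- sample(70:220, 1)
  kind <- sample(c("ramp_settle", "walk", "constant", "noisy_far"), 1)
  x <- switch(kind,
    ramp_settle = {
      n1 <- sample(20:(n - 10), 1)
      lvl <- runif(1, 0, 20)
      c(seq(runif(1, 25, 45), lvl, length.out = n1),
        rep(lvl, n - n1)) + abs(rnorm(n, 0, runif(1, 0, 3)))
    },
    walk = abs(cumsum(rnorm(n, 0, runif(1, 0.5, 3))) + runif(1, 5, 30)),
    constant = rep(runif(1, 0, 25), n) + abs(rnorm(n, 0, runif(1, 0, 1))),
    noisy_far = runif(n, 16, 60)
  )
  pmax(x, 0)
}

# Hand-built two-hand stream: static target hand (a scaled hand template),
# pointing fingertip at a fixed pixel separation from the target landmark.
manual_stream <- function(n = 90, sep_px = c(30, 0), target_index = 8L,
                          camera_scale = 10, fps = 30,
                          handsize_cm = 60) {
  template <- propoint::hand_template(handsize_cm = handsize_cm)
  target_cm <- sweep(template$pts_cm, 2, c(40, 40), `+`)
  target_px <- target_cm * camera_scale
  tip <- target_px[target_index + 1L, ] + sep_px
  point_px <- sweep(target_px, 2, target_px[9L, ] - tip, `-`)  # rigid shift
  frames <- list()
  for (i in seq_len(n)) {
    t <- (i - 1) / fps
    frames[[length(frames) + 1L]] <-
      propoint::landmark_frame(t, "target", "left", cbind(target_px, 0))
    frames[[length(frames) + 1L]] <-
      propoint::landmark_frame(t, "pointing", "right", cbind(point_px, 0))
  }
  propoint::frame_stream(frames, fps = fps)
}

# Small random-but-valid stream for round-trip property tests.
random_stream <- function(seed) {
  set.seed(seed)
  n <- sample(3:12, 1)
  frames <- list()
  for (h in c("target", "pointing")) {
    base <- matrix(runif(21 * 3, 0, 600), 21, 3)
    for (i in seq_len(n)) {
      frames[[length(frames) + 1L]] <- propoint::landmark_frame(
        (i - 1) / 30 + runif(1, 0, 1e-3), h,
        if (h == "target") "left" else "right",
        abs(base + matrix(rnorm(63, 0, 2), 21, 3)), runif(1))
    }
  }
  propoint::frame_stream(frames, fps = 30,
                         metadata = list(session = paste0("s", seed)))
}

expect_streams_equal <- function(a, b, tol = 1e-12) {
  testthat::expect_equal(names(a$hands), names(b$hands))
  for (h in names(a$hands)) {
    testthat::expect_equal(a$hands[[h]]$t, b$hands[[h]]$t, tolerance = tol)
    testthat::expect_equal(a$hands[[h]]$pts, b$hands[[h]]$pts, tolerance = tol)
    testthat::expect_equal(a$hands[[h]]$conf, b$hands[[h]]$conf, tolerance = tol)
    testthat::expect_identical(a$hands[[h]]$side, b$hands[[h]]$side)
  }
  testthat::expect_equal(a$fps, b$fps)
}
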