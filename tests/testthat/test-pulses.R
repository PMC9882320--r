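mk_trace <- function(z, dt = 5, spot_id = 1L, channel = "target") {
  list(times = (seq_along(z) - 1) * dt, z = z, spot_id = spot_id,
       channel = channel)
}

test_that("sub-threshold traces yield no pulses", {
  expect_equal(nrow(call_pulses(mk_trace(rep(0.5, 50)), threshold = 3)), 0)
})

test_that("frame arithmetic follows the inclusive-grid duration convention", {
  z <- rep(0, 30)
  z[11:20] <- 10                       # frames 10..19 (0-based)
  p <- call_pulses(mk_trace(z), threshold = 3)
  expect_equal(nrow(p), 1)
  expect_equal(p$onset, 50)
  expect_equal(p$duration, 50)         # 10 frames x 5 s
  expect_equal(p$end, 100)
  expect_false(p$censored)
  expect_equal(p$n_frames, 10L)
})

test_that("a run reaching the final frame is right-censored", {
  z <- rep(0, 30)
  z[25:30] <- 10
  p <- call_pulses(mk_trace(z), threshold = 3)
  expect_true(p$censored)
  expect_equal(p$end, 150)             # onset 120 + 6 frames x 5 s
})

test_that("single-frame gaps merge and short runs are discarded", {
  z <- rep(0, 40)
  z[c(5:9, 11:15)] <- 10               # 1-frame gap at frame index 9
  p <- call_pulses(mk_trace(z), threshold = 3, max_gap_frames = 1)
  expect_equal(nrow(p), 1)
  expect_equal(p$n_frames, 11L)        # gap frame counted in the span
  p2 <- call_pulses(mk_trace(z), threshold = 3, max_gap_frames = 0)
  expect_equal(nrow(p2), 2)
  z2 <- rep(0, 40); z2[7] <- 10
  expect_equal(nrow(call_pulses(mk_trace(z2), threshold = 3,
                                min_on_frames = 2)), 0)
  expect_equal(nrow(call_pulses(mk_trace(z2), threshold = 3,
                                min_on_frames = 1)), 1)
})

test_that("raising the threshold never increases total ON time", {
  set.seed(1)
  for (i in 1:30) {
    z <- rnorm(200) + ifelse(runif(200) < 0.2, 8, 0)
    tr <- mk_trace(z)
    on_time <- vapply(c(2, 3, 4, 5, 6), function(th)
      sum(call_pulses(tr, th, min_on_frames = 1, max_gap_frames = 0)$duration),
      numeric(1))
    expect_true(all(diff(on_time) <= 0))
  }
})

test_that("ON and OFF time partition the trace span exactly", {
  set.seed(2)
  for (i in 1:20) {
    z <- rnorm(100) + ifelse(runif(100) < 0.3, 8, 0)
    p <- call_pulses(mk_trace(z), threshold = 4, min_on_frames = 1,
                     max_gap_frames = 0)
    on_frames <- sum(p$n_frames)
    expect_equal(on_frames, sum(z >= 4))
  }
})

test_that("pulses called on one spot-channel are disjoint and ordered", {
  set.seed(3)
  z <- rnorm(300) + ifelse(runif(300) < 0.25, 9, 0)
  p <- call_pulses(mk_trace(z), threshold = 4)
  if (nrow(p) > 1) {
    expect_true(all(diff(p$onset) > 0))
    expect_true(all(p$onset[-1] >= p$end[-nrow(p)]))
  }
})

test_that("frame_schedule matches the printed acquisition counts", {
  expect_identical(frame_schedule(2700, 5), 541L)
  expect_identical(frame_schedule(0, 5), 1L)
  expect_identical(frame_schedule(60, 5), 13L)
  expect_error(frame_schedule(13, 5), "divisible")
})

test_that("called pulses agree with ground truth on rendered movies", {
  ## full-stack check at comfortable SNR: per-spot pulse counts match truth
  ## for >= 90% of spots (truth pulses shorter than one frame excluded)
  p <- kinetic_params(k_on_A = 4, k_off_A = 25, k_on_B = 0, duration = 1200)
  gt <- simulate_pulse_trains(p, 40, seed = 13, image_size = 128)
  opt <- optics_params(image_size = 128,
                       photons_per_fluor = photons_for_snr(8))
  mv <- render_movie(gt, opt, seed = 14, channels = c("template", "target"))
  spots <- detect_spots(mv$template)
  traces <- extract_traces(mv$target, spots)
  called <- call_pulses_all(traces, threshold = 4, min_on_frames = 1)
  m <- match_spots(spots$spots, gt$spot_positions, radius = 2)
  truth_n <- truth_visible_counts(gt, 40)
  called_n <- table(factor(called$spot_id,
                           levels = spots$spots$spot_id))
  agree <- mean(as.integer(called_n) == as.integer(truth_n[m$match]))
  expect_gte(agree, 0.9)
})
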