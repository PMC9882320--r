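test_that("empty noiseless field renders as flat background", {
  truth <- make_truth(data.frame(spot_id = integer(0), x = numeric(0),
                                 y = numeric(0)),
                      params = kinetic_params(duration = 120))
  opt <- optics_params(image_size = 32, background_level = 0,
                       read_noise_sd = 0)
  mv <- render_movie(truth, opt, seed = 1, channels = "template")
  expect_true(all(mv$template$frames == 0))
  expect_equal(mv$template$times, c(0, 60, 120))
})

test_that("a permanent template spot does not move without drift", {
  truth <- make_truth(data.frame(spot_id = 1L, x = 20.3, y = 14.7),
                      params = kinetic_params(duration = 300))
  mv <- render_movie(truth, quiet_optics(48), seed = 1,
                     channels = "template")
  cents <- t(apply(mv$template$frames, 3, function(fr) {
    w <- fr / sum(fr)
    c(x = sum(w * (col(fr) - 1)), y = sum(w * (row(fr) - 1)))
  }))
  ## shot noise alone limits localization to ~psf_sigma/sqrt(photons) per frame
  expect_lt(max(dist(cents)), 0.15)
  expect_lt(abs(mean(cents[, "x"]) - 20.3), 0.05)
  expect_lt(abs(mean(cents[, "y"]) - 14.7), 0.05)
})

test_that("linear drift displaces the centroid by the expected geometry", {
  ## 0.02 px/frame on the fast 5-s grid over 540 frames -> 10.8 px total
  truth <- make_truth(data.frame(spot_id = 1L, x = 16, y = 40),
                      params = kinetic_params(duration = 2700))
  opt <- quiet_optics(64, drift = c(0.02 / 5, 0))
  mv <- render_movie(truth, opt, seed = 1, channels = "template")
  fr1 <- mv$template$frames[, , 1]
  frN <- mv$template$frames[, , dim(mv$template$frames)[3]]
  cx <- function(fr) sum(fr * (col(fr) - 1)) / sum(fr)
  expect_lt(abs((cx(frN) - cx(fr1)) - 10.8), 0.1)
})

test_that("summed spot intensity scales linearly with photons_per_fluor", {
  pos <- data.frame(spot_id = 1:4, x = c(10, 25, 10, 25), y = c(10, 10, 25, 25))
  photons <- c(500, 1000, 2000)
  tot <- vapply(photons, function(ph) {
    truth <- make_truth(pos, params = kinetic_params(duration = 0.001,
                                                     dt_fast = 0.001,
                                                     dt_slow = 0.001))
    opt <- optics_params(image_size = 36, background_level = 50,
                         read_noise_sd = 3, photons_per_fluor = ph)
    mv <- render_movie(truth, opt, seed = 8, channels = "template")
    sum(mv$template$frames[, , 1]) - 50 * 36^2
  }, numeric(1))
  slope <- stats::coef(stats::lm(tot ~ photons))[2]
  expect_lt(abs(slope - 4) / 4, 0.05)   # 4 spots: slope = 4 photons/photon
})

test_that("protein pulses appear only on their scheduled frames", {
  truth <- make_truth(
    data.frame(spot_id = 1L, x = 12, y = 12),
    pulses = data.frame(spot_id = 1L, channel = "target",
                        onset = 10, end = 30),
    params = kinetic_params(duration = 60))
  mv <- render_movie(truth, quiet_optics(32), seed = 1, channels = "target")
  bright <- apply(mv$target$frames, 3, sum) > 1
  expect_equal(mv$target$times[bright], c(10, 15, 20, 25))  # [10, 30) grid
})

test_that("a truncated pulse stays visible through the final frame", {
  truth <- make_truth(
    data.frame(spot_id = 1L, x = 12, y = 12),
    pulses = data.frame(spot_id = 1L, channel = "target",
                        onset = 40, end = 60, truncated = TRUE),
    params = kinetic_params(duration = 60))
  mv <- render_movie(truth, quiet_optics(32), seed = 1, channels = "target")
  bright <- apply(mv$target$frames, 3, sum) > 1
  expect_true(bright[length(bright)])
})

test_that("bleach_rate = 1 leaves exactly one bright exposure per pulse", {
  truth <- make_truth(
    data.frame(spot_id = 1L, x = 12, y = 12),
    pulses = data.frame(spot_id = 1L, channel = "target",
                        onset = 0, end = 100, truncated = FALSE),
    params = kinetic_params(duration = 100, bleach_rate = 1))
  mv <- render_movie(truth, quiet_optics(32), seed = 2, channels = "target")
  bright <- apply(mv$target$frames, 3, sum) > 1
  expect_equal(sum(bright), 1)
  expect_true(bright[1])
})

test_that("out-of-field spots warn and render clipped", {
  truth <- make_truth(data.frame(spot_id = 1L, x = -3, y = 10),
                      params = kinetic_params(duration = 60))
  expect_warning(mv <- render_movie(truth, quiet_optics(32), seed = 1,
                                    channels = "template"),
                 "outside the field")
  expect_true(all(is.finite(mv$template$frames)))
})

test_that("movie TIFF round trip preserves schedule and intensities", {
  truth <- make_truth(data.frame(spot_id = 1L, x = 10, y = 12),
                      params = kinetic_params(duration = 120))
  opt <- optics_params(image_size = 32, photons_per_fluor = 800)
  mv <- render_movie(truth, opt, seed = 3, channels = "template")
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "tpl.tif")
  write_movie(mv$template, f)
  back <- read_movie(f)
  expect_equal(back$times, mv$template$times)
  expect_equal(back$channel, "template")
  expect_lt(max(abs(back$frames - mv$template$frames)) /
              max(mv$template$frames), 1e-4)
})
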