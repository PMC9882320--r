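roll_mat <- function(m, dr, dc) {
  m[((seq_len(nrow(m)) - 1 - dr) %% nrow(m)) + 1,
    ((seq_len(ncol(m)) - 1 - dc) %% ncol(m)) + 1]
}

test_that("identical frames give zero drift; integer rolls are recovered", {
  set.seed(1)
  f0 <- matrix(rnorm(48 * 48), 48, 48)
  st <- movie_stack(array(rep(f0, 3), c(48, 48, 3)), c(0, 60, 120))
  for (m in c("fft_xcorr", "translation_fit")) {
    dp <- estimate_drift(st, method = m)
    expect_equal(dp$dx_px, c(0, 0, 0), tolerance = 1e-6)
    expect_equal(dp$dy_px, c(0, 0, 0), tolerance = 1e-6)
  }
  f1 <- roll_mat(f0, -2, 3)   # content moved dy = -2, dx = +3
  st2 <- movie_stack(array(c(f0, f1), c(48, 48, 2)), c(0, 60))
  for (m in c("fft_xcorr", "translation_fit")) {
    dp <- estimate_drift(st2, method = m)
    expect_equal(dp$dx_px[2], 3, tolerance = 0.01)
    expect_equal(dp$dy_px[2], -2, tolerance = 0.01)
  }
})

test_that("zero-variance frames raise a registration error", {
  st <- movie_stack(array(5, c(32, 32, 2)), c(0, 60))
  expect_error(estimate_drift(st), "zero-variance")
})

test_that("subpixel drift on a rendered field is recovered within 0.15 px", {
  ## 0.4 px per 60-s template frame
  set.seed(2)
  pos <- data.frame(spot_id = 1:12,
                    x = runif(12, 8, 55), y = runif(12, 8, 55))
  truth <- make_truth(pos, params = kinetic_params(duration = 600))
  opt <- optics_params(image_size = 64, drift = c(0.4 / 60, -0.25 / 60),
                       photons_per_fluor = 3000)
  mv <- render_movie(truth, opt, seed = 3, channels = "template")
  dp <- estimate_drift(mv$template, upsample = 10)
  true_dx <- 0.4 / 60 * mv$template$times
  true_dy <- -0.25 / 60 * mv$template$times
  expect_lt(max(abs(dp$dx_px - true_dx)), 0.15)
  expect_lt(max(abs(dp$dy_px - true_dy)), 0.15)
})

test_that("drift estimation is translation-equivariant", {
  set.seed(3)
  f0 <- matrix(rnorm(48 * 48), 48, 48)
  f1 <- roll_mat(f0, 1, -2)
  base <- movie_stack(array(c(f0, f1), c(48, 48, 2)), c(0, 60))
  shifted <- movie_stack(array(c(roll_mat(f0, 2, 4), roll_mat(f1, 2, 4)),
                               c(48, 48, 2)), c(0, 60))
  d1 <- estimate_drift(base)
  d2 <- estimate_drift(shifted)
  ## a constant shift of every frame leaves relative drift unchanged
  expect_equal(d2$dx_px, d1$dx_px, tolerance = 0.1)
  expect_equal(d2$dy_px, d1$dy_px, tolerance = 0.1)
})

test_that("apply_drift with a zero path is the identity", {
  set.seed(4)
  st <- movie_stack(array(rnorm(32 * 32 * 2), c(32, 32, 2)), c(0, 60))
  zero <- structure(data.frame(time_s = c(0, 60), dx_px = 0, dy_px = 0),
                    class = c("drift_path", "data.frame"))
  out <- apply_drift(st, zero)
  expect_equal(out$frames, st$frames)
  expect_true(all(attr(out, "valid")))
})

test_that("integer drift correction equals a rolled frame inside the mask", {
  set.seed(5)
  f0 <- matrix(rnorm(32 * 32), 32, 32)
  f1 <- roll_mat(f0, 0, 5)   # content moved +5 columns
  st <- movie_stack(array(c(f0, f1), c(32, 32, 2)), c(0, 60))
  path <- structure(data.frame(time_s = c(0, 60), dx_px = c(0, 5),
                               dy_px = c(0, 0)),
                    class = c("drift_path", "data.frame"))
  out <- apply_drift(st, path)
  valid <- attr(out, "valid")[, , 2]
  expect_equal(out$frames[, , 2][valid], f0[valid])
  expect_false(all(valid))          # the wrapped 5 columns are invalid
})

test_that("apply then re-estimate leaves residual drift below 0.1 px", {
  set.seed(6)
  pos <- data.frame(spot_id = 1:10, x = runif(10, 8, 55), y = runif(10, 8, 55))
  truth <- make_truth(pos, params = kinetic_params(duration = 600))
  opt <- optics_params(image_size = 64, drift = c(0.3 / 60, 0.2 / 60),
                       photons_per_fluor = 3000)
  mv <- render_movie(truth, opt, seed = 7, channels = "template")
  dp <- estimate_drift(mv$template, upsample = 20)
  corr <- apply_drift(mv$template, dp)
  resid <- estimate_drift(corr, upsample = 20)
  expect_lt(max(abs(resid$dx_px)), 0.1)
  expect_lt(max(abs(resid$dy_px)), 0.1)
})

test_that("shift interpolation is linear with constant extrapolation", {
  path <- structure(data.frame(time_s = c(0, 60, 120),
                               dx_px = c(0, 1, 3), dy_px = c(0, -1, -2)),
                    class = c("drift_path", "data.frame"))
  out <- interpolate_drift(path, c(-10, 30, 90, 200))
  expect_equal(out$dx_px, c(0, 0.5, 2, 3))
  expect_equal(out$dy_px, c(0, -0.5, -1.5, -2))
})
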