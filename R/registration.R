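#' Estimate lateral stage drift from the template channel
#'
#' Per-frame translation of every template frame relative to the first one,
#' estimated either by fast-Fourier-transform cross-correlation with
#' subpixel refinement on a locally upsampled correlation surface
#' (`"fft_xcorr"`, default) or by the integer correlation peak with
#' parabolic refinement (`"translation_fit"`).  The reference frame is the
#' first template frame (spots are identified from the template channel
#' anchored at acquisition start), so the shift there is exactly `(0, 0)`.
#'
#' The estimated shift of frame k is the displacement of its content
#' relative to frame 0: a spot at `(x, y)` in frame 0 sits at
#' `(x + dx, y + dy)` in frame k.
#'
#' @param template_stack a [movie_stack()] with at least 2 frames.
#' @param method `"fft_xcorr"` or `"translation_fit"`.
#' @param upsample subpixel refinement factor for `"fft_xcorr"` (>= 1; shifts
#'   are resolved to `1/upsample` px).
#' @return An object of class `drift_path`: a data.frame with columns
#'   `time_s, dx_px, dy_px`, one row per template frame.
#' @seealso [apply_drift()], [interpolate_drift()]
#' @export
estimate_drift <- function(template_stack,
                           method = c("fft_xcorr", "translation_fit"),
                           upsample = 10) {
  method <- match.arg(method)
  stopifnot(inherits(template_stack, "movie_stack"))
  nf <- n_frames(template_stack)
  if (nf < 2) stop("need at least 2 template frames")
  v <- apply(template_stack$frames, 3, function(m) stats::var(as.vector(m)))
  if (any(v == 0)) stop("zero-variance frame(s): cannot register")

  ref <- template_stack$frames[, , 1]
  Fr <- stats::fft(ref - mean(ref))
  shifts <- matrix(0, nf, 2)
  for (k in 2:nf) {
    img <- template_stack$frames[, , k]
    Fi <- stats::fft(img - mean(img))
    R <- Fr * Conj(Fi)
    shifts[k, ] <- switch(method,
      fft_xcorr = xcorr_peak_upsampled(R, upsample),
      translation_fit = xcorr_peak_parabolic(R))
  }
  structure(data.frame(time_s = template_stack$times,
                       dx_px = -shifts[, 2], dy_px = -shifts[, 1]),
            class = c("drift_path", "data.frame"))
}

## R = fft(ref) * Conj(fft(img)).  The real cross-correlation surface
## cc(m) = sum_n ref[n] img[n + m] is ifft(R); its argmax m* satisfies
## img = ref shifted by -m* (row, col order).  Helpers return m* so the
## caller negates to get the content shift.
xcorr_surface <- function(R) {
  Re(stats::fft(R, inverse = TRUE)) / length(R)
}

wrap_index <- function(i, n) ifelse(i > n / 2, i - n, i)

xcorr_peak_int <- function(cc) {
  w <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  c(wrap_index(w[1] - 1, nrow(cc)), wrap_index(w[2] - 1, ncol(cc)))
}

xcorr_peak_parabolic <- function(R) {
  cc <- xcorr_surface(R)
  m <- xcorr_peak_int(cc)
  n1 <- nrow(cc); n2 <- ncol(cc)
  at <- function(i, j) cc[(i %% n1) + 1, (j %% n2) + 1]
  refine <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else 0.5 * (cm - cp) / den
  }
  dy <- refine(at(m[1] - 1, m[2]), at(m[1], m[2]), at(m[1] + 1, m[2]))
  dx <- refine(at(m[1], m[2] - 1), at(m[1], m[2]), at(m[1], m[2] + 1))
  m + c(dy, dx)
}

## Upsampled evaluation of the correlation surface on a (2*span*u + 1)^2
## fine grid around the integer peak, by direct local DFT of R.
xcorr_peak_upsampled <- function(R, upsample, span = 1.5) {
  m <- xcorr_peak_int(xcorr_surface(R))
  if (upsample <= 1) return(m)
  n1 <- nrow(R); n2 <- ncol(R)
  f1 <- wrap_index(0:(n1 - 1), n1)
  f2 <- wrap_index(0:(n2 - 1), n2)
  uu <- m[1] + seq(-span, span, by = 1 / upsample)
  vv <- m[2] + seq(-span, span, by = 1 / upsample)
  E1 <- exp(2i * pi * outer(uu, f1) / n1)           # |uu| x n1
  E2 <- exp(2i * pi * outer(f2, vv) / n2)           # n2 x |vv|
  cc <- Re(E1 %*% R %*% E2) / length(R)
  w <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  c(uu[w[1]], vv[w[2]])
}

#' Interpolate a drift path onto arbitrary timestamps
#'
#' Linear interpolation of the per-template-frame shifts onto (typically
#' faster) protein-channel timestamps, with constant extrapolation beyond the
#' template schedule.  Drift is slow relative to the template interval, so
#' linear interpolation between template frames is adequate.
#'
#' @param path a `drift_path` from [estimate_drift()].
#' @param times timestamps in seconds.
#' @return A data.frame `time_s, dx_px, dy_px` at the requested times.
#' @export
interpolate_drift <- function(path, times) {
  stopifnot(inherits(path, "drift_path"))
  data.frame(
    time_s = times,
    dx_px = stats::approx(path$time_s, path$dx_px, times, rule = 2)$y,
    dy_px = stats::approx(path$time_s, path$dy_px, times, rule = 2)$y)
}

#' Correct a stack for estimated drift
#'
#' Translates every frame by minus the (interpolated) shift at its timestamp
#' with bilinear subpixel interpolation, undoing the stage drift so all
#' frames share the reference-frame coordinates.  Pixels whose source falls
#' outside the field are filled with the frame median and flagged invalid in
#' the `valid` attribute (a `ny x nx x n_frames` logical array).
#'
#' @param stack a [movie_stack()].
#' @param path a `drift_path` covering (via interpolation/extrapolation) the
#'   stack timestamps.
#' @return The corrected [movie_stack()] with a `valid` attribute.
#' @export
apply_drift <- function(stack, path) {
  stopifnot(inherits(stack, "movie_stack"))
  sh <- interpolate_drift(path, stack$times)
  out <- stack$frames
  valid <- array(TRUE, dim(out))
  for (k in seq_len(n_frames(stack))) {
    tr <- translate_frame(stack$frames[, , k], sh$dx_px[k], sh$dy_px[k])
    out[, , k] <- tr$frame
    valid[, , k] <- tr$valid
  }
  res <- stack
  res$frames <- out
  attr(res, "valid") <- valid
  res
}

## Sample frame at (r + dy, c + dx) bilinearly: shifts content by (-dx, -dy).
translate_frame <- function(fr, dx, dy) {
  n1 <- nrow(fr); n2 <- ncol(fr)
  iy <- floor(dy); fy <- dy - iy
  ix <- floor(dx); fx <- dx - ix
  g <- function(oy, ox) {
    rows <- seq_len(n1) + iy + oy
    cols <- seq_len(n2) + ix + ox
    okr <- rows >= 1 & rows <= n1
    okc <- cols >= 1 & cols <= n2
    m <- matrix(NA_real_, n1, n2)
    m[okr, okc] <- fr[rows[okr], cols[okc]]
    m
  }
  w <- c((1 - fy) * (1 - fx), (1 - fy) * fx, fy * (1 - fx), fy * fx)
  acc <- matrix(0, n1, n2)
  wt <- matrix(0, n1, n2)
  parts <- list(g(0, 0), g(0, 1), g(1, 0), g(1, 1))
  for (i in 1:4) {
    if (w[i] == 0) next
    p <- parts[[i]]
    ok <- !is.na(p)
    acc[ok] <- acc[ok] + w[i] * p[ok]
    wt[ok] <- wt[ok] + w[i]
  }
  valid <- wt > 1 - 1e-9
  outfr <- acc
  outfr[!valid] <- stats::median(fr)
  outfr[valid] <- outfr[valid] / wt[valid]
  list(frame = outfr, valid = valid)
}
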