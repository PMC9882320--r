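#' Multi-channel image time series container
#'
#' A light container for one channel of an acquisition: a `ny x nx x n_frames`
#' array of pixel values, the frame timestamps in seconds, the channel name
#' and the pixel size.  Pixel `[r, c]` has continuous 0-based image
#' coordinates `x = c - 1`, `y = r - 1` at its center, matching the
#' coordinates used by the simulator and by [detect_spots()].
#'
#' @param frames 3-D numeric array (`ny x nx x n_frames`) or a matrix for a
#'   single frame.
#' @param times frame timestamps, seconds, strictly increasing.
#' @param channel channel name.
#' @param pixel_size um/px.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(frames, times, channel = "unknown", pixel_size = 0.11) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1))
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == length(times))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(frames = frames, times = times, channel = channel,
                 pixel_size = pixel_size),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("movie_stack '%s': %d x %d px, %d frame(s), t = %g..%g s\n",
              x$channel, d[1], d[2], d[3], min(x$times), max(x$times)))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]

#' Render TIRF-like movies from ground-truth pulse trains
#'
#' Converts a [simulate_pulse_trains()] ground truth into per-channel image
#' stacks: each frame is a uniform background plus one Gaussian PSF per
#' fluorophore ON at the frame time, at the spot position displaced by the
#' stage drift, with Poisson shot noise and Gaussian read noise.  The
#' template channel (surface-linked DNA, permanently labeled) is rendered on
#' the slow acquisition schedule; protein channels on the fast schedule.
#' With `bleach_rate > 0` each protein pulse carries one fluorophore that
#' survives each exposure with probability `1 - bleach_rate` and goes dark
#' for the rest of the pulse once bleached; the template is not bleached.
#'
#' @param truth a `ground_truth` from [simulate_pulse_trains()].
#' @param optics an [optics_params()]; its `image_size` should match the one
#'   used to place the spots.
#' @param seed integer seed for the noise and bleaching draws.
#' @param channels subset of `c("template", "target", "partner")` to render.
#' @param template_photons expected photons per template spot per exposure
#'   (defaults to `optics$photons_per_fluor`).
#' @return A named list of [movie_stack()] objects.
#' @export
render_movie <- function(truth, optics, seed,
                         channels = c("template", "target", "partner"),
                         template_photons = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(optics, "optics_params"))
  channels <- match.arg(channels, several.ok = TRUE)
  set.seed(as.integer(seed))
  p <- truth$params
  if (is.null(template_photons)) template_photons <- optics$photons_per_fluor
  pos <- truth$spot_positions
  sz <- optics$image_size
  if (any(pos$x < 0 | pos$x > sz - 1 | pos$y < 0 | pos$y > sz - 1))
    warning("spot positions outside the field; rendering clipped")

  out <- list()
  if ("template" %in% channels) {
    tt <- seq(0, p$duration, by = p$dt_slow)
    out$template <- render_channel(
      pos$x, pos$y, matrix(TRUE, nrow(pos), length(tt)),
      tt, optics, template_photons)
    out$template$channel <- "template"
  }
  tf <- seq(0, p$duration, by = p$dt_fast)
  for (ch in intersect(channels, c("target", "partner"))) {
    pl <- truth$pulses[truth$pulses$channel == ch, , drop = FALSE]
    onmat <- matrix(FALSE, nrow(pos), length(tf))
    if (nrow(pl)) {
      for (k in seq_len(nrow(pl))) {
        ## half-open [onset, end); pulses truncated at the acquisition end
        ## stay ON through the final frame so they are seen as censored
        on_idx <- which(tf >= pl$onset[k] &
                          (tf < pl$end[k] | (pl$truncated[k] & tf >= pl$end[k])))
        if (!length(on_idx)) next
        if (p$bleach_rate > 0) {
          surv <- stats::rgeom(1, p$bleach_rate) + 1  # exposures survived
          on_idx <- on_idx[seq_len(min(surv, length(on_idx)))]
        }
        onmat[pl$spot_id[k], on_idx] <- TRUE
      }
    }
    out[[ch]] <- render_channel(pos$x, pos$y, onmat, tf, optics,
                                optics$photons_per_fluor)
    out[[ch]]$channel <- ch
  }
  out
}

## Render one channel: onmat[spot, frame] says which fluorophores are ON.
render_channel <- function(x, y, onmat, times, optics, photons) {
  sz <- optics$image_size
  nf <- length(times)
  frames <- array(0, c(sz, sz, nf))
  for (f in seq_len(nf)) {
    d <- optics$drift_fun(times[f])
    lam <- matrix(optics$background_level, sz, sz)
    on <- which(onmat[, f])
    for (s in on)
      lam <- add_psf(lam, x[s] + d[1], y[s] + d[2], optics$psf_sigma, photons)
    fr <- matrix(stats::rpois(sz * sz, lam), sz, sz)
    if (optics$read_noise_sd > 0)
      fr <- fr + matrix(stats::rnorm(sz * sz, 0, optics$read_noise_sd), sz, sz)
    frames[, , f] <- fr
  }
  movie_stack(frames, times, pixel_size = optics$pixel_size)
}

## Add a 2-D Gaussian of total intensity `photons` centered at continuous
## 0-based (x, y) into matrix `lam`, clipped at the field edge.
add_psf <- function(lam, x, y, sigma, photons) {
  sz <- nrow(lam)
  r <- ceiling(4 * sigma)
  rc <- round(y) + 1; cc <- round(x) + 1
  r0 <- max(1, rc - r); r1 <- min(sz, rc + r)
  c0 <- max(1, cc - r); c1 <- min(sz, cc + r)
  if (r0 > r1 || c0 > c1) return(lam)
  yy <- (r0:r1) - 1
  xx <- (c0:c1) - 1
  gy <- exp(-(yy - y)^2 / (2 * sigma^2))
  gx <- exp(-(xx - x)^2 / (2 * sigma^2))
  lam[r0:r1, c0:c1] <- lam[r0:r1, c0:c1] +
    photons / (2 * pi * sigma^2) * outer(gy, gx)
  lam
}

#' Render a single endpoint snapshot
#'
#' One frame per channel for an endpoint colocalization assay: the template
#' channel shows all spots, the protein channel only the occupied ones.
#'
#' @param field a [simulate_endpoint_field()] result.
#' @param optics an [optics_params()].
#' @param seed integer seed.
#' @param template_photons photons per template spot (defaults to
#'   `optics$photons_per_fluor`).
#' @return A list of two single-frame [movie_stack()]s, `template` and
#'   `protein`.
#' @export
render_snapshot <- function(field, optics, seed, template_photons = NULL) {
  set.seed(as.integer(seed))
  if (is.null(template_photons)) template_photons <- optics$photons_per_fluor
  pos <- field$spot_positions
  all_on <- matrix(TRUE, nrow(pos), 1)
  occ_on <- matrix(field$occupied, nrow(pos), 1)
  tpl <- render_channel(pos$x, pos$y, all_on, 0, optics, template_photons)
  tpl$channel <- "template"
  prot <- render_channel(pos$x, pos$y, occ_on, 0, optics,
                         optics$photons_per_fluor)
  prot$channel <- "protein"
  list(template = tpl, protein = prot)
}
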