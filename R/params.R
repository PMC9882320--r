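#' Kinetic parameters for the two-channel binding simulator
#'
#' Bundles the ground-truth rates of the continuous-time Markov model used by
#' [simulate_pulse_trains()].  The target protein ("A", e.g. a GFP-tagged
#' centromeric histone) arrives on a free template with rate `k_on_A` and
#' detaches with rate `k_off_A`; the partner protein ("B", e.g. an
#' mCherry-tagged DNA-binding kinetochore protein) cycles independently between
#' absent and present with rates `k_on_B` / `k_off_B`.  While the partner is
#' present the instantaneous detachment rate of the target is
#' `coupling_factor * k_off_A`, so `coupling_factor < 1` models stabilization
#' of the target by the partner (a ternary complex) and `coupling_factor = 1`
#' uncoupled kinetics.
#'
#' Default rates emulate a typical centromeric-nucleosome assembly experiment:
#' about one target residence per template over a 45-min acquisition
#' (`k_on_A = 1.4`/hr), a non-ternary target off-rate of 29/hr, and a
#' persistent DNA-binding partner (`k_on_B = 30`/hr, `k_off_B = 6`/hr) giving
#' ~0.83 stationary partner occupancy and high (~0.9) partner co-occupancy of
#' ternary residence time, while leaving both detachment pools populated
#' enough that the ternary/non-ternary off-rate contrast is estimable from a
#' single simulated field.
#'
#' @param k_on_A target arrival rate while the target is absent, per hour.
#' @param k_off_A target detachment rate while the partner is absent, per hour.
#' @param k_on_B,k_off_B partner arrival/departure rates, per hour.
#' @param coupling_factor multiplier applied to `k_off_A` while the partner is
#'   present; must be positive, `<= 1` means stabilization.
#' @param bleach_rate per-exposure bleaching probability per fluorophore
#'   (applied by [render_movie()] on frames where the channel is excited).
#' @param duration total acquisition time in seconds.
#' @param dt_fast interval between protein-channel frames, seconds.
#' @param dt_slow interval between template-channel frames, seconds.
#' @return An object of class `kinetic_params` (a validated list).
#' @seealso [simulate_pulse_trains()], [render_movie()]
#' @export
kinetic_params <- function(k_on_A = 1.4, k_off_A = 29,
                           k_on_B = 30, k_off_B = 6,
                           coupling_factor = 1,
                           bleach_rate = 0,
                           duration = 2700, dt_fast = 5, dt_slow = 60) {
  p <- list(k_on_A = k_on_A, k_off_A = k_off_A,
            k_on_B = k_on_B, k_off_B = k_off_B,
            coupling_factor = coupling_factor,
            bleach_rate = bleach_rate,
            duration = duration, dt_fast = dt_fast, dt_slow = dt_slow)
  rates <- c(k_on_A, k_off_A, k_on_B, k_off_B)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("kinetic rates must be finite and >= 0")
  if (!is.finite(coupling_factor) || coupling_factor <= 0)
    stop("coupling_factor must be finite and > 0")
  if (!is.finite(bleach_rate) || bleach_rate < 0 || bleach_rate > 1)
    stop("bleach_rate must be a probability in [0, 1]")
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0")
  if (dt_fast <= 0 || dt_slow <= 0 || dt_fast > dt_slow)
    stop("need 0 < dt_fast <= dt_slow")
  class(p) <- "kinetic_params"
  p
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (rates per hour):\n")
  cat(sprintf("  target : k_on %.3g, k_off %.3g (coupling %.3g while partner present)\n",
              x$k_on_A, x$k_off_A, x$coupling_factor))
  cat(sprintf("  partner: k_on %.3g, k_off %.3g\n", x$k_on_B, x$k_off_B))
  cat(sprintf("  acquisition: %g s, protein frames every %g s, template every %g s\n",
              x$duration, x$dt_fast, x$dt_slow))
  if (x$bleach_rate > 0)
    cat(sprintf("  bleaching: %.3g per exposure per fluorophore\n", x$bleach_rate))
  invisible(x)
}

#' Optical parameters for movie rendering
#'
#' Describes the camera geometry and noise model used by [render_movie()] and
#' [render_snapshot()].  Defaults follow a typical EMCCD TIRF configuration:
#' 512 x 512 px at 0.11 um/px.  Rendered spots are 2-D Gaussians of standard
#' deviation `psf_sigma` integrating to `photons_per_fluor` expected photons
#' per exposure per fluorophore, on a uniform `background_level`; pixel values
#' receive Poisson shot noise plus Gaussian read noise of sd `read_noise_sd`.
#'
#' @param image_size field size, pixels per side (>= 32).
#' @param pixel_size pixel pitch, um/px (metadata only).
#' @param psf_sigma Gaussian PSF standard deviation, px.
#' @param photons_per_fluor expected photons per fluorophore per exposure.
#' @param background_level uniform background, photons per pixel per exposure.
#' @param read_noise_sd Gaussian read noise sd, photons.
#' @param drift lateral stage drift: `NULL` (none), a numeric pair giving a
#'   linear drift velocity in px per second, or a function `f(t)` returning the
#'   `(dx, dy)` shift in px at time `t` seconds (with `f(0) = c(0, 0)`).
#' @return An object of class `optics_params`.
#' @export
optics_params <- function(image_size = 512, pixel_size = 0.11,
                          psf_sigma = 1.2, photons_per_fluor = 2000,
                          background_level = 100, read_noise_sd = 3,
                          drift = NULL) {
  if (!is.finite(psf_sigma) || psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (image_size < 32) stop("image_size must be >= 32")
  if (background_level < 0) stop("background_level must be >= 0")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  drift_fun <- resolve_drift(drift)
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 psf_sigma = psf_sigma, photons_per_fluor = photons_per_fluor,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 drift = drift, drift_fun = drift_fun),
            class = "optics_params")
}

## Normalise the drift spec to a function of time -> c(dx, dy) px.
resolve_drift <- function(drift) {
  if (is.null(drift)) return(function(t) c(0, 0))
  if (is.function(drift)) return(drift)
  if (is.numeric(drift) && length(drift) == 2) {
    v <- drift
    return(function(t) v * t)
  }
  stop("drift must be NULL, a numeric velocity pair (px/s), or a function of time")
}

#' Specification of a synthetic CDEII-like sequence
#'
#' Target composition for [generate_cdeii_sequence()]: overall A+T fraction
#' and the fraction of positions falling inside homopolymeric A or T runs of
#' length >= 4 (the run-content statistic of [run_fraction()]).
#'
#' @param length sequence length, bp.
#' @param at_fraction target A+T fraction, in `[0, 1]`.
#' @param target_run_fraction target fraction of bp inside homopolymeric A/T
#'   runs of length >= 4; must not exceed `at_fraction`.
#' @param seed integer seed making the construction reproducible.
#' @return An object of class `sequence_spec`.
#' @export
sequence_spec <- function(length = 84, at_fraction = 0.9,
                          target_run_fraction = 0.5, seed = 1) {
  if (length <= 0) stop("length must be > 0")
  if (at_fraction < 0 || at_fraction > 1) stop("at_fraction must be in [0, 1]")
  if (target_run_fraction < 0 || target_run_fraction > at_fraction)
    stop("need 0 <= target_run_fraction <= at_fraction")
  structure(list(length = as.integer(length), at_fraction = at_fraction,
                 target_run_fraction = target_run_fraction,
                 seed = as.integer(seed)),
            class = "sequence_spec")
}
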