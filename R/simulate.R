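#' Simulate ground-truth binding pulse trains
#'
#' Runs the continuous-time Markov binding model of [kinetic_params()]
#' independently for `n_spots` immobilized template molecules and records every
#' target ("A") and partner ("B") residence as a continuous-time pulse.  Each
#' spot starts unoccupied in both channels (the extract is introduced at
#' t = 0).  Event times are exact (Gillespie simulation); quantization onto the
#' camera frame grid happens later, in the analysis, so the ground truth stays
#' exact.  Pulses still ON at `duration` are emitted with `end = duration` and
#' flagged `truncated` (they become right-censored observations downstream).
#'
#' @param params a [kinetic_params()] object.
#' @param n_spots number of template molecules (>= 1).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param image_size field side in px used to place spots (for rendering).
#' @param min_separation minimum pairwise spot distance in px (default 8,
#'   keeping Gaussian PSFs non-overlapping).
#' @param margin border in px kept free of spots.
#' @return An object of class `ground_truth`: a list with `spot_positions`
#'   (data.frame `spot_id, x, y`; 0-based continuous px), `pulses` (data.frame
#'   `spot_id, channel, onset, end, truncated` with channel `"target"` or
#'   `"partner"`), `params`, and `seed`.
#' @examples
#' gt <- simulate_pulse_trains(kinetic_params(k_on_A = 4), n_spots = 10, seed = 1)
#' head(gt$pulses)
#' @export
simulate_pulse_trains <- function(params, n_spots, seed,
                                  image_size = 512, min_separation = 8,
                                  margin = 8) {
  stopifnot(inherits(params, "kinetic_params"))
  if (n_spots < 1) stop("n_spots must be >= 1")
  set.seed(as.integer(seed))
  positions <- place_spots(n_spots, image_size, min_separation, margin)

  ## per-second rates
  kaon <- params$k_on_A / 3600
  kaoff <- params$k_off_A / 3600
  kbon <- params$k_on_B / 3600
  kboff <- params$k_off_B / 3600
  cf <- params$coupling_factor
  dur <- params$duration

  res <- vector("list", n_spots)
  for (s in seq_len(n_spots)) {
    t <- 0
    a <- FALSE; b <- FALSE
    a_on <- NA_real_; b_on <- NA_real_
    onset <- numeric(0); end <- numeric(0); chan <- character(0)
    repeat {
      ra <- if (a) kaoff * (if (b) cf else 1) else kaon
      rb <- if (b) kboff else kbon
      tot <- ra + rb
      if (tot <= 0) { t <- dur; break }
      t2 <- t + stats::rexp(1, tot)
      if (t2 >= dur) break
      t <- t2
      if (stats::runif(1) < ra / tot) {
        if (a) { onset <- c(onset, a_on); end <- c(end, t); chan <- c(chan, "target") }
        else a_on <- t
        a <- !a
      } else {
        if (b) { onset <- c(onset, b_on); end <- c(end, t); chan <- c(chan, "partner") }
        else b_on <- t
        b <- !b
      }
    }
    if (a) { onset <- c(onset, a_on); end <- c(end, dur); chan <- c(chan, "target") }
    if (b) { onset <- c(onset, b_on); end <- c(end, dur); chan <- c(chan, "partner") }
    if (length(onset))
      res[[s]] <- data.frame(spot_id = s, channel = chan,
                             onset = onset, end = end)
  }
  pulses <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(pulses))
    pulses <- data.frame(spot_id = integer(0), channel = character(0),
                         onset = numeric(0), end = numeric(0))
  pulses <- pulses[order(pulses$spot_id, pulses$channel, pulses$onset), ,
                   drop = FALSE]
  rownames(pulses) <- NULL
  pulses$truncated <- pulses$end >= dur

  structure(list(spot_positions = positions, pulses = pulses,
                 params = params, seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d spots, %d pulses (%d target, %d partner), %g s\n",
              nrow(x$spot_positions), nrow(x$pulses),
              sum(x$pulses$channel == "target"),
              sum(x$pulses$channel == "partner"),
              x$params$duration))
  invisible(x)
}

## Uniform rejection placement with a minimum pairwise distance.
## Uses the caller's RNG stream.  Returns 0-based continuous coordinates.
place_spots <- function(n, image_size, min_separation, margin) {
  lo <- margin
  hi <- image_size - 1 - margin
  if (hi <= lo) stop("margin too large for image_size")
  x <- numeric(n); y <- numeric(n)
  k <- 0
  tries <- 0
  max_tries <- 2000 * n
  while (k < n) {
    px <- stats::runif(1, lo, hi)
    py <- stats::runif(1, lo, hi)
    if (k == 0 ||
        min((x[1:k] - px)^2 + (y[1:k] - py)^2) >= min_separation^2) {
      k <- k + 1
      x[k] <- px; y[k] <- py
    }
    tries <- tries + 1
    if (tries > max_tries)
      stop("could not place spots: density too high for min_separation")
  }
  data.frame(spot_id = seq_len(n), x = x, y = y)
}

#' Simulate an endpoint field: occupied and unoccupied template spots
#'
#' Ground truth for endpoint colocalization assays: `n_spots` template
#' positions of which an exact fraction `occupied_fraction` carry a protein
#' fluorophore (as after incubating extract and washing the chamber).
#'
#' @inheritParams simulate_pulse_trains
#' @param occupied_fraction fraction of template spots carrying a protein;
#'   realized exactly as `round(occupied_fraction * n_spots)` spots.
#' @return A list with `spot_positions`, logical vector `occupied`, and `seed`.
#' @seealso [render_snapshot()], [colocalize()]
#' @export
simulate_endpoint_field <- function(n_spots, occupied_fraction, seed,
                                    image_size = 512, min_separation = 8,
                                    margin = 8) {
  if (occupied_fraction < 0 || occupied_fraction > 1)
    stop("occupied_fraction must be in [0, 1]")
  set.seed(as.integer(seed))
  positions <- place_spots(n_spots, image_size, min_separation, margin)
  n_occ <- round(occupied_fraction * n_spots)
  occupied <- rep(FALSE, n_spots)
  occupied[sample.int(n_spots, n_occ)] <- TRUE
  list(spot_positions = positions, occupied = occupied, seed = as.integer(seed))
}

#' Simulate photobleaching decay traces
#'
#' Generates continuously illuminated intensity traces for spots carrying
#' `n_fluor` fluorophores, each bleaching independently with probability
#' `bleach_prob` per frame.  Fluorophores contribute unit-level steps of size
#' `snr` noise standard deviations (noise sd is 1), so `snr` is the step
#' signal-to-noise ratio.  The default 400-frame traces let essentially all
#' fluorophores bleach within the observation (`0.99^400 < 0.02`).
#'
#' @param n_traces number of traces.
#' @param n_fluor fluorophores per spot (may be a vector recycled over traces,
#'   e.g. for a monomer/dimer mixture).
#' @param bleach_prob per-frame bleaching probability per fluorophore.
#' @param snr step height in units of the frame noise sd.
#' @param n_frames trace length in frames.
#' @param dt frame interval in seconds (for the time axis).
#' @param seed integer seed.
#' @return A list with `traces` (a `n_frames x n_traces` matrix), `times`,
#'   `n_fluor` (per trace), and `true_steps`: the number of distinct downward
#'   bleaching transitions visible in each trace (simultaneous bleaches within
#'   one frame merge into a single step; unbleached fluorophores produce none).
#' @export
simulate_bleach_traces <- function(n_traces, n_fluor = 2, bleach_prob = 0.01,
                                   snr = 8, n_frames = 400, dt = 1, seed = 1) {
  set.seed(as.integer(seed))
  nf <- rep_len(n_fluor, n_traces)
  traces <- matrix(0, n_frames, n_traces)
  true_steps <- integer(n_traces)
  for (i in seq_len(n_traces)) {
    ## frame index after which each fluorophore is dark (Inf = never bleaches)
    bleach_at <- stats::rgeom(nf[i], bleach_prob) + 1
    bleach_at[bleach_at > n_frames] <- Inf
    alive <- vapply(seq_len(n_frames),
                    function(f) sum(bleach_at >= f), numeric(1))
    traces[, i] <- alive * snr + stats::rnorm(n_frames)
    true_steps[i] <- length(unique(bleach_at[is.finite(bleach_at)]))
  }
  list(traces = traces, times = (seq_len(n_frames) - 1) * dt,
       n_fluor = nf, true_steps = true_steps, seed = as.integer(seed))
}
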