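# Shared fixture builders (everything is generated in code at test time).

# Hand-built ground truth with explicit positions and pulses.
make_truth <- function(positions, pulses = NULL, params = kinetic_params()) {
  if (is.null(pulses))
    pulses <- data.frame(spot_id = integer(0), channel = character(0),
                         onset = numeric(0), end = numeric(0),
                         truncated = logical(0))
  if (is.null(pulses$truncated))
    pulses$truncated <- pulses$end >= params$duration
  structure(list(spot_positions = positions, pulses = pulses,
                 params = params, seed = 0L),
            class = "ground_truth")
}

# photons_per_fluor giving a requested peak SNR for given optics noise
photons_for_snr <- function(snr, psf_sigma = 1.2, background = 100,
                            read_sd = 3) {
  snr * sqrt(background + read_sd^2) * 2 * pi * psf_sigma^2
}

# noiseless optics for geometric checks
quiet_optics <- function(image_size = 64, ...) {
  optics_params(image_size = image_size, background_level = 0,
                read_noise_sd = 0, ...)
}

# match detected centroids to true positions within a radius;
# returns list(recall, false_pos, match: index of true spot per detection)
match_spots <- function(detected, truth_xy, radius = 2) {
  n_true <- nrow(truth_xy)
  used <- rep(FALSE, n_true)
  match_id <- rep(NA_integer_, nrow(detected))
  for (i in seq_len(nrow(detected))) {
    d2 <- (truth_xy$x - detected$x[i])^2 + (truth_xy$y - detected$y[i])^2
    j <- which.min(d2)
    if (d2[j] <= radius^2 && !used[j]) {
      match_id[i] <- j
      used[j] <- TRUE
    }
  }
  list(recall = sum(used) / n_true,
       false_pos = sum(is.na(match_id)),
       match = match_id)
}

# Independent grid-based oracle for the ternary residence partition.
# Works on integer-valued pulse times with a 1-s unit grid, using explicit
# per-unit set operations instead of interval arithmetic.
oracle_classify <- function(target, partner, tol = 5) {
  out <- target
  out$ternary_time <- 0
  out$nonternary_time <- 0
  out$first_overlap <- NA_real_
  for (i in seq_len(nrow(target))) {
    t_units <- if (target$end[i] > target$onset[i])
      seq(target$onset[i], target$end[i] - 1) else integer(0)
    first <- NA_real_
    ps <- partner[partner$spot_id == target$spot_id[i], , drop = FALSE]
    if (nrow(ps)) {
      ps <- ps[order(ps$onset), , drop = FALSE]
      for (j in seq_len(nrow(ps))) {
        p_units <- if (ps$end[j] > ps$onset[j])
          seq(ps$onset[j], ps$end[j] - 1) else integer(0)
        if (length(intersect(t_units, p_units))) { first <- ps$onset[j]; break }
      }
    }
    out$first_overlap[i] <- first
    if (is.na(first)) {
      out$nonternary_time[i] <- length(t_units)
    } else if (first <= target$onset[i] + tol) {
      out$ternary_time[i] <- length(t_units)
    } else {
      out$nonternary_time[i] <- sum(t_units < first)
      out$ternary_time[i] <- sum(t_units >= first)
    }
  }
  out
}

# per-spot count of ground-truth pulses that are observable on the fast frame
# grid: a pulse is visible iff at least one frame timestamp falls in
# [onset, end), or it is truncated at the acquisition end (then the final
# frame shows it)
truth_visible_counts <- function(gt, n_spots, channel = "target") {
  p <- gt$params
  tf <- seq(0, p$duration, by = p$dt_fast)
  pl <- gt$pulses[gt$pulses$channel == channel, , drop = FALSE]
  vis <- vapply(seq_len(nrow(pl)), function(k)
    any(tf >= pl$onset[k] &
          (tf < pl$end[k] | (pl$truncated[k] & tf >= pl$end[k]))),
    logical(1))
  table(factor(pl$spot_id[vis], levels = seq_len(n_spots)))
}

# random integer-time pulse configurations on one spot (disjoint per channel)
random_pulse_set <- function(n_max = 5, horizon = 600) {
  make <- function() {
    n <- sample(0:n_max, 1)
    if (n == 0)
      return(data.frame(spot_id = integer(0), onset = numeric(0),
                        end = numeric(0)))
    edges <- sort(sample(0:horizon, 2 * n))
    data.frame(spot_id = 1L, onset = edges[seq(1, 2 * n, 2)],
               end = edges[seq(2, 2 * n, 2)])
  }
  repeat {
    tg <- make()
    if (!nrow(tg) || all(tg$end > tg$onset)) break
  }
  repeat {
    pt <- make()
    if (!nrow(pt) || all(pt$end > pt$onset)) break
  }
  list(target = tg, partner = pt)
}
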