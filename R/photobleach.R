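#' Count photobleaching steps in an intensity decay trace
#'
#' Fits a piecewise-constant model to a continuously illuminated spot trace
#' by recursive binary change-point splitting and selects the number of
#' change points with an information criterion (BIC by default).  Only
#' downward level transitions are counted as bleaching steps; upward
#' transitions (blinking returns) are retained in the fit but excluded from
#' the step count.  Step counts across many spots estimate the fluorophore
#' stoichiometry distribution (e.g. dimeric proteins bleach predominantly in
#' two steps).
#'
#' @param trace a numeric intensity vector, or a list with a numeric `values`
#'   field (an [extract_traces()] trace works: `raw_mean - local_bg` is
#'   used).  At least 10 frames.
#' @param max_steps maximum number of change points considered.
#' @param penalty model-selection criterion, `"bic"` or `"aic"`.
#' @param min_segment minimum frames per fitted level (default 3).
#' @param min_step_sd minimum |level difference| of a retained transition, in
#'   units of the robust frame-noise sd (default 3): fluorophore bleaching
#'   steps have finite brightness, so transitions smaller than the noise are
#'   merged away after model selection.  Set to 0 to disable.
#' @param times optional frame times (defaults to 0, 1, 2, ... frames).
#' @return An object of class `step_fit`: `n_steps` (downward steps),
#'   `step_times`, `step_levels` (fitted level per segment), `changepoints`
#'   (frame indices of all selected transitions), `residual` (sum of squared
#'   residuals of the selected model), and `penalty`.
#' @export
count_steps <- function(trace, max_steps = 5, penalty = c("bic", "aic"),
                        min_segment = 3, min_step_sd = 3, times = NULL) {
  penalty <- match.arg(penalty)
  x <- if (is.numeric(trace)) trace
       else if (!is.null(trace$values)) trace$values
       else if (!is.null(trace$raw_mean)) trace$raw_mean - trace$local_bg
       else stop("cannot interpret trace input")
  n <- length(x)
  if (n < 10) stop("trace shorter than 10 frames")
  if (is.null(times)) times <- seq_len(n) - 1

  ## greedy nested binary segmentation: repeatedly apply the single split
  ## with the largest residual reduction anywhere in the current segmentation
  S <- c(0, cumsum(x))
  SS <- c(0, cumsum(x^2))
  rss <- function(a, b) {                      # RSS of x[a..b] about its mean
    m <- b - a + 1
    SS[b + 1] - SS[a] - (S[b + 1] - S[a])^2 / m
  }
  best_split <- function(a, b) {
    ## best single change point inside [a, b]; returns c(gain, j) where the
    ## segments become [a, j] and [j+1, b]
    j <- seq(a + min_segment - 1, b - min_segment)
    if (!length(j) || j[1] > j[length(j)]) return(c(-Inf, NA))
    nl <- j - a + 1
    nr <- b - j
    sl <- S[j + 1] - S[a]
    sr <- S[b + 1] - S[j + 1]
    red <- sl^2 / nl + sr^2 / nr - (S[b + 1] - S[a])^2 / (b - a + 1)
    k <- which.max(red)
    c(red[k], j[k])
  }

  segs <- list(c(1, n))
  cps <- integer(0)
  rss_k <- rss(1, n)
  rss_path <- rss_k
  cand <- list(best_split(1, n))
  while (length(cps) < max_steps) {
    gains <- vapply(cand, `[`, numeric(1), 1)
    gi <- which.max(gains)
    if (!is.finite(gains[gi]) || gains[gi] <= 0) break
    j <- cand[[gi]][2]
    a <- segs[[gi]][1]; b <- segs[[gi]][2]
    segs[[gi]] <- c(a, j)
    segs[[length(segs) + 1]] <- c(j + 1, b)
    cand[[gi]] <- best_split(a, j)
    cand[[length(cand) + 1]] <- best_split(j + 1, b)
    cps <- c(cps, j)
    rss_k <- rss_k - gains[gi]
    rss_path <- c(rss_path, rss_k)
  }

  ## model selection over the nested path (k = number of change points)
  kk <- seq_along(rss_path) - 1
  pen <- if (penalty == "bic") (2 * (kk + 1)) * log(n) else 2 * (2 * (kk + 1))
  crit <- n * log(pmax(rss_path, 1e-12) / n) + pen
  k_sel <- which.min(crit) - 1
  cp_sel <- sort(cps[seq_len(k_sel)])

  seg_levels <- function(cp) {
    bounds <- c(0, cp, n)
    vapply(seq_len(length(bounds) - 1), function(i)
      mean(x[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
  }
  levels <- seg_levels(cp_sel)
  ## merge sub-noise transitions (robust sd from first differences)
  if (min_step_sd > 0 && length(cp_sel)) {
    sigma <- stats::mad(diff(x)) / sqrt(2)
    repeat {
      dl <- abs(diff(levels))
      if (!length(dl) || all(dl >= min_step_sd * sigma)) break
      j <- which.min(dl)
      cp_sel <- cp_sel[-j]
      levels <- seg_levels(cp_sel)
    }
    k_sel <- length(cp_sel)
  }
  down <- if (k_sel > 0) diff(levels) < 0 else logical(0)
  fitted <- rep(levels, diff(c(0, cp_sel, n)))
  structure(list(
    n_steps = sum(down),
    step_times = if (k_sel > 0) times[cp_sel[down] + 1] else numeric(0),
    step_levels = levels,
    changepoints = cp_sel,
    residual = sum((x - fitted)^2),
    penalty = penalty,
    rss_path = rss_path), class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("Step fit: %d bleaching step(s), %d change point(s), RSS %.3g\n",
              x$n_steps, length(x$changepoints), x$residual))
  invisible(x)
}

#' Distribution of photobleaching step counts
#'
#' @param fits a list of [count_steps()] results (or an integer vector of
#'   step counts).
#' @return A named numeric vector of proportions by step count (sums to 1).
#' @examples
#' step_distribution(c(1, 2, 2, 3))
#' @export
step_distribution <- function(fits) {
  counts <- if (is.numeric(fits)) fits
            else vapply(fits, `[[`, numeric(1), "n_steps")
  if (!length(counts)) stop("need at least one fit")
  tab <- table(counts)
  stats::setNames(as.numeric(tab) / length(counts), names(tab))
}
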