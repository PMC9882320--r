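#' Call ON/OFF pulses from a z-normalized intensity trace
#'
#' Binarizes a trace with a single channel-specific threshold: frames with
#' `z >= threshold` are ON; ON runs separated by at most `max_gap_frames`
#' sub-threshold frames are merged (single-frame blinks do not terminate a
#' residence); merged runs spanning fewer than `min_on_frames` frames are
#' discarded.  A pulse's onset is the time of its first ON frame and its
#' duration is `n_frames * dt`, where `n_frames` counts the frames it spans
#' (a one-frame pulse lasts one frame interval, not zero).  A pulse whose run
#' includes the final frame of the acquisition is flagged right-censored.
#'
#' @param trace an [extract_traces()] trace, or a list/data.frame with
#'   numeric fields `times` (strictly increasing, regular) and `z`; fields
#'   `spot_id`/`channel` are carried through when present.
#' @param threshold ON threshold in z units (> 0).
#' @param min_on_frames minimum frames per pulse (default 2).
#' @param max_gap_frames maximum sub-threshold frames bridged inside a pulse
#'   (default 1).
#' @return A data.frame of pulses: `spot_id, channel, onset, end, duration,
#'   censored, n_frames` with `end = onset + duration` (half-open interval
#'   semantics on the frame grid).
#' @examples
#' tr <- list(times = seq(0, 100, 5), z = rep(0, 21))
#' tr$z[11:20] <- 10
#' call_pulses(tr, threshold = 3)   # one pulse: onset 50, duration 50
#' @export
call_pulses <- function(trace, threshold, min_on_frames = 2,
                        max_gap_frames = 1) {
  if (threshold <= 0) stop("threshold must be > 0")
  times <- trace$times
  z <- trace$z
  nf <- length(z)
  stopifnot(length(times) == nf, nf >= 1)
  dt <- if (nf > 1) times[2] - times[1] else NA_real_
  empty <- data.frame(spot_id = integer(0), channel = character(0),
                      onset = numeric(0), end = numeric(0),
                      duration = numeric(0), censored = logical(0),
                      n_frames = integer(0))
  on <- z >= threshold
  if (!any(on)) return(empty)
  if (nf == 1) dt <- 1   # degenerate single-frame trace

  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ## merge ON runs separated by short OFF gaps
  is_on <- r$values
  seg <- data.frame(start = starts[is_on], end = ends[is_on])
  if (nrow(seg) > 1) {
    keep <- logical(nrow(seg))
    keep[1] <- TRUE
    cur <- 1
    for (i in 2:nrow(seg)) {
      gap <- seg$start[i] - seg$end[cur] - 1
      if (gap <= max_gap_frames) {
        seg$end[cur] <- seg$end[i]
      } else {
        cur <- i
        keep[i] <- TRUE
      }
    }
    seg <- seg[keep, , drop = FALSE]
  }
  n_frames <- seg$end - seg$start + 1L
  ok <- n_frames >= min_on_frames
  seg <- seg[ok, , drop = FALSE]
  n_frames <- n_frames[ok]
  if (!nrow(seg)) return(empty)
  onset <- times[seg$start]
  duration <- n_frames * dt
  data.frame(
    spot_id = if (!is.null(trace$spot_id)) trace$spot_id else NA_integer_,
    channel = if (!is.null(trace$channel)) trace$channel else NA_character_,
    onset = onset, end = onset + duration, duration = duration,
    censored = seg$end == nf, n_frames = as.integer(n_frames))
}

#' Call pulses on every trace of a channel
#'
#' Applies [call_pulses()] with one shared threshold to a list of traces (one
#' threshold per channel per image set, as in a manually thresholded
#' analysis) and row-binds the results.
#'
#' @param traces list of traces from [extract_traces()].
#' @inheritParams call_pulses
#' @return A pulse data.frame (see [call_pulses()]).
#' @export
call_pulses_all <- function(traces, threshold, min_on_frames = 2,
                            max_gap_frames = 1) {
  out <- lapply(traces, call_pulses, threshold = threshold,
                min_on_frames = min_on_frames, max_gap_frames = max_gap_frames)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Number of frames in an acquisition schedule
#'
#' Inclusive frame count for an acquisition of `total_s` seconds sampled
#' every `dt` seconds starting at t = 0: `total_s / dt + 1`.  A 45-min
#' acquisition at 5-s intervals has 541 frames.
#'
#' @param total_s total acquisition time, seconds; must be divisible by `dt`.
#' @param dt frame interval, seconds.
#' @return Integer frame count.
#' @examples
#' frame_schedule(2700, 5)  # 541
#' @export
frame_schedule <- function(total_s, dt) {
  if (dt <= 0) stop("dt must be > 0")
  k <- total_s / dt
  if (abs(k - round(k)) > 1e-9)
    stop("total_s must be divisible by dt")
  as.integer(round(k)) + 1L
}
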