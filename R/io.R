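#' Write a movie stack as multi-page TIFF with a sidecar schedule
#'
#' Pixel values are stored as 16-bit unsigned integers (values scaled by the
#' recorded `scale` so the full dynamic range survives the round trip); the
#' acquisition schedule (channel, frame timestamps, pixel size, scale) goes
#' to `<path>.json`.
#'
#' @param stack a [movie_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "movie_stack"))
  mx <- max(stack$frames, 1e-12)
  scale <- 65535 / mx
  pages <- lapply(seq_len(n_frames(stack)), function(f)
    pmin(pmax(stack$frames[, , f] / mx, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(channel = stack$channel, times = stack$times,
         pixel_size = stack$pixel_size, scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie stack written by [write_movie()]
#'
#' @param path TIFF path (expects `<path>.json` alongside).
#' @return A [movie_stack()].
#' @export
read_movie <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  frames <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  frames <- frames * 65535 / meta$scale
  movie_stack(frames, meta$times, meta$channel, meta$pixel_size)
}

#' Write ground truth to plain-text files
#'
#' Pulses go to `<prefix>_pulses.csv` (`spot_id, channel, onset_s, end_s,
#' truncated`), spot positions to `<prefix>_spots.csv`, and the kinetic
#' parameters to `<prefix>_params.json`.
#'
#' @param truth a `ground_truth`.
#' @param prefix output path prefix.
#' @return The three paths, invisibly.
#' @export
write_ground_truth <- function(truth, prefix) {
  p1 <- paste0(prefix, "_pulses.csv")
  p2 <- paste0(prefix, "_spots.csv")
  p3 <- paste0(prefix, "_params.json")
  pl <- truth$pulses
  utils::write.csv(
    data.frame(spot_id = pl$spot_id, channel = pl$channel,
               onset_s = pl$onset, end_s = pl$end, truncated = pl$truncated),
    p1, row.names = FALSE)
  utils::write.csv(truth$spot_positions, p2, row.names = FALSE)
  jsonlite::write_json(unclass(truth$params), p3, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(p1, p2, p3))
}

#' Write a drift path to CSV
#'
#' @param path a `drift_path` from [estimate_drift()].
#' @param file output CSV path (`time_s, dx_px, dy_px`).
#' @return `file`, invisibly.
#' @export
write_drift <- function(path, file) {
  utils::write.csv(as.data.frame(unclass(path)), file, row.names = FALSE)
  invisible(file)
}

#' Write called pulses to CSV
#'
#' @param pulses a pulse data.frame from [call_pulses_all()].
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_pulses <- function(pulses, file) {
  utils::write.csv(
    data.frame(spot_id = pulses$spot_id, channel = pulses$channel,
               onset_s = pulses$onset, end_s = pulses$end,
               duration_s = pulses$duration, censored = pulses$censored),
    file, row.names = FALSE)
  invisible(file)
}
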