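#' Endpoint colocalization between template and protein spots
#'
#' Re-implementation of a parent/child object-relation count: a template spot
#' is colocalized if at least one protein-spot centroid falls inside its
#' pixel mask dilated by `match_radius` px (i.e. within `match_radius` of a
#' mask pixel center).  Each protein spot is assigned to at most one template
#' spot (the one with the nearest centroid among those it falls into), so a
#' protein spot can never satisfy two templates.
#'
#' @param template,protein `spot_map`s from [detect_snapshot_spots()] on
#'   co-registered channels.
#' @param match_radius dilation radius in px (default 1).
#' @param channel_offset optional `(dx, dy)` offset of the protein channel
#'   relative to the template channel (e.g. from
#'   [estimate_channel_offset()]); subtracted from protein centroids before
#'   matching.  Default none: channels are assumed co-registered.
#' @return An object of class `coloc_result`: `n_template_spots`,
#'   `n_colocalized`, `percent`, `match_radius`, and the per-template logical
#'   vector `colocalized`.
#' @export
colocalize <- function(template, protein, match_radius = 1,
                       channel_offset = NULL) {
  stopifnot(inherits(template, "spot_map"), inherits(protein, "spot_map"))
  nt <- nrow(template$spots)
  if (!nt) stop("empty template spot map")
  np <- nrow(protein$spots)
  if (is.null(channel_offset)) channel_offset <- c(0, 0)
  hit <- rep(FALSE, nt)
  if (np) {
    px <- protein$spots$x - channel_offset[1]
    py <- protein$spots$y - channel_offset[2]
    tx <- template$spots$x; ty <- template$spots$y
    ## per-template mask extent from its centroid, for a cheap prefilter
    maxr <- vapply(seq_len(nt), function(i) {
      m <- template$masks[[i]]
      sqrt(max((m[, 2] - 1 - tx[i])^2 + (m[, 1] - 1 - ty[i])^2))
    }, numeric(1))
    for (j in seq_len(np)) {
      ## template masks whose dilation could contain this protein centroid
      cand <- which((tx - px[j])^2 + (ty - py[j])^2 <=
                      (match_radius + maxr + 1e-9)^2)
      inside <- cand[vapply(cand, function(i) {
        m <- template$masks[[i]]
        any((m[, 2] - 1 - px[j])^2 + (m[, 1] - 1 - py[j])^2 <= match_radius^2)
      }, logical(1))]
      if (length(inside)) {
        ## nearest-centroid assignment among containing templates
        i <- inside[which.min((tx[inside] - px[j])^2 + (ty[inside] - py[j])^2)]
        hit[i] <- TRUE
      }
    }
  }
  structure(list(n_template_spots = nt, n_colocalized = sum(hit),
                 percent = 100 * sum(hit) / nt, match_radius = match_radius,
                 colocalized = hit),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("colocalization: %d / %d template spots (%.1f%%), radius %g px\n",
              x$n_colocalized, x$n_template_spots, x$percent, x$match_radius))
  invisible(x)
}

#' Estimate a constant inter-channel offset from bright colocalized spots
#'
#' A single-translation calibration: each protein centroid is paired with
#' its nearest template centroid, pairs farther apart than `max_shift` px
#' are dropped, and the offset is the coordinate-wise median displacement.
#' Intended for bead-like bright fiducials; pass the result to
#' [colocalize()] as `channel_offset` when channels are not perfectly
#' co-registered.
#'
#' @param template,protein `spot_map`s.
#' @param max_shift largest plausible offset, px (default 3).
#' @return `c(dx, dy)` in px.
#' @export
estimate_channel_offset <- function(template, protein, max_shift = 3) {
  stopifnot(inherits(template, "spot_map"), inherits(protein, "spot_map"))
  if (!nrow(template$spots) || !nrow(protein$spots))
    stop("both maps must contain spots")
  tx <- template$spots$x; ty <- template$spots$y
  dx <- dy <- rep(NA_real_, nrow(protein$spots))
  for (j in seq_len(nrow(protein$spots))) {
    d2 <- (tx - protein$spots$x[j])^2 + (ty - protein$spots$y[j])^2
    i <- which.min(d2)
    if (d2[i] <= max_shift^2) {
      dx[j] <- protein$spots$x[j] - tx[i]
      dy[j] <- protein$spots$y[j] - ty[i]
    }
  }
  if (all(is.na(dx))) stop("no spot pairs within max_shift")
  c(stats::median(dx, na.rm = TRUE), stats::median(dy, na.rm = TRUE))
}

#' Aggregate colocalization over fields of view
#'
#' Mean and standard deviation of the colocalization percentage across
#' replicate fields (typically >= 3).
#'
#' @param results list of [colocalize()] results.
#' @return A list with `mean_percent`, `sd_percent`, `n_fields`.
#' @export
aggregate_coloc <- function(results) {
  p <- vapply(results, `[[`, numeric(1), "percent")
  list(mean_percent = mean(p),
       sd_percent = if (length(p) > 1) stats::sd(p) else NA_real_,
       n_fields = length(p))
}
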