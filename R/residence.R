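#' Partition target residences into ternary and non-ternary pools
#'
#' Implements the five-way residence partition used to estimate ternary and
#' non-ternary off-rates of a target protein (e.g. the centromeric histone)
#' relative to a partner protein (e.g. a DNA-binding kinetochore protein or
#' the histone chaperone) observed on the same template spot:
#'
#' * if a partner pulse overlaps the target residence and the partner arrived
#'   before, or within `simultaneity_tol` of, the target onset, the entire
#'   residence is ternary time (whole-residence cases, "T1/T2");
#' * if the first overlapping partner arrives later, the head
#'   `[onset, partner onset)` is non-ternary ("T3") and the tail
#'   `[partner onset, end]` is ternary ("T5") regardless of when the partner
#'   departs afterwards (partner disappearance is indistinguishable from
#'   partner photobleaching, so a residence stays ternary after first contact);
#' * if no partner ever overlaps, the whole residence is non-ternary ("T4").
#'
#' The detachment event of an uncensored residence is assigned to the pool
#' active at the residence end (ternary for T1/T2/T5 cases, non-ternary for
#' T4); right-censored residences contribute observation time but no event.
#' Note a T3 head never contributes an event: the molecule did not detach at
#' the head boundary.
#'
#' @param target_pulses data.frame of target pulses with columns
#'   `spot_id, onset, end` and optionally `censored` (default all `FALSE`);
#'   pulses of one spot must not overlap.
#' @param partner_pulses data.frame of partner pulses (`spot_id, onset, end`).
#' @param simultaneity_tol tolerance in seconds for "partner arrived no later
#'   than the target"; default 5 s, one fast frame.
#' @return A data.frame of residence records, one row per target pulse:
#'   `spot_id, onset, end, duration, censored, ternary, first_overlap`
#'   (onset of the first overlapping partner pulse, `NA` if none),
#'   `ternary_time, nonternary_time, overlap_time` (seconds of actual
#'   partner co-presence within the residence), and
#'   `event_pool` (`"ternary"`, `"nonternary"`, or `"censored"`).
#' @references the `ternary_time + nonternary_time = duration` identity holds
#'   exactly for every record.
#' @export
classify_ternary <- function(target_pulses, partner_pulses,
                             simultaneity_tol = 5) {
  tp <- check_pulse_df(target_pulses, "target_pulses")
  pp <- check_pulse_df(partner_pulses, "partner_pulses", need_censored = FALSE)
  ## overlapping target pulses on one spot violate the trace model
  if (nrow(tp) > 1) {
    o <- order(tp$spot_id, tp$onset)
    same <- tp$spot_id[o][-1] == tp$spot_id[o][-nrow(tp)]
    if (any(same & tp$onset[o][-1] < tp$end[o][-nrow(tp)]))
      stop("overlapping target pulses on one spot")
  }
  n <- nrow(tp)
  first_overlap <- rep(NA_real_, n)
  ternary_time <- numeric(n)
  nonternary_time <- numeric(n)
  overlap_time <- numeric(n)
  pp_by_spot <- split(pp, pp$spot_id)
  for (i in seq_len(n)) {
    on <- tp$onset[i]; en <- tp$end[i]
    ps <- pp_by_spot[[as.character(tp$spot_id[i])]]
    dur <- en - on
    if (!is.null(ps)) {
      ## half-open interval semantics [onset, end): pulses that merely touch
      ## end-to-onset share no frame and do not overlap
      ov <- ps$end > on & ps$onset < en
      if (any(ov)) {
        ps <- ps[ov, , drop = FALSE]
        first_overlap[i] <- min(ps$onset)
        overlap_time[i] <- sum(pmin(ps$end, en) - pmax(ps$onset, on))
      }
    }
    if (is.na(first_overlap[i])) {          # T4
      nonternary_time[i] <- dur
    } else if (first_overlap[i] <= on + simultaneity_tol) {   # T1/T2
      ternary_time[i] <- dur
    } else {                                 # T3 head + T5 tail
      nonternary_time[i] <- first_overlap[i] - on
      ternary_time[i] <- en - first_overlap[i]
    }
  }
  censored <- if ("censored" %in% names(tp)) tp$censored else rep(FALSE, n)
  ternary <- ternary_time > 0
  event_pool <- ifelse(censored, "censored",
                       ifelse(ternary, "ternary", "nonternary"))
  data.frame(spot_id = tp$spot_id, onset = tp$onset, end = tp$end,
             duration = tp$end - tp$onset, censored = censored,
             ternary = ternary, first_overlap = first_overlap,
             ternary_time = ternary_time, nonternary_time = nonternary_time,
             overlap_time = overlap_time, event_pool = event_pool)
}

check_pulse_df <- function(df, what, need_censored = FALSE) {
  req <- c("spot_id", "onset", "end")
  if (!all(req %in% names(df)))
    stop(what, " must have columns spot_id, onset, end")
  if (nrow(df) && any(df$end < df$onset))
    stop(what, ": pulse end before onset")
  df
}

#' Estimate ternary and non-ternary off-rates
#'
#' Pooled off-rate estimators over a set of residence records: the ternary
#' off-rate is the number of detachment events recorded in the ternary pool
#' divided by the total ternary residence time observed (T1 + T2 + T5), and
#' the non-ternary off-rate is the non-ternary event count over the total
#' non-ternary time (T3 + T4); both are reported per hour.  Censored
#' residences contribute observation time but no event, the standard
#' maximum-likelihood treatment of right-censored exponential dwells.  The
#' reported standard error is the Poisson-count approximation `k / sqrt(N)`.
#'
#' @param records a data.frame from [classify_ternary()].
#' @return A list with elements `kt` and `kn`, each a list
#'   `(k, n_events, total_time, se, defined)`; a pool with zero observed time
#'   is flagged `defined = FALSE` (with `k = NA`) rather than an error.
#' @examples
#' recs <- classify_ternary(
#'   data.frame(spot_id = 1, onset = 100, end = 300),
#'   data.frame(spot_id = 1, onset = 0, end = 500))
#' estimate_off_rates(recs)$kt$k   # 1 event / 200 s = 18/hr
#' @export
estimate_off_rates <- function(records) {
  if (!nrow(records)) stop("need at least one residence record")
  pool <- function(time_s, n_events) {
    total <- sum(time_s)
    if (total <= 0)
      return(list(k = NA_real_, n_events = n_events, total_time = 0,
                  se = NA_real_, defined = FALSE))
    k <- n_events / (total / 3600)
    list(k = k, n_events = n_events, total_time = total,
         se = if (n_events > 0) k / sqrt(n_events) else NA_real_,
         defined = TRUE)
  }
  list(kt = pool(records$ternary_time,
                 sum(records$event_pool == "ternary")),
       kn = pool(records$nonternary_time,
                 sum(records$event_pool == "nonternary")))
}

#' Arrival order of target and partner in ternary residences
#'
#' Classifies each ternary residence by the onset difference between the
#' target and its first overlapping partner pulse: arrivals within
#' `simultaneity_tol` seconds of each other are simultaneous (default 5 s,
#' one fast frame); the partner-first and target-first proportions are
#' computed among the non-simultaneous pairs, with the simultaneous fraction
#' (over all ternary residences) reported separately.
#'
#' @param records a data.frame from [classify_ternary()].
#' @param simultaneity_tol seconds.
#' @return A list with `partner_first`, `target_first` (proportions among
#'   non-simultaneous ternary pairs), `simultaneous` (proportion of all
#'   ternary residences), and counts `n_ternary`, `n_simultaneous`.
#' @export
arrival_order <- function(records, simultaneity_tol = 5) {
  r <- records[records$ternary, , drop = FALSE]
  n <- nrow(r)
  if (!n)
    return(list(partner_first = NA_real_, target_first = NA_real_,
                simultaneous = NA_real_, n_ternary = 0L, n_simultaneous = 0L))
  d <- r$onset - r$first_overlap       # > 0: partner arrived first
  sim <- abs(d) <= simultaneity_tol
  nonsim <- sum(!sim)
  list(partner_first = if (nonsim) sum(d > simultaneity_tol) / nonsim else NA_real_,
       target_first = if (nonsim) sum(d < -simultaneity_tol) / nonsim else NA_real_,
       simultaneous = mean(sim),
       n_ternary = n, n_simultaneous = sum(sim))
}

#' Residence-count and duration summaries
#'
#' Field-level summaries of target residences: mean residences per template
#' spot, the proportions of short (`< short_cut`) and long (`> long_cut`)
#' residences among uncensored ones, and the mean partner co-occupancy of
#' ternary residences (ternary time as a fraction of residence duration,
#' averaged over ternary residences; supply `records` to get it).
#'
#' @param pulses data.frame of target pulses (or residence records) with a
#'   `censored` column and durations either as a `duration` column or as
#'   `end - onset`.
#' @param n_spots number of template spots observed (> 0).
#' @param short_cut,long_cut duration cutoffs in seconds, `short_cut < long_cut`
#'   (defaults 120 and 300).
#' @param records optional [classify_ternary()] output for the co-occupancy
#'   summary.
#' @return A list: `mean_residences_per_spot`, `fraction_short`,
#'   `fraction_long`, `ternary_cooccupancy_fraction` (NA without `records`).
#' @export
residence_summaries <- function(pulses, n_spots, short_cut = 120,
                                long_cut = 300, records = NULL) {
  if (n_spots <= 0) stop("n_spots must be > 0")
  if (short_cut >= long_cut) stop("need short_cut < long_cut")
  dur <- if ("duration" %in% names(pulses)) pulses$duration
         else pulses$end - pulses$onset
  cens <- if ("censored" %in% names(pulses)) pulses$censored
          else rep(FALSE, length(dur))
  u <- dur[!cens]
  cooc <- NA_real_
  if (!is.null(records)) {
    tr <- records[records$ternary, , drop = FALSE]
    if (nrow(tr)) cooc <- mean(tr$ternary_time / tr$duration)
  }
  list(mean_residences_per_spot = nrow(pulses) / n_spots,
       fraction_short = if (length(u)) mean(u < short_cut) else NA_real_,
       fraction_long = if (length(u)) mean(u > long_cut) else NA_real_,
       ternary_cooccupancy_fraction = cooc)
}
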