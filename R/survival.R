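#' Kaplan-Meier survival estimate for residence lifetimes
#'
#' Unweighted product-limit estimator with right censoring (censored
#' residences reduce the risk set without contributing an event), Greenwood
#' variance, and a 95% confidence band.  The band is linear (untransformed)
#' by default, clipped to `[0, 1]`; a log-log band is available via
#' `conf_type = "log-log"`.  The median is the smallest observed time at
#' which the survival estimate drops to 0.5 or below, and is undefined
#' (`NA`) if the curve never reaches 0.5.  Ties between an event and a
#' censoring at the same time follow the standard convention (events first).
#'
#' Estimation is delegated to [survival::survfit()].
#'
#' @param durations residence durations in seconds (> 0).
#' @param censored logical vector: `TRUE` for right-censored residences.
#' @param conf_type `"plain"` (linear Greenwood band, default) or `"log-log"`.
#' @return An object of class `survival_curve`: a list with `time`, `S`,
#'   `ci_low`, `ci_high`, `n_risk`, `n_event`, `median`, `n_total`,
#'   `n_censored`, and the underlying `survfit` object as `fit`.
#' @examples
#' km <- kaplan_meier(c(10, 20, 30), c(FALSE, FALSE, FALSE))
#' km$median   # 20
#' @export
kaplan_meier <- function(durations, censored = rep(FALSE, length(durations)),
                         conf_type = c("plain", "log-log")) {
  conf_type <- match.arg(conf_type)
  if (!length(durations)) stop("empty input")
  if (length(durations) != length(censored))
    stop("durations and censored must have equal length")
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("durations must be finite and > 0")
  fit <- survival::survfit(
    survival::Surv(durations, !censored) ~ 1,
    conf.type = if (conf_type == "plain") "plain" else "log-log",
    conf.int = 0.95)
  S <- fit$surv
  lo <- pmax(fit$lower, 0)
  hi <- pmin(fit$upper, 1)
  ## all-censored data yield no confidence band from survfit
  if (is.null(lo)) lo <- rep(NA_real_, length(S))
  if (is.null(hi)) hi <- rep(NA_real_, length(S))
  ## tolerance guards exact S = 0.5 steps against cumulative-product rounding
  med <- if (any(S <= 0.5 + 1e-9)) min(fit$time[S <= 0.5 + 1e-9]) else NA_real_
  structure(list(time = fit$time, S = S, ci_low = lo, ci_high = hi,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 median = med, n_total = length(durations),
                 n_censored = sum(censored), conf_type = conf_type,
                 fit = fit),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d (%d censored), median %s\n",
              x$n_total, x$n_censored,
              if (is.na(x$median)) "not reached" else sprintf("%g s", x$median)))
  invisible(x)
}

#' Plot a survival curve with its confidence band
#'
#' @param x a `survival_curve`.
#' @param add logical, add to an existing plot.
#' @param col line color.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.survival_curve <- function(x, add = FALSE, col = "black", ...) {
  t <- c(0, rep(x$time, each = 2))
  s <- c(1, 1, rep(x$S[-length(x$S)], each = 2), x$S[length(x$S)])
  if (!add)
    graphics::plot(t, s, type = "n", xlab = "time (s)",
                   ylab = "survival fraction", ylim = c(0, 1), ...)
  graphics::lines(t, s, col = col)
  if (!all(is.na(x$ci_low))) {
    graphics::lines(x$time, x$ci_low, lty = 2, col = col)
    graphics::lines(x$time, x$ci_high, lty = 2, col = col)
  }
  invisible(x)
}

#' Log-rank comparison of two groups of lifetimes
#'
#' One-degree-of-freedom log-rank statistic over the pooled event times, with
#' the two-tailed p-value from the chi-square tail (via
#' [survival::survdiff()]).
#'
#' @param durations_a,durations_b lifetimes in seconds.
#' @param censored_a,censored_b logical right-censoring flags.
#' @return A list with `chi2`, `p`, and `defined` (`FALSE`, with `NA`
#'   statistics, when neither group has any event).
#' @export
logrank <- function(durations_a, censored_a, durations_b, censored_b) {
  if (!length(durations_a) || !length(durations_b))
    stop("both groups must be non-empty")
  ev <- c(!censored_a, !censored_b)
  if (!any(ev))
    return(list(chi2 = NA_real_, p = NA_real_, defined = FALSE))
  d <- c(durations_a, durations_b)
  g <- rep(c("A", "B"), c(length(durations_a), length(durations_b)))
  sd <- survival::survdiff(survival::Surv(d, ev) ~ g)
  list(chi2 = sd$chisq, p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       defined = TRUE)
}

#' Compare off-rates across replicate experiments
#'
#' Two-sample unpaired t-test (equal variance) on per-replicate off-rate
#' estimates, the replicate-level significance test for ternary versus
#' non-ternary off-rates.
#'
#' @param replicate_k_a,replicate_k_b numeric vectors of per-replicate
#'   off-rates (>= 2 each).
#' @return The two-tailed p-value.
#' @export
compare_off_rates <- function(replicate_k_a, replicate_k_b) {
  if (length(replicate_k_a) < 2 || length(replicate_k_b) < 2)
    stop("need >= 2 replicates per group")
  if (stats::var(replicate_k_a) == 0 && stats::var(replicate_k_b) == 0) {
    ## degenerate: no within-group variability
    return(if (mean(replicate_k_a) == mean(replicate_k_b)) 1 else 0)
  }
  stats::t.test(replicate_k_a, replicate_k_b, var.equal = TRUE)$p.value
}
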