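#!/usr/bin/env Rscript
# Pulse-level residence kinetics at statistical scale (no imaging): simulate
# ~2000 templates with and without partner coupling, partition ternary
# residences, and tabulate off-rates, arrival order and residence summaries.

library(smcoloc)
dir.create("results", showWarnings = FALSE)

analyze <- function(coupling, seed) {
  gt <- simulate_pulse_trains(kinetic_params(coupling_factor = coupling),
                              2000, seed = seed)
  tg <- gt$pulses[gt$pulses$channel == "target", ]
  tg$censored <- tg$truncated
  recs <- classify_ternary(tg, gt$pulses[gt$pulses$channel == "partner", ])
  est <- estimate_off_rates(recs)
  ao <- arrival_order(recs)
  sm <- residence_summaries(tg, 2000, records = recs)
  data.frame(coupling = coupling,
             n_residences = nrow(recs),
             kt = est$kt$k, kt_se = est$kt$se, Nt = est$kt$n_events,
             kn = est$kn$k, kn_se = est$kn$se, Nn = est$kn$n_events,
             partner_first = ao$partner_first,
             simultaneous = ao$simultaneous,
             cooccupancy = sm$ternary_cooccupancy_fraction,
             residences_per_spot = sm$mean_residences_per_spot,
             fraction_short = sm$fraction_short,
             fraction_long = sm$fraction_long)
}

tab <- rbind(analyze(coupling = 1, seed = 30),
             analyze(coupling = 0.5, seed = 31))
write.csv(tab, "results/residence_kinetics.csv", row.names = FALSE)
print(tab, digits = 3)

cat("\nFindings:\n")
cat(sprintf(" - uncoupled control: kt = %.1f, kn = %.1f /hr (both estimate k_off = 29/hr)\n",
            tab$kt[1], tab$kn[1]))
cat(sprintf(" - coupling 0.5: kt = %.1f < kn = %.1f /hr (ratio %.2f; partner stabilizes the target)\n",
            tab$kt[2], tab$kn[2], tab$kt[2] / tab$kn[2]))
cat(sprintf(" - partner arrives first in %.0f%% of non-simultaneous ternary residences\n",
            100 * tab$partner_first[2]))

## replicate-level significance of the coupled kt vs kn contrast
reps <- t(sapply(1:3, function(r) {
  gt <- simulate_pulse_trains(kinetic_params(coupling_factor = 0.5), 1000,
                              seed = 40 + r)
  tg <- gt$pulses[gt$pulses$channel == "target", ]
  tg$censored <- tg$truncated
  est <- estimate_off_rates(
    classify_ternary(tg, gt$pulses[gt$pulses$channel == "partner", ]))
  c(kt = est$kt$k, kn = est$kn$k)
}))
p <- compare_off_rates(reps[, "kt"], reps[, "kn"])
cat(sprintf(" - across 3 replicate fields, kt vs kn two-tailed t-test p = %.3g\n", p))
write.csv(data.frame(replicate = 1:3, reps),
          "results/replicate_off_rates.csv", row.names = FALSE)
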