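# smcoloc

Single-molecule TIRF colocalization analysis for de-novo centromeric
nucleosome assembly assays — and for CoSMoS-style experiments generally,
where surface-immobilized DNA templates are imaged in a slow channel while
the arrival and departure of fluorescent proteins on each template is
followed in fast channels.

The package takes multi-channel image stacks (or simulates them) and
produces the quantities such an experiment is run for:

* **Residence lifetimes** — drift correction of the stack (FFT
  cross-correlation, subpixel), template-spot detection with size and
  time-persistency filters, z-normalized intensity traces with local
  background subtraction, and threshold binarization into ON/OFF pulses
  with right-censoring annotation.
* **Ternary-residence off-rates** — each target residence is partitioned
  relative to a partner protein on the same template: whole-residence
  ternary when the partner arrived first or within one frame (5 s);
  non-ternary head plus permanently ternary tail when the partner arrived
  mid-residence; non-ternary when the partner never appeared.  Pooled
  off-rates are detachment events over observed pool time,

      kt = Nt / sum(T_ternary)      kn = Nn / sum(T_nonternary)

  reported per hour; censored residences contribute time but no event.
* **Survival analysis** — unweighted right-censored Kaplan-Meier curves
  with Greenwood 95% bands, medians, log-rank comparisons, and
  replicate-level t-tests on off-rates.
* **Endpoint colocalization** — native parent/child matching of protein
  spots to template spots in washed-chamber snapshots.
* **Photobleaching stoichiometry** — change-point step counting (binary
  segmentation + BIC, downward steps only) to estimate fluorophore copy
  numbers.
* **CDEII sequence statistics** — the homopolymeric A/T run-content
  statistic (fraction of bp in single-base A or T runs of length >= 4) and
  its correlation with recruitment.
* **A synthetic-data generator** — exact continuous-time Markov binding
  kinetics with optional partner coupling, Gaussian-PSF movie rendering
  with drift, shot/read noise and photobleaching, and CDEII-like sequences
  with controlled run content — providing ground truth for every stage.

## Worked example

Simulate 1000 templates for 45 min with a partner that halves the target's
detachment rate while bound (coupling 0.5), then recover the kinetics:

```r
library(smcoloc)

gt <- simulate_pulse_trains(kinetic_params(coupling_factor = 0.5),
                            n_spots = 1000, seed = 42)
target  <- subset(gt$pulses, channel == "target")
partner <- subset(gt$pulses, channel == "partner")
target$censored <- target$truncated

recs  <- classify_ternary(target, partner, simultaneity_tol = 5)
rates <- estimate_off_rates(recs)
```

```
ternary     kt = 16.3 /hr (se 0.6, N = 781)
non-ternary kn = 29.6 /hr (se 2.9, N = 107)
```

`kn` recovers the uncoupled detachment rate (29/hr); `kt` is lower because
partner binding stabilizes the target — the ratio is ~0.55 rather than the
coupling factor 0.5 because ternary tails keep accruing pool time after the
partner departs (see the methods vignette).  Survival and arrival-order
summaries from the same records:

```r
kaplan_meier(recs$duration[recs$ternary], recs$censored[recs$ternary])
#> Kaplan-Meier curve: n = 846 (65 censored), median 164.071 s
arrival_order(recs)$partner_first
#> 0.89   # partner precedes the target in ~89% of ternary residences
run_fraction("AAAATTGCGTTTT")
#> 0.6153846   # 8 of 13 bp inside A/T runs of length >= 4
```

For the full image path (render movies, drift-correct, detect, trace, call
pulses, analyze) see `run_pipeline()` and the numbered drivers under
`analysis/`:

```sh
Rscript analysis/01_simulate_field.R     # write a simulated field (TIFF + truth)
Rscript analysis/02_image_pipeline.R     # analyze it end to end
Rscript analysis/03_residence_kinetics.R # off-rates at statistical scale
Rscript analysis/04_survival_analysis.R  # KM curves + log-rank
Rscript analysis/05_endpoint_photobleach.R
Rscript analysis/06_sequence_stats.R
```

Each writes its tables under `results/`.

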