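---
title: "Models and methods behind smcoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smcoloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcoloc)
```

# The assay and the quantities it measures

`smcoloc` analyzes colocalization single-molecule spectroscopy (CoSMoS)
experiments in which centromeric DNA templates are immobilized sparsely on a
coverslip, visualized in a slow "template" channel, and the arrival and
departure of fluorescently tagged proteins on each template is followed in
fast "protein" channels by TIRF microscopy.  The observables are *residences*:
contiguous ON intervals of a protein on one template.  From them the package
computes residence lifetimes, right-censored Kaplan-Meier survival curves,
*ternary* residence partitions relative to a partner protein, off-rates per
pool, endpoint colocalization percentages, photobleaching step counts, and
homopolymeric A/T run statistics of the CDEII centromere element.

# The kinetic model and its simulator

Every stage is tested against a generative model
(`simulate_pulse_trains()`), a continuous-time Markov process per template:

* the partner protein B cycles between absent and present with rates
  $k_{on,B}$, $k_{off,B}$;
* the target protein A arrives with rate $k_{on,A}$ while absent; its
  instantaneous detachment rate is $k_{off,A}$ while B is absent and
  $c \cdot k_{off,A}$ while B is present, where $c$ is the
  `coupling_factor` ($c<1$ means the partner stabilizes the target; $c=1$
  decouples the channels).

Event times are exact (Gillespie simulation); quantization onto the 5-s
camera grid is done by the *analysis*, not the simulator, so ground truth
stays exact.  Templates start unoccupied, as when extract first enters the
flow chamber.  Residences still ON at the end of the acquisition are flagged
and become right-censored observations downstream.

Default parameters describe a typical experiment: a 45-min acquisition with
protein frames every 5 s and template frames every 60 s (541 fast frames);
$k_{on,A} = 1.4$/hr (about one target residence per template per
acquisition); $k_{off,A} = 29$/hr (the non-ternary target off-rate scale);
and a persistent DNA-binding partner with $k_{on,B} = 30$/hr,
$k_{off,B} = 6$/hr.  The partner values were fixed by a design scan *before*
the acceptance seeds were frozen, with two requirements: (i) high stationary
partner occupancy (0.83) and high partner co-occupancy of ternary residence
time (~0.9, matching the observed ~84% for the DNA-binding inner-kinetochore
partner), and (ii) enough partner-free residences that both detachment pools
are populated and the ternary/non-ternary off-rate ratio is estimable from a
single ~1000-residence field.  A faster-exchanging partner with the same
occupancy (e.g. $120/24$ per hr) reproduces the published partner dwell time
better but leaves ~35 non-ternary detachments per 1000 residences, which
makes the ratio statistically uninformative at that scale; we chose the
balanced design and note the trade-off here.

## Movie rendering

`render_movie()` converts ground truth into image stacks: uniform background
plus one symmetric 2-D Gaussian PSF (sd `psf_sigma`, default 1.2 px at
0.11 um/px) per ON fluorophore, Poisson shot noise, and Gaussian read noise.
EMCCD excess noise is approximated by the Gaussian read-noise term; the
downstream analysis normalizes traces with robust statistics and is
insensitive to the exact noise law.  Lateral stage drift is a configurable
displacement path (none, linear velocity, or an arbitrary function of time).
Photobleaching is modeled per fluorophore per *exposure* — only frames on
which the channel is excited — with per-exposure probability `bleach_rate`;
the surface-linked template is not bleached by default.  Spots are placed
uniformly at random with a minimum pairwise separation of 8 px so PSFs do
not overlap; at the published density (~1000 templates per 512 x 512 px
field) this rejection sampling is unproblematic.  What the simulator does
*not* emulate: extract biochemistry (chaperone concentrations, remodelers),
3-D PSF structure, camera gain registers, non-uniform illumination, and
aggregation.  Tests passing on simulated movies therefore validate the
*computational* pipeline, not the optical calibration of any particular
microscope.

# Image processing

**Drift correction** (`estimate_drift()`, `apply_drift()`).  Per-frame
translation of the template channel relative to its first frame, by FFT
cross-correlation with subpixel refinement on a locally upsampled
correlation surface (a direct local DFT evaluated on a fine grid around the
integer peak), or by the integer peak with parabolic refinement
(`translation_fit`).  Shifts are linearly interpolated from the 60-s
template grid onto the 5-s protein grid (drift is slow on that scale) and
removed by bilinear resampling; pixels whose source leaves the field are
filled with the frame median and masked.  Rotation and scaling are not
corrected — the published correction is translation-only.  Images are
corrected *before* trace extraction (the alternative, correcting
trajectories afterwards, was rejected so that one spot mask applies to all
frames).

**Spot detection** (`detect_spots()`).  Frames are matched-filtered with a
Gaussian of sd 1 px (roughly the PSF; this approximately doubles detection
SNR for diffraction-limited spots and is the one step we add beyond plain
global thresholding), then binarized at the global median plus
`threshold_sigmas` (default 5) robust standard deviations (1.4826 MAD) of
the smoothed frame.  8-connected components with 2-50 px area are linked
across template frames within 2 px, and spots present in at least 80% of
frames are kept — the time-persistency filter that rejects transiently
binding contaminants.  Centroids are background-subtracted
intensity-weighted means; the first detection's component pixels become the
spot mask.  The published analysis does not print its size or persistence
cutoffs; all are exposed as parameters.

**Trace extraction** (`extract_traces()`).  Per spot and frame: mean
intensity over the spot mask minus the median over a 4-7 px background
annulus, then per-trace z-normalization.  The baseline center and scale are
estimated robustly *from the OFF level*: the noise scale is seeded from
first differences of the trace (blind to slow ON/OFF switching), the center
from the intensity cluster near the trace minimum, and both are refined on
frames within 3 scales of the center.  A plain median/MAD fails here in two
regimes we care about — target traces with ON duty above ~20% (scale
inflation) and partner traces with duty above 50% (the median lands on the
ON level) — whereas the lower-cluster anchor is correct whenever OFF is the
dimmer state, which is physically guaranteed.  Normalization is per trace;
whether the original analysis normalized per trace or per image set is not
documented, and per-set thresholds are still honored by applying one
`z_threshold` to all traces of a channel.

**Pulse calling** (`call_pulses()`).  Frames with $z \ge$ threshold
(default 4) are ON; ON runs separated by at most `max_gap_frames` (default
1) sub-threshold frames merge — a single blinking or noise frame does not
terminate a residence; merged runs spanning fewer than `min_on_frames`
(default 2) frames are discarded.  Durations follow the inclusive-grid
convention `n_frames * dt`: a one-frame residence lasts 5 s, not 0 s, which
keeps 45 min / 5 s = 541 frames consistent and makes the measured duration
an unbiased estimate of the true dwell (the expected number of grid points
inside an interval of length $L$ is $L/dt$).  A run containing the final
frame is right-censored.  For off-rate recovery studies we set
`min_on_frames = 1`: discarding short dwells left-truncates the exponential
and biases the rate estimate down by about $k \cdot t_{min}$, which is
material at the 2-standard-error level; with a z-threshold of 4 the
single-frame false-positive yield is negligible (~$3\times10^{-5}$ per
frame).

# Ternary residence analysis

`classify_ternary()` partitions each target residence relative to the
partner channel on the same spot, with half-open interval semantics
(pulses that merely touch end-to-onset share no frame and do not overlap):

* partner overlaps and arrived no later than `simultaneity_tol` (default
  5 s, one fast frame) after the target onset: the **whole** residence is
  ternary time;
* the first overlapping partner arrives later: the head before partner
  arrival is non-ternary, the tail from partner arrival to target end is
  ternary **regardless of partner departure** — partner disappearance is
  indistinguishable from partner photobleaching, so first contact marks the
  residence permanently;
* no partner ever overlaps: the whole residence is non-ternary.

The detachment event goes to the pool active at the residence end; censored
residences contribute time to their pools but no event (the
maximum-likelihood treatment of right-censored exponential dwells).  A
non-ternary head never contributes an event — the molecule did not detach
when the partner arrived.  Off-rates are pooled estimators,

$$k_t = \frac{N_t}{\sum T_{ternary}}, \qquad
  k_n = \frac{N_n}{\sum T_{nonternary}},$$

reported per hour with the Poisson approximation $se = k/\sqrt{N}$ used for
display only; formal comparisons across replicate extracts use the
equal-variance two-tailed t-test (`compare_off_rates()`).  Note $k_t$ is a
*pool* rate: when the partner departs mid-tail the molecule detaches at the
non-ternary rate during part of the ternary pool time, so with coupling
$c = 0.5$ and co-occupancy $f$, the expected ratio is
$k_t/k_n \approx 1 - f(1-c)$ — about 0.55 under the default kinetics, not
$c$ itself.  The classification is verified exactly against an independent
brute-force oracle that rasterizes pulses onto a 1-s grid and reasons about
per-unit co-presence.

`arrival_order()` classifies ternary residences by the onset difference to
the first overlapping partner (within tolerance = simultaneous; proportions
of partner-first/target-first among the non-simultaneous pairs, the
simultaneous fraction reported separately), and `residence_summaries()`
reports residences per template, short (<120 s) and long (>300 s) residence
fractions among uncensored residences, and mean partner co-occupancy.

# Survival analysis

`kaplan_meier()` wraps the product-limit estimator of the `survival`
package: unweighted right censoring, Greenwood variance with a linear
(untransformed) 95% band clipped to [0, 1] (log-log available by flag),
events processed before ties at the same time, and the median defined as
the smallest observed time with $S(t) \le 0.5$ (so for uncensored data it
is the lower sample median; a small numerical tolerance guards the exact
$S = 0.5$ step).  `logrank()` is the one-degree-of-freedom log-rank test
over pooled event times.  The estimator is cross-checked in the test suite
against hand-computed product limits, the closed-form exponential median
($\ln 2 \cdot 3600/25 \approx 99.8$ s at 25/hr), and a 2000-replicate
type-I-error calibration of the log-rank test.

# Endpoint colocalization

`colocalize()` re-implements a parent/child object relation natively: a
template spot is colocalized when at least one protein-spot centroid falls
within its pixel mask dilated by `match_radius` (default 1 px; the original
pipeline's distance criterion is not printed, so containment after 1-px
dilation is our documented choice), and each protein spot satisfies at most
one template (nearest centroid).  Channels are assumed co-registered.
Percentages aggregate over fields as mean ± sd.

# Photobleaching step counting

The published stoichiometry analysis is not described procedurally, so
`count_steps()` is our own change-point formulation and results are
method-dependent by construction: greedy binary segmentation of the trace
into piecewise-constant levels, number of change points selected by BIC
($n \log(RSS/n) + (2k+2)\log n$ over the nested path; AIC available), then
transitions smaller than `min_step_sd` (default 3) frame-noise sd are merged
away — fluorophore steps have finite brightness, and this guard removes
noise splits that the likelihood criterion alone admits.  Only *downward*
transitions count as bleaching steps; upward transitions (blinking returns)
stay in the fit but not in the count.  Minimum segment length is 3 frames,
so two fluorophores bleaching within ~2 frames of each other register as
one step; the trace simulator accounts for this when reporting truly
visible steps.  Simulated 400-frame dimer traces (per-frame bleach
probability 0.01, so <2% of fluorophores survive the observation) are
classified as two-step in ~90% of cases at step SNR 8.

# CDEII sequence statistics

`run_fraction()` computes the fraction of positions inside maximal
single-base A or T runs of length ≥ 4 (`AAAA` counts, `ATAT` does not; a
7-run contributes all 7 positions), the statistic whose value across
centromere variants tracks centromeric-histone recruitment.  It operates on
whole FASTA records or on CDEII intervals supplied as 0-based half-open BED.
`generate_cdeii_sequence()` solves the inverse problem for testing: given
length, A+T fraction and target run fraction, it lays down homopolymer
blocks of 4-8 bp (natural CDEII elements contain no longer runs),
alternating A/T so adjacent blocks never merge, and fills the remainder with
a greedy assignment that never creates an unplanned 4-run nor extends a
block; the construction is verified against `run_stats()` and retried (still
under the caller's seed) in the rare stuck configurations.  The native CEN3
CDEII sequence itself is not bundled: it must be retrieved from the
reference yeast genome, which requires network access; the package
validates the statistic on constructed sequences and on the published
variant table (`cdeii_recruitment_table()`) instead.

# Numerical choices and degenerate inputs

* Registration refuses zero-variance frames; correction fills out-of-field
  pixels with the frame median and records a validity mask.
* Detection thresholds are robust (median/MAD), so constant offsets and
  gain changes do not move counts; z-traces are invariant to affine
  rescaling of the raw movie to ~1e-6.
* Off-rate pools with zero observed time return `defined = FALSE` rather
  than erroring; log-rank with no events in either group likewise.
* Degenerate t-test inputs (zero variance in both groups) return p = 1 for
  equal means.
* All simulation, rendering and pipeline entry points take an integer seed
  and are bit-reproducible given it.

# Problem sizes

The shipped tests and acceptance script run at desk scale, chosen as the
smallest sizes at which each statistical claim is testable at its stated
tolerance: 1000-2000 residences for rate recovery, 100 replicate fields of
~1000 residences for the coupling direction, a 256-px / 200-template /
45-min field for the end-to-end image run, 500 traces for photobleaching,
2000 replicates for log-rank calibration.  The published experiments are
3-4 fields of ~1000 templates each; the pipeline code is identical at that
scale.

# Known limitations

* Traces whose ON duty approaches 100% leave no OFF cluster to anchor the
  baseline; such spots (like permanently occupied templates in a protein
  channel) are not reliably called.
* The ternary partition inherits the published convention that a residence
  stays ternary after first partner contact; it therefore *underestimates*
  the pure ternary stabilization when the partner exchanges quickly (the
  ratio formula above quantifies this).
* Step counting merges near-simultaneous bleaching events and is blind to
  steps in the first or last two frames.
* No chromatic-offset model between channels (an optional translation
  calibration hook exists but default-off), no Cox regression, no on-rate
  estimation.
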