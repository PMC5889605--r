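---
title: "Gait-cycle-referenced sEMG mode analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-cycle-referenced sEMG mode analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgmodes)
```

## The analysis problem

Surface electromyography of locomotion in animals has two normalization
problems that this package addresses together. Amplitude cannot be
referenced to a maximal voluntary contraction, so each electrode's
signal is normalized to its own maximum within a data-collection day
(DCD), bounding the scale at 1. Timing is only meaningful relative to
the motion cycle, so all activity is expressed in percent of the stride
(hoof-on to next hoof-on, 0–100%). On that common axis, the *pattern*
of a muscle's activity is summarized by the locations and magnitudes of
a small number of activity foci — modes of a Gaussian mixture fitted to
the phases of the largest envelope peaks — which are stable enough to
compare across electrode positions, gaits, body sides and sessions.

## Pipeline stages and their parameters

| Stage | Parameter | Default | Why |
|---|---|---|---|
| Kinematic smoothing | Butterworth low-pass | order 4, 10 Hz, zero-phase | stride content of treadmill hoof motion is < 10 Hz; zero-phase so events are not delayed |
| Cycle cutting | position threshold | min + 10% of range | robust plateau detector on smooth treadmill data |
|  | velocity gate | 10% of peak \|velocity\| | rejects the moving-but-low part of swing |
|  | hysteresis | 0.05 s | bridges chatter near thresholds |
| Minimum cycles | walk / trot | 6 / 13 per trial | protocol minimum; trials below it are excluded, not padded |
| EMG chain | order | DC removal → rectify → 120 Hz → 20 Hz low-pass → normalize | fixed; there is deliberately no high-pass stage |
| Decimation | anti-alias filter | zero-phase, order 4, 0.4×target (48 Hz) | rectification creates harmonics that would alias |
| Envelope | Butterworth low-pass | order 4, 20 Hz, zero-phase, clipped at 0 | linear-envelope smoothing of the rectified signal |
| Normalization | scope | per electrode per DCD, gaits pooled | one scaling constant per (side, position, DCD); per-gait scope available via `normalization_scope = "dcd_gait"` |
| Peaks | per cycle | 10 highest interior maxima | caps each cycle's contribution; ties break to the earlier phase, plateaus contribute their first sample |
| Mixture | `K_max` | 10 | upper bound on the number of modes |
|  | `merge_tol` | 2% of cycle | components closer than this are one focus of activity |
|  | `weight_floor` | 1/(4·n_cycles) | a mode claiming fewer than ~2–3 peaks of a typical group is noise |
|  | `sd_floor` | 0.25% of cycle | prevents singular components |
|  | restarts / tolerance | 10 / 1e-8 relative log-likelihood | multimodal likelihood; deterministic under the seed |
| Statistics | significance | 0.05 | gate for Shapiro–Wilk routing and all tests |

## The mixture model

Pooled peak phases $x_1,\dots,x_n$ of one horse × gait × side ×
electrode group are modelled as

$$p(x) = \sum_{k=1}^{K} w_k\, \mathcal{N}(x \mid \mu_k, \sigma_k^2),$$

fitted by EM. Initialization places components at phase quantiles,
refined by k-means; subsequent restarts resample initial centers from
the data. After convergence, components whose means lie within
`merge_tol` are merged *transitively* (single linkage): a chain of
overlapping components is one mode, which is what lets an
over-parameterized 10-component fit collapse onto, say, two true
clusters while leaving ten well-separated bursts untouched. Components
below `weight_floor` are then dropped and weights renormalized.

The surviving means are the mean mode locations (MML). Amplitude enters
only after the fit: each peak is assigned to its maximum-responsibility
mode, and the mode's mean mode value (MMV) is the responsibility-
weighted mean amplitude of its peaks. This keeps the mixture
one-dimensional — mode count stays identifiable, and MML remains a pure
timing quantity — while MMV is bounded by 1 because normalized
amplitudes are. A two-dimensional (phase, amplitude) mixture was
considered and rejected: amplitude spread differs across modes in a way
that destabilizes the mode count.

Phases are treated on a linear [0, 100) axis; a mode of activity
spanning the cycle boundary can split into a mode near 0 and one near
100. This is a known limitation; only the left–right comparison uses
circular distance.

### Stance/swing summaries

Each mode is assigned to stance or swing by its MML. The phase summary
reports, per phase, the mean of the mode MMVs and the MML of the mode
with the largest MMV (the dominant mode). The dominant-mode rule is a
documented choice: when a phase holds several modes, its
"representative timing" is taken from the strongest activity focus
rather than an average that may fall between foci.

### Common phase reference for the two sides

Left- and right-side envelopes are both phase-referenced to the *left*
hind cycle, while stance/swing classification uses each limb's own
events (the right limb's stance interval, expressed on the left-cycle
axis, wraps around 0). This is the only referencing under which the
left–right timing comparison is meaningful: with hind limbs alternating
at half a cycle, corresponding MMLs should differ by about 50% of the
cycle, and the package's symmetry-recovery experiment confirms the
pipeline reproduces that shift to within a percentage point. Cycles are
cut at hoof-on (not hoof-off); the convention is echoed in every run
manifest, because stance/swing MML values are not comparable across
conventions.

## The synthetic generator

`generate_hoof_trajectory()` emulates vertical hoof displacement as a
flat minimal stance plateau (duty factor 0.62 at walk, 0.42 at trot —
typical equine treadmill values) and a smooth positive swing arc
(half-sine raised to the power 0.5, giving the steep lift-off and
touch-down of real hoof motion and a crisply delimited plateau). Cycle
durations default to 1.1 s (walk) and 0.7 s (trot) — treadmill belt
speed, and hence cycle duration, is a free parameter in the protocol —
with a 2% coefficient of variation of timing jitter. A short late-swing
lead-in precedes the first hoof-on so every cycle boundary is an
observable swing-to-stance transition.

`generate_emg_channel()` models raw sEMG as zero-mean Gaussian
broadband noise amplitude-modulated by per-cycle Gaussian burst
envelopes — the standard interference model for surface EMG — at
1200 Hz (an integer multiple of 120 Hz, making decimation exact; the
true recording rate of wireless sEMG systems is higher than 120 Hz but
unspecified in typical protocols). Kinematic and EMG generators seeded
identically share one jittered cycle schedule, so ground truth is
consistent across modalities; `generate_study()` writes it to a
manifest so segmentation and mode recovery can be scored without
circularity.

What the generator does *not* emulate: soft-tissue marker artifact,
electrode crosstalk, motion-artifact transients, non-Gaussian amplitude
distributions, or inter-electrode correlation. Passing tests therefore
demonstrate that the pipeline recovers the structure it assumes —
burst-modulated noise referenced to detectable cycles — not that it is
robust to every pathology of real recordings.

## Numerical choices

* **Zero-phase filtering with reflection padding.** All filters run
  forward–backward (squaring the magnitude response, cancelling phase),
  since group delay would bias MML, the headline quantity. Signals are
  extended by odd reflection before filtering so start-up transients
  decay inside the padding (pad length ≈ 12·fs/fc samples, enough for
  the slowest pole to decay below 1e-12).
* **Decimation.** Integer rate ratios use anti-alias filtering followed
  by index selection; non-integer ratios interpolate the anti-aliased
  signal linearly onto the target grid (adequate because the signal is
  already band-limited to 0.4× the target rate).
* **Event refinement.** The stance mask requires low position *and* low
  velocity; because the velocity gate settles a few samples inside the
  plateau, detected events are refined outward to the position-only
  threshold crossing, which lands within ~2 samples of truth on
  synthetic data.
* **Intervals and indices.** All cycle intervals are half-open
  `[start, end)` with 1-based sample indices, the natural R convention;
  stance and swing partition each cycle exactly.
* **Degenerate inputs.** Constant traces are valid for the filters
  (DC gain 1) but raise an insufficient-cycles error (count 0) in
  segmentation; an all-zero channel raises a degenerate-channel error
  at normalization; a peak set with a single distinct phase yields a
  single mode at that phase; identical paired samples return a
  degenerate result with adjusted p = 1.
* **Statistics conventions.** Sample variances use n−1 throughout;
  quartiles use linear interpolation (R type 7), which matters when
  comparing integer-printed IQRs; Cronbach's alpha is the raw-score
  (covariance) form, with rows being horse × side × electrode groups by
  default — the row unit is configurable since published alphas rarely
  state it. Bonferroni families are recorded in every output row so
  users can re-family the comparisons.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
data at the protocol's own scale: trials of 6 walk / 13 trot cycles
(18 and 39 per day), recovery experiments on 20-cycle trials, mixture
fits on ~200 pooled peaks, 20-seed mode-recovery sweeps, and 1000-draw
null calibrations of the paired route. These sizes were chosen as the
smallest at which the contracts they verify are meaningful.

## Known limitations

* Linear phase axis inside the mixture (boundary-spanning modes split).
* The MMV definition ("responsibility-weighted mean amplitude") is one
  of several defensible readings of "magnitude of activity"; it is
  monotone in burst height and bounded by 1, but it is not an integral
  of the envelope, so broad and narrow bursts of equal height score
  alike.
* Whether the original normalization pooled gaits within a day is not
  documented in the protocols this mirrors; pooled is the default here
  and the alternative is a switch.
* The segmentation thresholds (10% position, 10% velocity) are tuned
  for smooth treadmill data; overground or pathological gait may need
  the configurable variants.
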