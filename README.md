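# emgmodes

Gait-cycle-referenced mode analysis of surface electromyography (sEMG)
for treadmill locomotion studies — built around the equine gluteus
medius, but applicable to any cyclic-locomotion sEMG recorded alongside
hoof (or foot) marker kinematics.

## The problem

In animals, sEMG amplitude cannot be normalized to a maximal voluntary
contraction, and activity timing only has meaning relative to the motion
cycle. The pipeline implemented here addresses both: electrical activity
is normalized to its maximum per electrode per data-collection day
(DCD), timing is normalized to the motion cycle (0–100%, hoof-on to next
hoof-on), and the *pattern* of activity is summarized by a small number
of reproducible quantities suitable for test–retest reliability
analysis across sessions.

## The method

For each horse × gait × side × electrode group:

1. **Kinematics** — vertical hoof displacement (120 Hz) is zero-phase
   Butterworth low-pass filtered (order 4, cutoff 10 Hz); motion cycles
   are cut at hoof-on; stance and swing are identified by a
   position-and-velocity threshold rule; each cycle's duration is
   normalized to 100%. Right-limb events are referenced to the left
   cycle so both sides share one phase axis while stance/swing stay
   ipsilateral.
2. **sEMG conditioning** — DC-offset removal, full-wave rectification,
   decimation to 120 Hz, zero-phase Butterworth low-pass (order 4,
   cutoff 20 Hz; no high-pass), then normalization by the single pooled
   maximum per electrode per DCD so max = 1.
3. **Mode analysis** — the ten highest envelope peaks per cycle are
   pooled over all cycles of the group, and the pooled peak phases
   x₁…x_n are modelled by a one-dimensional Gaussian mixture

   p(x) = Σₖ wₖ · N(x | μₖ, σₖ²),  k = 1…K ≤ 10,

   fitted by EM with multiple restarts, followed by merging of
   components with means closer than 2% of the cycle and dropping of
   components with weight below 1/(4·n_cycles). Each surviving μₖ is a
   **mean mode location** (MML, % of motion cycle); each mode's **mean
   mode value** (MMV ≤ 1) is the responsibility-weighted mean amplitude
   of the peaks it claims. Modes are split into stance and swing
   summaries.
4. **Statistics** — Shapiro–Wilk-routed paired comparisons (paired t /
   Wilcoxon signed-rank) and repeated-measures comparisons across DCDs
   (RM-ANOVA / Friedman), Bonferroni-corrected, plus Cronbach's alpha
   for across-day reliability of MML and MMV.

A synthetic-data generator (cyclic hoof displacement with distinct
stance/swing dynamics; sEMG as burst-amplitude-modulated Gaussian noise
with per-cycle timing jitter) makes every stage testable without any
recorded data, with ground truth written alongside.

## Worked example

```r
library(emgmodes)

## one synthetic group: 18 walk cycles, two activity bursts
## (early stance at 10% of the cycle, late swing at 88%)
gs     <- gait_spec("walk", n_cycles = 18)
bursts <- list(burst_spec(10, rel_amplitude = 1.0, width_pct = 4),
               burst_spec(88, rel_amplitude = 0.6, width_pct = 3.5))
raw  <- generate_emg_channel(gs, bursts, rate = 1200, noise_floor = 0.05,
                             seed = 2024)
env  <- normalize_session(list(preprocess_emg(raw)))[[1]]
hoof <- generate_hoof_trajectory(gs, rate = 120, seed = 2024)

cycles <- ground_truth_cycles(hoof)
peaks  <- pool_peaks(lapply(seq_along(cycles), function(i)
  extract_cycle_peaks(env, cycles[[i]], cycle_id = i)))
fit <- fit_mixture(peaks, K_max = 10, seed = 1)
print(fit)
#> <mixture_fit: 9 modes, loglik -762.239>
#>   mode MML_pct   MMV weight   sd
#> 1    1    9.47 0.830  0.129 1.58
#> 2    2   27.34 0.052  0.124 3.67
#> ...
#> 9    9   87.52 0.465  0.124 1.37

summarize_by_phase(fit, stance_interval = c(0, 62), swing_interval = c(62, 0))
#> MML stance 9.5%, MMV stance 0.18; MML swing 87.5%, MMV swing 0.19
```

The two injected bursts are recovered as the dominant modes (MML 9.5%
and 87.5% against true centers 10% and 88%, with the largest MMVs,
0.83 and 0.47); the remaining low-MMV modes absorb the noise-floor
peaks that the ten-peaks-per-cycle rule necessarily collects — the same
behaviour that makes real recordings show 8–10 modes. The full study
pipeline (`run_pipeline()` over a `pipeline_config()`) adds
segmentation, both sides, normalization scopes, TSV outputs and the
statistics layer; `inst/cli/emgmodes.R` wraps it for shell use.

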