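---
title: "Spectral-threshold sleep scoring and the REMS-continuity biomarker analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-threshold sleep scoring and the REMS-continuity biomarker analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnarch)
```

somnarch implements, end to end, the analysis pipeline of a mouse
fear-conditioning (PTSD-model) sleep study: semi-automatic vigilance-state
scoring of EEG/EMG recordings from spectral band-power thresholds,
sleep-architecture quantification across the circadian day, behavioral
endpoint computation, and the statistics that relate pre-trauma rapid eye
movement sleep (REMS) continuity to post-trauma hyperarousal. Because no
recordings from such studies are deposited publicly, the package ships a
calibrated synthetic generator for every input, and all validation is
parameter recovery: the generator plants known structure, the pipeline must
find it.

## The scoring model

Mouse vigilance states are scored on consecutive 4-s epochs of a two-channel
recording (EEG band-limited 0.5–29 Hz, EMG; both at 64 Hz). Per epoch the
package computes a plain FFT periodogram (256 samples, rectangular window,
0.25 Hz resolution, DC excluded) and integrates it with the trapezoid rule
over five bands:

| band  | range (Hz)  |
|-------|-------------|
| delta | 0.5–5       |
| theta | 6–9         |
| alpha | 10–15       |
| eta   | 16–22.5     |
| beta  | 23–31.75    |

The 5–6 and 9–10 Hz gaps belong to no band. Two composite features sharpen
the NREMS/REMS contrast:

$$\delta' = \frac{\delta \cdot \alpha}{\eta \cdot \beta}, \qquad
  \theta' = \frac{\theta^2}{\delta \cdot \alpha}.$$

The underlying formulas from the rat-scoring lineage this algorithm descends
from are printed in operator-ambiguous form; the grouping above is the
reading consistent with the classifier's direction (NREMS has high $\delta'$,
REMS has low $\delta'$ together with high $\theta'$). A useful consequence of
this grouping is that both composites are ratios of degree-2 products of
band powers, hence exactly invariant under amplitude rescaling of the EEG —
threshold settings transfer across gain changes. Epochs with a zero
denominator are flagged indeterminate; the classifier carries the previous
epoch's label over them (the first epoch defaults to NREMS) rather than
inventing a fifth state.

Scoring applies three thresholds in fixed priority order:

1. EMG RMS above the movement threshold → WAKE;
2. otherwise $\delta'$ below the delta threshold **and** $\theta'$ above the
   theta threshold → REMS;
3. everything else → NREMS.

Finally every maximal WAKE run shorter than 3 epochs (12 s) is relabelled as
a microarousal (MA). Runs touching the recording boundary are eligible — no
exception is stated in the scoring rule, and exempting them would make the
first and last epochs of a slice behave differently from interior ones. No
further smoothing or hysteresis is applied.

### Automatic thresholds

The original procedure sets the three thresholds manually and proof-reads
the scores; both steps are irreproducible. somnarch replaces them with a
deterministic rule: each of log EMG RMS, log $\delta'$ and log $\theta'$ is
split at the variance-minimizing (Otsu) cut point, computed exactly over all
candidate cut points by a cumulative-sum scan rather than on a binned
histogram (binning would add a resolution parameter with no benefit at
20&nbsp;000 epochs). Manual values can override any subset. Two safeguards
handle degenerate recordings: if a feature has fewer than two distinct
values, or the best split explains less than half of the feature's variance
(an essentially unstructured distribution), the threshold falls back to the
median with a warning. Thresholds are fitted per recording by default; for
single-state or otherwise unrepresentative slices the intended workflow is
to fit thresholds on a full mixed recording of the same animal and pass them
to `score_recording()` explicitly.

The theta threshold deserves a note: over a whole day REMS occupies only
5–10% of epochs, so the Otsu split of log $\theta'$ typically falls between
the NREMS and WAKE clusters, not at the REMS boundary. This is harmless by
construction — WAKE epochs are claimed by the EMG rule before the spectral
rules are consulted, and NREMS sits far below any such cut — but it is the
reason the threshold values themselves should not be interpreted as REMS
boundaries.

## The synthetic generator

`simulate_hypnogram()` draws a per-epoch WAKE/NREMS/REMS sequence from a
phase-dependent Markov chain: in state $s$ the chain leaves with probability
$1/m_s$ per epoch ($m_s$ = mean bout length in epochs) and then redraws the
state from $\mu_s \propto p_s / m_s$, where $p$ is the target occupancy of
the current 6-h Zeitgeber phase. The redraw may return the current state,
which simply extends the bout; the stationary occupancy of this chain is
*exactly* $p$ for any feasible $(p, m)$, which is why this construction was
chosen over an embedded semi-Markov chain (whose rates would have to be
re-solved approximately). Bout lengths are geometric — memoryless at the
epoch scale — the simplest law that reproduces both occupancy and
episode-count structure. Relaxation after a phase switch takes on the order
of one mean bout (~25 epochs of 5400 per phase), so phase transients are
negligible.

Default occupancy targets are the study's pooled baseline values per phase
(dark phases I–II, light phases III–IV). The printed per-phase percentages
do not always sum to 100 (phase IV sums to ~97); the package takes NREMS and
REMS at their printed pooled values and assigns WAKE the complement, which
reproduces the printed circadian summaries (77.3% dark-phase WAKE, 65.4%
light-phase NREMS, 8.5% light-phase REMS) exactly by arithmetic. Default
dwell means are 25/20/15 epochs (100/80/60 s) for WAKE/NREMS/REMS —
realistic polyphasic mouse sleep, giving ~30 REMS episodes per 6-h light
phase.

`synthesize_signals()` builds each EEG epoch in the frequency domain: every
analysis band receives complex Gaussian spectral amplitudes totalling the
state's band-profile weight, and the epoch is the real inverse FFT. Default
profiles make NREMS delta-dominant, REMS theta-dominant and WAKE mixed; EMG
is white noise with per-state RMS 4/1/0.8 (WAKE ≫ sleep). With these
defaults the log-feature clusters are separated by 2–4 units against
within-cluster spreads of ~0.4–0.7, and the full pipeline recovers simulated
hypnograms with ≥ 99% epoch accuracy. That is deliberately cleaner than real
mouse EEG: the generator has no artifacts, no state-transition ambiguity, no
drift, and no spindles or phasic REM events. Passing the recovery tests
therefore validates the *machinery* (filters, spectra, thresholds, rules,
bookkeeping), not the field performance of the scorer on noisy recordings.

`simulate_cohort()` plants the biomarker structure. Per animal a trivariate
standard-normal latent draw generates the baseline phase-IV REMS episode
count, the NREMS→REMS transition count, and the 115-dB acoustic startle
response (ASR), with correlations (0.78, 0.80) in the shocked group and 0 in
controls — the linear latent-trait model matches the linear fit used for the
association in the original analysis. Episodes and transitions are latently
correlated at 0.95, since they count nearly the same events. Counts are
rounded to integers (mean 30, SD 6 episodes; the study reports no
between-animal dispersion, so these are free parameters of the generator);
rounding attenuates the realized correlation by ~0.1%, far below the
recovery tolerance. Phase-IV REMS is multiplied by 1.5 on days 0/1/55 in
shocked animals (the study prints box plots, not an effect magnitude; 150%
of baseline is a realistic elevation consistent with them), with day-1 and
day-55 baseline-normalized changes correlated at $\sqrt{0.54}$ so their
squared correlation is 0.54. Freezing percentages are generated
independently of all sleep traits in both groups, mirroring the reported
absence of a sleep–freezing association.

## Architecture and statistics

Zeitgeber hours map to phases by half-open intervals [0,6), [6,12), [12,18),
[18,24) — the printed "1–6 h / 7–12 h" labels are whole-hour names for the
same 6-h blocks. Occupancy is reported over all four states (summing to
100%) or with MA merged into WAKE for circadian summaries. Episodes are
maximal runs; boundary-truncated episodes are counted but flagged, so either
convention can be recovered. Transition counts are adjacency counts with a
zero diagonal and satisfy the identity (total transitions) = (episodes − 1)
on any slice. State-specific band power is the mean over a state's epochs of
the per-epoch trapezoid-rule band AUC (averaging per epoch rather than
pooling spectra keeps states with unequal durations comparable). All
post-shock values can be normalized to the baseline group mean (100% =
baseline). On the shock day, phase I is flagged excluded because the animals
spent part of it outside the recording cage.

The repeated-measures analysis mirrors the original plan: Wilks' lambda
multivariate tests for group (on day-averaged variables), day and group×day
(on day-minus-baseline contrast variables) over a small subgroup of
dependent variables — subgrouping avoids collinearity among the many sleep
parameters; the default grouping is occupancy | episodes | transitions |
power, configurable since the original subgrouping is not enumerated. When a
multivariate effect reaches α = 0.05, univariate mixed-model F tests follow
per variable, then Bonferroni-corrected contrasts: day-vs-baseline within
group (six contrasts, α/6 ≈ 0.0083) and group-vs-group per day (four
contrasts, α/4 = 0.0125), matching the significance conventions of the
study's figures. No sphericity correction is applied, as none is reported.
With a single variable the multivariate tests reduce to the exact univariate
F. Correlation tests (Pearson, and Spearman as Pearson on average ranks) use
the t transform for p values and are deliberately uncorrected for
multiplicity, as in the original analysis.

## Numerical choices

* **Filter**: eight-pole Butterworth band-pass 0.5–29 Hz applied
  forward–backward (`signal::filtfilt`), i.e. zero-phase, so filter delay
  cannot smear state boundaries across epochs; the 48 dB/octave analog
  roll-off of the recording hardware is met or exceeded. Signals shorter
  than three filter lengths are rejected.
* **Spectra**: rectangular window, no overlap — the convention implied by a
  plain FFT on consecutive intervals. Band integration includes the
  boundary bins at 0.25 Hz resolution.
* **EMG RMS** is computed on the raw (unfiltered) EMG over the same 256
  sample window as the EEG epoch.
* **Ties and degenerate inputs**: Otsu cut points between tied values are
  not realizable thresholds and are skipped; zero-denominator composite
  epochs are flagged rather than propagated as NaN; a zero or negative
  baseline mean yields an undefined (NA) normalized value with a warning.
* **Seeds**: every generator takes an explicit integer seed and all
  downstream seeds are derived deterministically, so whole-study output is
  a pure function of the configuration.

## Problem sizes used in validation

The test and acceptance suites size their simulations as follows: staging
recovery uses 8 animals × 24 h (the study's group size and recording
length); correlation recovery uses one cohort of n = 2000 per group, where
the sampling SD of r at ρ ≈ 0.78 is ~0.009 against a ±0.03 tolerance
(Fisher-z averaging over many n = 8 replicates was rejected because the
z-scale mean back-transforms with an upward bias of ~ρ/2(n−1) ≈ 0.06 at
n = 8, larger than the tolerance); the type-I-error calibration of the
repeated-measures group test uses 1000 null simulations of 2 × 8 animals,
giving a Monte-Carlo SE of 0.7 percentage points.

## Known limitations

* The generator's spectral realism is intentionally minimal (stationary
  Gaussian band noise per epoch, independent epochs); scorer accuracy on
  real recordings will be lower and threshold quality depends on the
  recording actually containing all three states.
* Manual proof-reading of machine scores — part of the original workflow —
  is out of scope, as are artifact rejection and notch filtering.
* The cohort table carries the latent-model episode and transition counts;
  hypnograms generated for the same animals match them in expectation, not
  exactly.
* MANOVA follow-ups assume balanced complete cases and will refuse
  unbalanced tables rather than approximate them.

## A worked example

```{r, eval = FALSE}
sp <- sim_params(seed = 1)
h <- simulate_hypnogram(sp, n_days = 1)       # ground truth
rec <- synthesize_signals(h, sp)              # EEG/EMG at 64 Hz
scored <- score_recording(rec)                # auto thresholds
sapply(split_phases(scored), state_occupancy, merge_ma = TRUE)

co <- simulate_cohort(cohort_params(n_per_group = 8, seed = 1))
sh <- subset(co$table, group == "shocked")
correlation(sh$baseline_rems_episodes, sh$asr_115)
```
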