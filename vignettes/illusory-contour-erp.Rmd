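---
title: "Mass-univariate ERP analysis of illusory-contour processing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-univariate ERP analysis of illusory-contour processing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icerp)
```

## The scientific setting

Kanizsa figures — arrangements of "pac-man" inducers whose openings align —
produce a vivid illusory contour (IC): a diamond is perceived although no
luminance edge exists along most of its outline. Event-related potentials
(ERPs) to Kanizsa (K) versus rotated-inducer control (C) stimuli differ in
two occipito-parietal negative components: an early IC-sensitive deflection
around 130–166 ms and a later one around 234–290 ms. A two-stage account of
attentional modulation predicts that the early component depends on whether
spatial attention covers the contour region, while the later component
depends on whether the contour is task relevant. The experimental design
that separates these factors uses three tasks on identical stimulus
sequences: a Kanizsa-figure task (KF: attend the contour region, contour
task-relevant), a central-color task (CC: attend the contour region,
contour irrelevant) and a peripheral-color task (PC: attend outside the
contour region, contour irrelevant). The predicted pattern is that the
early K−C effect is equal in KF and CC and absent in PC, while the later
effect is present only in KF.

`icerp` re-implements this analysis as a reusable, fully tested pipeline.
Because no data were deposited with the study it emulates, the package
includes a first-class synthetic-data generator that encodes the design, so
that every downstream stage — preprocessing, mass-univariate statistics,
leave-one-subject-out (LOSO) window selection, repeated-measures inference —
can be exercised and calibrated without any download.

## The synthetic-data generator

`generate_dataset()` produces one continuous multi-channel recording per
subject × task at 500 Hz on a 64-scalp-channel extended 10–20 montage plus
HEOG/VEOG. Key modelling choices:

* **Stimulus sequence.** 400 trials per task by default (the tests and
  calibration studies use the scaled design of `scaled_config()`, 60
  trials), split exactly evenly between K and C, presented for 150 ms with
  inter-stimulus intervals uniform on 900–1200 ms. Within a subject the
  sequence and its timing are identical across the three tasks, as in the
  emulated procedure. Records begin 1 s before the first stimulus so that
  epoching with padding is genuinely exercised.
* **Components.** Each ERP component is a raised-cosine (Hann) bump —
  smooth, compactly supported, no ringing — with full width
  `2 * temporal_width`, peak at `peak_latency`, projected through a fixed
  channel-weight topography. Defaults: P1 (+2 µV, 100 ms) and N1 (−3 µV,
  170 ms) identical for K and C (so they cancel in difference waves), an
  early IC component (−1.5 µV, support exactly 130–166 ms, present in the
  K condition of KF and CC only) and a later IC component (−2 µV, support
  234–290 ms, K condition of KF only), both with occipito-parietal
  topography centred on PO5/PO6.
* **Variability.** One Gaussian amplitude offset per (subject, component),
  applied in every cell where the component is present — a subject with a
  large early component has it large in both KF and CC, which is both
  physiologically sensible and what makes the KF−CC comparison a true null.
  Independent Gaussian per-trial amplitude jitter. Channel noise is
  independent white plus `1/f^α` ("pink") noise per channel; spatial noise
  correlation is deliberately out of scope so that the null calibration
  stays interpretable.
* **Artifacts.** Blinks are a Poisson process (default 2/min) of 80 µV
  raised-cosine deflections on VEOG, projected frontally onto the scalp.
  The generator returns exact ground truth: the set of events whose epoch
  of interest contains blink-driven EOG above the rejection threshold,
  which the preprocessing tests compare against the actually rejected set.
* **Reproducibility.** All randomness derives from one master seed through
  named substreams per (subject, task, purpose), so enabling blink
  injection does not perturb noise draws, and the same configuration is
  bit-identical across runs.

### Noise defaults and the power calculation

The emulated study reports no noise levels or single-trial variability, so
the defaults (`white_sd = 0.4`, `pink_sd = 0.5`, `pink_exponent = 1`) were
fixed once by a power calculation, and are documented here as the package's
operating point — they are **not** a claim about the real data's
signal-to-noise ratio. The binding requirement is the LOSO window-overlap
property: a recovered early window must cover ≥ 80 % of the injected
130–166 ms support, which requires point-wise significance where the Hann
bump has fallen to ~10 % of its peak (the outer 10 % of a raised cosine's
support carries very little amplitude). Working backwards at n = 14
subjects, 30 trials per condition, α = 0.05 (t₁₃ ≈ 2.16): with a target
t ≈ 3.5 at the 10 %-amplitude point of a 1.5 µV (pre-reference) component,
the subject-level point-wise SD of the K−C difference wave must be
≲ 0.15 µV, i.e. a filtered single-trial noise SD ≲ 0.6 µV. The defaults
land there after the 0.5–30 Hz band-pass. At this operating point the
detection of all four true effects is at ceiling; the stochastic element
that remains in the pattern-recovery study is the behaviour of the two
truly null contrasts, which are uncorrected α = 0.05 tests by design.

## The preprocessing chain

`preprocess_recording()` applies, in this order:

1. **Epoching** (`cut_epochs()`): −100 to +400 ms around each stimulus,
   inclusive of both endpoint samples (251 samples at 500 Hz; time 0 is the
   event sample), padded with 300 ms on each side so that filter
   transients fall outside the window of interest.
2. **EOG rejection** (`reject_eog_epochs()`): an epoch is excluded iff
   |HEOG| or |VEOG| strictly exceeds 50 µV anywhere in the epoch of
   interest. "Exceeding ±50 µV" is read literally: a peak of exactly
   50.0 µV is retained, and the criterion is absolute peak (not
   peak-to-peak) evaluated on the epoch of interest only — the padding
   exists solely for filtering.
3. **Average reference** (`rereference_average()`): the mean over scalp
   channels is subtracted at every sample; EOG channels are excluded from
   the reference set and left unreferenced (they have no further role).
4. **Band-pass** (`bandpass()`): 0.5–30 Hz, zero-phase. The realization is
   a frequency-domain multiplication with a real, non-negative response —
   unity in the pass band, raised-cosine transitions (width `lo` Hz at the
   low edge, 5 Hz at the high edge), zero at DC — applied over the full
   padded epoch. Exactly zero phase means a symmetric pulse keeps its peak
   latency to the sample. On a 1.1 s padded epoch the frequency resolution
   is ≈ 0.9 Hz, so the low edge acts as mean removal plus a soft roll-off
   of the slowest resolvable components; this is the honest meaning of a
   0.5 Hz high-pass at this epoch length.
5. **Baseline correction** (`baseline_correct()`): the −100–0 ms mean is
   removed per epoch and channel, before averaging, following the emulated
   chain literally.
6. **Averaging** (`average_erp()`): point-wise mean, padding trimmed,
   epoch count recorded.

Every stage after rejection is linear, so the ERP of the K−C difference
equals the difference of the ERPs — asserted as a test. Re-referencing and
filtering commute to numerical precision (both linear, the filter
channel-separable); their printed order is retained but immaterial, which a
documentation test also asserts.

## Mass-univariate statistics

* `difference_wave()` / `double_difference()` form K−C contrasts per
  subject and their between-task differences.
* `pointwise_paired_t()` computes, at each (channel, time) point, the
  one-sample t of the subjects' difference values against zero (equivalent
  to the paired t between conditions), two-tailed, df = n−1. Zero-variance
  points get t = 0, p = 1 when the mean is also zero, else p = 0 — a
  documented convention rather than silent `NaN`, counted on the map.
* `temporal_extent_mask()` implements the temporal-extent criterion:
  a point survives only within a run of ≥ `min_run_samples` consecutive
  p < α points. `min_run_from_duration(20, 500)` converts the 20 ms
  criterion to 10 samples.
* `topo_stat_map()` tests window-mean amplitudes per electrode (t values,
  not microvolts, are what the topographic map shows) and keeps only
  adjacency-connected sets of ≥ 2 significant electrodes. Electrode
  adjacency is not part of the emulated description, so the package uses a
  parameter-light rule: two scalp electrodes are neighbours when their
  Euclidean distance is ≤ 1.3 × the median nearest-neighbour distance of
  the montage. This reproduces intuitive 10–20 neighbourhoods and adapts
  to reduced montages; the factor is configurable.
* `find_significant_windows()` averages the difference waves over the
  electrodes of interest (PO5/PO6, matching how they enter the follow-up
  ANOVAs), applies the point-wise test and temporal criterion to that
  single series, and reports surviving intervals as closed ms ranges at
  sample resolution. A per-electrode mode is available.

## LOSO windows and repeated-measures inference

For each subject i, `loso_define_windows()` re-runs the window search on
the other n−1 subjects only, then selects, within each component's search
range (early 100–200 ms, later 200–320 ms — ranges that bracket the
expected components without overlapping each other), the surviving
interval with the largest overlap with the range, clipped to it; ties go
to the interval whose midpoint is nearest the range midpoint. Folds with
no surviving interval are flagged and excluded from that component with a
warning. Subject i's window is thus independent of subject i's data — a
property tested literally by corrupting one subject's data and checking
that subject's window is unchanged.

`extract_amplitudes()` averages each subject's K−C wave over (their LOSO
window) × (hemisphere electrode set); the default sets are {PO5} and
{PO6}, with `hemisphere_sets_extended()` providing the
{PO3, PO5, PO7}/{PO4, PO6, PO8} preset. `rm_anova()` is a classical
within-subject sums-of-squares decomposition (one or two factors), each
effect tested against its own effect-by-subject interaction, with
Greenhouse–Geisser ε estimated from the sample covariance of the effect's
orthonormal within-subject contrasts, clipped to [1/(k−1), 1], scaling
both degrees of freedom; partial η² = SS_effect/(SS_effect+SS_error).
`posthoc_paired_t()` provides uncorrected two-tailed paired tests
(df = n−1) with η² = t²/(t²+df) — matching the emulated reporting, which
gives df = 13 post-hocs with no correction mentioned; a Holm option exists
but is off by default. Degenerate inputs are resolved by convention: an
all-equal ANOVA cell structure yields F = 0, p = 1; a singular contrast
covariance yields the ε lower bound with a warning.

The behavioral arm (`simulate_behavior()`, `behavioral_summarize()`,
`behavioral_anova()`) analyses correct rate over all trials and mean RT
over correct trials only (the emulated description does not say; correct
trials is the field's standard), via the same one-way repeated-measures
ANOVA and post-hoc machinery. Generator defaults encode the qualitative
behavioral pattern (accuracy highest in KF and lowest in CC, RT fastest in
KF and slowest in CC).

## Calibration studies and problem sizes

Two replicated studies ship with the package and back the acceptance
checks; their sizes are the package's chosen desk-scale operating points:

* `null_calibration()` — 500 replicate experiments at n = 14 with both IC
  amplitudes set to zero, 12 trials per task on a 4-scalp-channel
  posterior montage (the paired t's false-positive rate is invariant to
  the noise scale, so small cells suffice). It measures the per-comparison
  false-positive rate of the six windowed pairwise tests (early/later ×
  three task pairs, fixed 130–166 and 234–290 ms windows) and the
  proportion of replicates with ≥ 1 surviving temporal run at PO5 for
  min_run ∈ {1, 5, 10, 15}, which must decrease monotonically.
* `pattern_recovery()` — 100 replicate experiments at n = 14, 60 trials
  per task on an 8-scalp-channel posterior montage, full pipeline ending
  in the LOSO-windowed post-hoc comparisons. A replicate "recovers the
  pattern" when all six comparisons match the encoded two-stage structure
  (early: KF≈CC, KF>PC, CC>PC; later: KF>CC, KF>PC, CC≈PC, with "larger"
  meaning more negative). Note an analytic ceiling: the pattern contains
  two truly null contrasts tested uncorrected at α = 0.05, so no
  signal-to-noise ratio can push the expected recovery rate above
  0.95² ≈ 0.90; observed rates hover there with binomial fluctuation.

What passing these studies shows — and what it does not: the pipeline's
statistics are calibrated and the design's effect structure is recoverable
under the generator's assumptions (stationary independent channel noise,
stereotyped component shapes, no eye movements beyond blinks, no spatial
noise correlation, no latency jitter across subjects). Real EEG violates
several of these; the studies validate the machinery, not the biology.

## File interchange

Events travel as TSV (`onset_sample`, `onset_ms`, `condition`, `task`,
`subject`; strictly increasing onsets enforced with row-numbered errors).
Raw recordings round-trip bit-exactly through an array-on-disk container
(little-endian float64 + JSON sidecar) and, with 16-bit quantization,
through a minimal EDF writer/reader (one-second records, physical
dimension µV, the true sample count stored in the reserved header field).
Configurations mirror `simulation_config()` field-for-field in YAML;
unknown keys are rejected. A thin command-line wrapper
(`system.file("cli", "icerp.R", package = "icerp")`) exposes
`simulate`, `preprocess`, `statmap`, `windows` and `report` subcommands
over these formats.

## Known limitations

* The generator's components have fixed latencies and shapes across
  subjects and trials; latency jitter would smear group averages and is
  not modelled.
* Electrode adjacency and the LOSO selection details (search ranges,
  tie-breaks) are package choices where the emulated description is
  silent; both are configurable and documented above.
* The EDF implementation covers the subset of the format the package
  writes; it is not a general-purpose EDF reader.
* Huynh–Feldt correction and cluster-mass permutation testing are out of
  scope; the extent criteria stand in for multiplicity control, as in the
  emulated analysis.
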