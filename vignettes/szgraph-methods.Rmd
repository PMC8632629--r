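---
title: "Similarity-graph classification of seizure states: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-graph classification of seizure states: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

People with drug-resistant epilepsy experience seizures with little or no
warning. Two clinically distinct tasks — *detection* (is a seizure happening
now?) and *prediction* (is one about to happen within minutes?) — can be
posed as a single windowed classification problem: assign every 1-second
epoch of multichannel EEG to one of three states, **non-seizure**,
**pre-seizure** (a fixed 10-minute pre-ictal horizon before electrographic
onset), or **seizure**. A third clinical question, *lateralization*, splits
the seizure class into **left** and **right** mesial-temporal onset, giving
a four-class problem.

`szgraph` implements this pipeline for intracranial (SEEG), scalp, or
combined recordings: EDF input with a JSON seizure-annotation sidecar,
montage assembly, windowing and class extraction, similarity-graph
construction, neural-network classification, and the evaluation designs
(patient-held-out and patient-agnostic 5-fold cross-validation,
surface-negative detection, lateralization analysis). A synthetic
simultaneous scalp+iEEG generator makes every stage testable without
patient data.

## Windows, montages, and the class-extraction rule

Recordings are cut into non-overlapping 1-s windows on the integer grid; at
512 Hz each window holds 512 samples per channel. Montage views fix the
channel roster and its order: 19 scalp contacts (10-10 system), 48 SEEG
slots (4 contacts in each of six anatomic groups per hemisphere: amygdala,
lateral anterior temporal, hippocampus, lateral mid temporal, medial
orbitofrontal, lateral frontal), or their 67-channel concatenation. A
unilateral implant fills 24 slots and zero-pads the other 24; all
similarity values involving padded slots are 0 by convention, so the
classifier input geometry is identical across patients.

Windows are labelled from the intracranial clock: *seizure* if the window
intersects an annotated ictal interval `[onset, offset)`, *pre-seizure* if
it intersects the horizon `[onset − 600 s, onset)`, otherwise
*non-seizure*. Training samples follow the fixed class ratio
non-seizure : pre-seizure : seizure = **4 : 3 : 2**, anchored on each
seizure's duration `D`: all ictal windows, `floor(1.5 D)` pre-seizure
windows drawn uniformly (seeded) from the horizon, and `floor(2 D)`
non-seizure windows drawn uniformly from eligible interictal time. A 60-s
seizure therefore contributes 120 s of non-seizure and 90 s of pre-seizure
data; the pre-seizure quota can never exceed the 600-s horizon.

Decisions the source material leaves open, made here once:

* **Post-ictal buffer.** Non-seizure windows are additionally excluded from
  the 600 s after every seizure offset, so the "normal" class is not
  contaminated by post-ictal activity.
* **Quota rounding** floors to whole windows (never over-samples scarce
  classes); **partial ictal overlap** counts as seizure.
* **Overlapping horizons.** If two seizures are closer than 600 s, the later
  horizon is truncated at the earlier offset plus the buffer.
* Windowing operates at the recording's native rate (window = 1 s = `rate`
  samples); nothing is silently resampled.

## Similarity graphs

Each window yields a dense symmetric `n × n` weighted adjacency matrix
whose vertices are contacts. Three edge models are provided:

* **Correlation**: the Pearson correlation of the two channels' samples
  within the window; entries in `[-1, 1]`.
* **Mutual information**: each channel is discretized into 16 equal-width
  bins over its per-window range, and the edge is the plug-in discrete MI
  in bits. The bin count and log base are declared choices (the estimator
  for continuous signals is otherwise under-determined); both are
  configurable.
* **Waxman**: `w_ij = β exp(−d_ij / (α · max d))` with `d_ij` the Euclidean
  distance between the two channels' sample vectors, `max d` the largest
  off-diagonal distance among recorded channels in the window, `β = 0.4`,
  `α = 0.1`. Identical channels get weight `β`; the most dissimilar pair
  gets `β e^{−10} ≈ 1.8 × 10⁻⁵`. The scope of `max d` (per window, recorded
  channels only) is a declared choice that keeps each graph a pure function
  of its window; a per-recording scope would couple windows.

Conventions shared by all metrics: the diagonal is 0 (self-similarity
differs across metrics — 1, H, or β — and carries no class information),
padded/unrecorded rows and columns are 0, and zero-variance channels get 0
correlation and MI (the Waxman distance is still well defined). Adjacency
matrices are vectorized row-major: lengths 361, 2304 and 4489 for the
scalp, iEEG and combined views.

## Classifiers

Three families consume the vectorized graphs, built on an internal
minibatch-Adam engine (dense, 1-D/2-D convolution via im2col, LSTM; all
gradients verified against finite differences in the test suite):

* **shallow** — one hidden layer of 64 units; the baseline, valid only for
  single-window samples.
* **cnn** — two 1-D convolution blocks (32 then 64 filters, kernel 5,
  ReLU, max-pool 2) over the graph vector, the `k ∈ {1, 2, 6}` consecutive
  windows of a sample entering as `k` input channels, then a dense layer of
  128 units and softmax. Learning rate 0.0005. The pool widths are
  configurable (`pool_widths`); on the long iEEG/combined vectors a wider
  first pool (4) gives the same recovery at roughly a third of the
  compute, and the acceptance runs use it. A 2-D mode that convolves
  the raw `n × n` matrix (one 5×5 block of 16 filters) is available behind
  `matrix_mode = TRUE`; the vector mode is the default, matching the
  vectorized-input design.
* **lstm** — one recurrent layer (hidden 128) over the length-`k` sequence
  of graph vectors, then softmax. Learning rate 0.001.

Exact layer shapes are not fully determined by the source architecture
diagrams; the defaults above are the smallest stacks that reliably recover
the synthetic generator's class structure, and every width is a spec
field. Training defaults: 50 epochs, batch 64, unweighted cross-entropy
(the 4:3:2 extraction already bounds imbalance), no early stopping. Inputs
are z-scaled per feature with training-set statistics stored in the model:
Waxman edge weights live mostly below 10⁻², and a fixed learning rate
needs unit-scale inputs. Given a spec seed, initialization, batching and
hence the fitted parameters and predictions are deterministic; class
probabilities argmax with ties broken toward the earlier class in the
fixed ordering (non-seizure, pre-seizure, seizure[, left/right]).

## Evaluation designs

* **Patient-held-out 5-fold CV**: folds partition patients (with 19
  patients: shuffled round-robin gives five pairwise-disjoint test groups
  of 4/4/4/4/3 — five disjoint triples with the four leftover patients
  spread one per fold); no patient contributes to both sides of a fold,
  and the runner asserts this.
* **Patient-agnostic ("bag-of-epochs") 5-fold CV**: samples are shuffled
  individually; every epoch is tested exactly once.

Confusion matrices count **window-seconds** (a `k`-window sample counts
`k` s). Both pooled and per-fold-mean accuracies are reported, since
averaging conventions differ between studies. The surface-negative
analysis scores a scalp-view model on ictal windows only: for
surface-negative seizures all ictal windows, for delayed-onset seizures
only the portion `[iEEG onset, scalp onset)` — the surface-negative
portion — and for simultaneous-onset seizures all ictal windows. The
lateralization analysis reports per-side, per-category detection and the
left↔right confusion count in seconds. Chance level for negative controls
is the maximum class prior of the test set.

## The synthetic cohort generator

The generator emulates the study population this pipeline is aimed at —
simultaneous 19-contact scalp + 24/48-contact SEEG monitoring of mesial
temporal lobe epilepsy, including unilateral implants and scalp-invisible
seizures — without claiming biophysical realism. Per channel `c`:

```
y_c(t) = σ_c [ √(1 − w1_c² − w2_c(t)²) ε_c(t) + w1_c S_bg(t) + w2_c(t) S_foc(t) ]
         + rhythm_c(t)
```

* `ε_c` is unit-variance channel noise with a 1/f spectrum over the EEG
  band (an autoregressive pink approximation, flat below ≈3 Hz).
  Sub-delta drift is deliberately left out: with appreciable power below
  1 Hz, a 1-s window of a 1/f process carries a random offset and only a
  handful of effective samples, and windowed similarity estimates become
  noise-dominated.
* The shared sources are broadband (synchronization is wide-band) and
  power-normalized per 1-s block, so the coupling level a window
  expresses is set by the state, not by the source's random envelope.
* `ρ` is the **shared-variance fraction** (mixing weight `√ρ`): two
  channels with full topography weight correlate at `ρ_state`, so a
  preset's ladder is a correlation ladder across states. `S_bg` is a
  background source every channel couples to at level `ρ₀` through a
  fixed heterogeneous gain profile (interictal synchronization
  topography).
* `S_foc` is a **focal** source, lateralized to the onset hemisphere and
  strongest over its mesial-temporal network, engaged only in the
  pre-ictal state (level `ρ₁`) and ictal state (`ρ₂`). The pre-seizure
  state is thus a change in coupling topography with no eye-visible
  waveform — the feature the windowed graphs must pick up. Presets meant
  to be learnable satisfy `ρ₀ < ρ₁ < ρ₂`.
* Focal-network channels additionally carry a state-dependent
  **band-power modulation**: channel amplitude scales by
  `1 + 0.35 · h_c · √ρ_state` when the focal source is engaged
  (pre-ictal power changes are among the most replicated pre-ictal
  findings). This is the component the amplitude-sensitive Waxman metric
  keys on; correlation and MI are amplitude-invariant and key on the
  coupling itself.
* `rhythm` is a 5-Hz sinusoid with a 5-s amplitude ramp injected into the
  8 amygdala+hippocampus contacts of the onset hemisphere (150 µV over a
  50 µV iEEG background).
* **Scalp expression** is scaled by a leakage coefficient `λ ∈ [0, 1]`
  applied to both the focal coupling and a laterality-weighted rhythm leak
  (ipsilateral temporal chain 1.0, other ipsilateral 0.5, midline 0.3,
  contralateral 0.1; 40 µV before weighting over a 20 µV background).
  `λ = 0` reproduces the surface-negative pattern — scalp windows during a
  seizure are statistically indistinguishable from baseline. For
  delayed-onset seizures all scalp ictal content begins at the annotated
  scalp onset; the portion between intracranial and scalp onset carries
  only pre-ictal-level structure.

Cohort conditions follow the target population: 19 patients, 5 with
unilateral implants, roughly a quarter with left-sided onset, and a
surface-negative / delayed / simultaneous category mix of 0.34 / 0.59 /
0.07. One seizure is generated per recording with duration 15–25 s and
onset placed 610–640 s into a 1380-s recording — the smallest layout that
leaves a full 10-min horizon plus enough interictal time outside the
horizon and post-ictal buffer to fill the 4:3:2 quotas. These sizes, and
the training schedules used in the test suite (5 epochs at batch 64 for
the single-window iEEG cross-validations, 12 for the scalp models, on a
strongly separated preset where Adam converges within a handful of
passes), are the package's desk-scale working points; they are
deliberately small enough to re-run routinely while exercising every code
path at the full 512-Hz rate.

Documented presets: `strong_separation` (ρ = 0.1/0.4/0.8, λ = 1, the
full 19-patient cohort), `weak`, `null` (background coupling only, no
focal source, no rhythm — classifiers should sit at chance; 8 patients,
a negative control does not need the full cohort), and `surfneg_sweep`
(all surface-negative, 3 patients per cohort, λ grid 0, 0.05, 0.1,
0.2). The free parameters of the strong preset — topography weights,
amplitude modulation, gain spread — are calibrated once so that the
preset actually has its defining property (a classifier can recover the
three states almost perfectly); the `weak` preset exists for subtler
conditions.

What passing tests on this generator do and do not show: they demonstrate
that the pipeline recovers class structure of the kind hypothesized
(state-dependent functional connectivity plus a focal ictal rhythm) under
controlled conditions, that the evaluation designs are leak-free, and that
the qualitative phenomena — detectability of scalp-invisible seizures at
small λ, clean left/right separation, ictal windows never confused with
baseline — emerge when the generating process has them. They say nothing
about accuracy on real EEG: the generator has no artifacts, no electrode
drift, no inter-patient anatomy differences, no medication effects, and
its surface-negative mechanism (λ-scaled leakage) is an abstraction — the
real scalp signature of surface-negative seizures is unknown.

## Numerical choices and degenerate inputs

* EDF signals are 16-bit with per-channel symmetric integer physical
  ranges; the round-trip error is at most half a quantization step.
* All similarity computation is double precision. Equal-width MI binning
  puts boundary samples in the upper bin; a constant channel occupies a
  single bin (MI 0). If every recorded channel pair in a window is
  identical, the Waxman limit convention assigns β to all recorded
  off-diagonal entries.
* Empty sample sets (e.g. a delayed seizure whose scalp onset equals the
  intracranial onset) yield empty analysis rows, not errors; a test class
  absent from a fold is reported as absent, never zero-divided.
* Seeds: every stochastic step (extraction draws, fold assignment,
  initialization, batching, cohort generation) is seeded, and per-patient
  seeds are small offsets of the master seed.

## Known limitations

* The internal network engine is plain R on BLAS; it is sized for
  desk-scale experiments, not for hours of clinical EEG.
* `simulate_cohort()` holds full recordings in memory; use
  `simulate_dataset()` (one patient at a time) or `generate_cohort()`
  (EDF files on disk) for full-rate cohorts.
* MI graphs cost O(n² · samples) per window and dominate graph-building
  time on the 67-channel view.
* The 2-D convolution mode is a single block; it is provided for
  comparison, not tuned.
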