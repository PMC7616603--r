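---
title: "Time-resolved RSA of scene-object congruency: models, inference and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved RSA of scene-object congruency: models, inference and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenersa)
```

## The scientific question and the analysis it requires

When an object appears inside a scene, observers recognise it more easily if
it fits the scene's meaning — a cushion in a living room rather than a
chopping board. EEG studies index this *congruency effect* as a stronger
N300/N400 negativity for incongruent objects. `scenersa` implements a
model-based, time-resolved representational similarity analysis (RSA) that
asks a sharper question than a univariate contrast: *when* do multichannel
EEG patterns carry information about scene-object congruency, and *when* do
they carry semantic information about the object itself, separately for
congruent and incongruent contexts?

The design the package targets is a counterbalanced one: each of 152 scenes
is paired with a congruent and an incongruent object, every participant sees
each scene exactly once (76 trials per condition), and the scene-condition
assignment is complemented across two participant groups. Epochs run from
-200 to 900 ms around object onset at 5 ms resolution (221 timepoints, 64
channels).

## The model and its estimator

### Representational dissimilarity matrices

At each timepoint $t$, the neural pattern of trial $i$ is its vector of 64
channel amplitudes. The neural RDM entry for trials $i, j$ is the
correlation distance

$$d_{ij}(t) = 1 - r\big(x_i(t),\, x_j(t)\big) \in [0, 2],$$

with $r$ the Pearson correlation across channels. Two model RDMs provide the
hypotheses:

* **Congruency model.** Each kept trial is coded 1 (congruent) or 0
  (incongruent); the model entry is the Euclidean distance $|c_i - c_j|$, so
  same-condition pairs are 0 and cross-condition pairs 1. With the full
  design this is a $152 \times 152$ matrix with $2 \cdot 76 \cdot 76 =
  11{,}552$ off-diagonal ones. The model is participant-specific because
  counterbalancing reverses each scene's condition between groups.
* **Semantic model.** Object labels are matched to a concept-by-feature
  property-norm matrix (a zebra "has stripes", "eats grass", ...);
  matching is exact case-insensitive equality plus an explicit alias table,
  never fuzzy, so every exclusion is auditable. For each condition
  separately, the model entry is the cosine distance between the two
  trials' feature vectors. Trials without a norm match are excluded from the
  semantic analysis only; the congruency analysis keeps them.

### Model fit and group inference

Per subject and timepoint, model fit is the Spearman correlation between the
strictly-lower-triangle vectorisations of the model and neural RDMs
(average ranks for ties). Group inference on the subject $\times$ time fit
matrix uses the sign-flip cluster-mass permutation test:

1. one-sample $t$ tests against zero at each timepoint
   ($t = \bar\rho / (s/\sqrt{n})$, $n-1$ denominator);
2. contiguous runs with $|t|$ above the two-tailed critical value at the
   cluster-forming alpha (default 0.01), split at sign changes, form
   clusters whose *mass* is the summed $t$;
3. on each of `n_perm` permutations an independent random $\pm 1$ multiplies
   each subject's whole time series; the maximum absolute cluster mass of the
   permuted data (0 if none) enters the reference distribution;
4. each observed cluster's $p$ is the proportion of the permutation maxima,
   *plus the observed cluster itself*, at or above its absolute mass:
   $p = (\#\{m^{*} \ge |m|\} + 1)/(n_{perm} + 1)$, so $p \ge 1/(n_{perm}+1)$.

Condition differences use the identical machinery on per-subject difference
time series (equivalent to paired $t$ tests), and the congruency fit curve
is related to the curve of semantic-fit differences (incongruent minus
congruent) by Pearson correlation with the usual $t_{n-2}$ p-value.

### Choices the method description leaves open

* **Tail of the cluster-forming test.** The threshold is two-tailed at
  alpha, clusters carry their sign, and the permutation maximum is taken
  over absolute mass, which controls family-wise error across both signs;
  `tail = "pos"` switches to a one-tailed positive test.
* **Order of preprocessing.** Noisy-trial rejection runs before baseline
  correction by default; both steps are configurable and the order matters
  little because rejection uses peak-to-peak amplitudes and variance ratios
  that are invariant to the baseline offset.
* **Correlation window.** The congruency/semantic-difference correlation
  defaults to the full epoch; any closed ms window can be requested.
* **Noisy-trial screening.** Manual artifact inspection is not an
  algorithm, so the package uses a deterministic two-rule stand-in: flag a
  trial when its maximum channel peak-to-peak amplitude exceeds 200 µV or
  when the z-score of its log-variance across trials exceeds 4. Flags only
  touch the trial table's `keep` column; amplitudes are never altered.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.01 | — | cluster-forming threshold (two-tailed) |
| `n_perm` | 10000 | — | sign-flip permutations |
| `seed` | required | — | permutation RNG; recorded in every report |
| `baseline_window` | (-200, 0) | ms | closed baseline interval on the grid |
| `ptp_threshold_uv` | 200 | µV | peak-to-peak rejection rule |
| `zvar_threshold` | 4 | — | log-variance z-score rejection rule |
| `binarise` (semantic) | FALSE | — | threshold norm values at > 0 |

Windows are closed intervals evaluated on the millisecond grid; timepoint
indices are 1-based in R fashion, and cluster bounds are reported in ms at
grid positions.

## What the synthetic generator emulates

`simulate_cohort()` produces data whose *representational geometry* is known
by construction, so every pipeline stage can be validated by parameter
recovery without any recordings:

* **Design**: each scene once per participant, 50/50 congruent/incongruent,
  complementary assignment in the two counterbalancing groups; scene $s$
  owns two distinct object concepts (its congruent and incongruent object).
* **Norms**: sparse binary concept-by-feature matrices, i.i.d.
  Bernoulli(`feature_density`, default 0.1 over 300 features, roughly 30
  features per concept), resampled so no concept is featureless; optional
  planted categories raise within-category feature overlap.
* **Epochs**: Gaussian sensor noise (`noise_sd`, default 1 µV per sample;
  optional AR(1) temporal correlation) plus two injected signals confined to
  latency windows with one-grid-step ramps. The congruency signal is a fixed
  per-subject channel pattern added with $+a$ on congruent and $-a$ on
  incongruent trials (bipolar, so at high SNR the neural geometry matches
  the binary model exactly); the semantic signal projects each trial's
  unit-normalised feature vector to channels through a fixed per-subject
  random projection. Defaults place the congruency window at 290-450 ms and
  the semantic windows at 150-235 ms (congruent) versus 150-360 ms
  (incongruent) with equal amplitude 1 — the qualitative pattern of a
  congruency effect in the N300/N400 range and semantic processing that is
  extended in time for incongruent objects.

Default amplitudes equal the noise SD ("high SNR"): with 64-channel
patterns this yields unambiguous recovery, which is what a validation
instrument should do. Real EEG effects are far weaker and the generator's
amplitude is the dial for emulating that; the reproduction script described
in the README uses amplitude 0.2 so that group statistics stay well below
the rank-correlation ceiling.

What the generator does **not** emulate: 1/f spectra and channel covariance
of real EEG, ERP waveform morphology, eye/muscle artifacts, or natural-image
content. Passing recovery tests therefore demonstrates correctness of the
estimator and inference chain under known geometry, not fidelity to the
biophysics of any particular recording.

## Numerical choices and degenerate inputs

* Amplitudes are stored as float64 in the HDF5 container, making read/write
  round-trips bit-exact.
* Time spacing must be uniform to within $10^{-9}$ ms and consistent with
  the stored sampling frequency; non-finite amplitudes are rejected at load.
* A constant channel pattern (zero variance) is an error naming the trial
  and timepoint rather than a silent `NaN`: simulated and real EEG are never
  exactly flat, so a flat pattern signals an upstream bug.
* Correlation and cosine distances are clamped to their theoretical ranges
  to absorb floating-point leakage at the boundaries ($\pm 10^{-15}$).
* A timepoint with zero between-subject variance gets $t = \pm\infty$,
  which any finite cluster-forming threshold treats as suprathreshold; this
  occurs only at rank-correlation saturation ($\rho \equiv 1$).
* Spearman fits require at least 3 item pairs and non-constant triangles;
  cluster p-values are exactly $(k+1)/(n_{perm}+1)$, never 0.

## Validation strategy and problem sizes

The test suite validates the pipeline at three levels, with simulation sizes
chosen to keep the full suite in the minutes range:

1. **Oracle equivalence** — distances, Spearman with ties, cluster finding
   and masses match naive brute-force reimplementations to $10^{-10}$ on
   100 random fixtures.
2. **Exactness of the permutation test** — for 10 subjects, Monte-Carlo
   p-values (10,000 flips) match the exhaustive $2^{10}$ enumeration within
   3 standard errors.
3. **Calibration and recovery** — on 500 null cohorts (zero injected
   amplitude; 20 subjects of 16 trials $\times$ 64 channels $\times$ 60
   timepoints) the family-wise rate of any cluster $p \le 0.05$ stays in
   [0.02, 0.08]; on 50 cohorts per setting (20 subjects, 24 trials, 64
   channels, 10 ms grid) the injected congruency window 290-450 ms is
   recovered by a significant cluster covering at least half the window, and
   the paired semantic test recovers an incongruent > congruent cluster
   overlapping 235-360 ms.

Channel count is deliberately kept at the study's 64 in these simulations:
the subject-level null of the rank statistic is noticeably right-skewed when
patterns have few dimensions (skewness near 0.9 at 8 channels versus 0.34 at
64), and the sign-flip test assumes a symmetric subject-level null. This is
a real limitation worth knowing about — the test should not be trusted for
very low-channel montages — and the validation therefore runs in the regime
the method is actually used in.

## Known limitations

* Sign-flip inference assumes subject-level symmetry under the null; see
  above for the low-dimensionality caveat.
* Cluster bounds are not precise effect on/offsets; a cluster's p-value
  concerns its whole mass, and interpretation of its temporal extent
  inherits the usual caveats of cluster-based inference.
* Concept matching is intentionally strict; labels that differ from norm
  concepts by pluralisation or compounding need alias entries.
* The pipeline starts from epoched, filtered, ICA-cleaned data; no raw-EEG
  preprocessing or vendor-format reading is provided.
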