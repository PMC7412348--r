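---
title: "Recurrence-plot imaging of gait force signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence-plot imaging of gait force signals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Neurodegenerative diseases — amyotrophic lateral sclerosis (ALS),
Parkinson's disease (PD) and Huntington's disease (HD) — disturb the timing
and force pattern of walking long before other signs are reliable. A cheap,
non-invasive probe of that disturbance is the vertical ground reaction
force (vGRF): the downward force under each foot, recorded by in-shoe
force-sensitive resistors while the subject walks. gaitrp implements an
image-based screening pipeline over such recordings:

1. **Windowing.** Each 5-minute, two-channel (left foot LF / right foot RF;
   compound foot CF = LF + RF) trace loses its first 20 s (gait
   initiation), then is cut into 10-s windows whose starts advance by one
   third of the window length, i.e. consecutive windows overlap by 6.66 s.
   The number of windows per subject is
   `floor((l - TW)/d + 1)` for post-trim length `l`, window length `TW`
   and start distance `d`; at the defaults `(280 - 10)/(10/3) + 1 = 82`.
2. **Recurrence-plot encoding.** Every window `x` becomes the matrix
   `P[i, j] = |x[i] - x[j]| / max(x)` — an *unthresholded* recurrence plot
   of the scalar series, with no embedding, delay or recurrence threshold.
   For a nonnegative signal all entries lie in `[0, 1]`; rendered as a
   gray-level image (0 = black = similar states), stance phases appear as
   dark squares whose size tracks the stance duration and whose internal
   "cross" pattern reflects the double force peak of a stance.
3. **PCA feature enhancement (optional stage).** All flattened images form
   a matrix `X` (one image per row); the eigenvectors `W` of the
   *uncentered* scatter `C = t(X) X` define scores `F = X W`, retaining
   the full nonzero spectrum. Scores are folded back into images and
   min–max rescaled per image.
4. **Feature extraction + linear SVM.** Images are fed to a feature
   extractor; the resulting vectors train a linear support vector machine
   (one-vs-one for more than two classes).
5. **Evaluation.** Leave-one-out cross-validation, per force channel and
   per task (the seven two-class tasks and the four-class task), reporting
   accuracy, sensitivity, specificity, AUC and Youden's index
   `J = sensitivity + specificity - 1`; `J` selects the best channel.

## The synthetic cohort: a stated world

Real cohorts of this kind are small external downloads. The package
therefore ships a generator whose defaults encode the qualitative
phenomenology the pipeline is meant to detect, and the entire test suite
runs against it:

| group | stride CV | stance fraction | valley depth | reading |
|-------|-----------|-----------------|--------------|---------|
| HC    | 0.02      | 0.62            | 0.25         | regular stance and swing of constant length |
| ALS   | 0.05      | 0.72            | 0.45         | prolonged stance, pronounced double peak |
| PD    | 0.09      | 0.65            | 0.15         | irregular stride/swing timing |
| HD    | 0.14      | 0.50            | 0.40         | most irregular; stance ≈ swing duration |

Stride intervals are i.i.d. lognormal (positive, right-skewed; no
distributional form is prescribed by the source material, so the natural
positive-support law was chosen once). The stance burst is the sum of two
Gaussian bumps at 25 % and 75 % of stance whose width is set so the
mid-stance valley sits at `1 - depth` of the peaks. The right foot starts
near mid-left-stride, jittered by the same CV. Additive Gaussian sensor
noise (SD 0.01–0.015 of peak force) is clipped at zero. Stride means
(1.1–1.4 s) correspond to self-selected walking speeds around 1.0–1.4 m/s.
Default trace geometry is 300 s at 300 Hz; tests and the acceptance run use
80 s at 40 Hz and 64-px images purely for runtime, leaving the profiles
untouched.

What the generator does **not** emulate: body-mass and kinematic coupling,
footswitch saturation, severity staging, medication state, or any
within-subject drift. A green end-to-end test therefore establishes that
the pipeline recovers class structure *of this stated kind* — it is not
evidence about real patient cohorts.

## Numerical choices

* **Window-count epsilon.** `(l - TW)/d` is computed with a `1e-9` slack
  before `floor` so that boundary-exact layouts (e.g. `d` rendered as the
  decimal 3.33 instead of 10/3) count their final window. Start indices are
  quantized to whole samples by rounding `k * d * fs`.
* **Degenerate windows.** `compute_rp()` refuses all-zero windows (the
  normalizer `max(x)` would vanish) and negative forces; a signed signal
  must be rescaled upstream, deliberately outside the canonical method.
* **Resampling convention.** Images are resized with pixel-center-aligned
  bilinear interpolation: output center `i` maps to source coordinate
  `(i - 0.5) * n/N + 0.5`. Matching sizes give the exact identity, and 2×
  downsampling equals area-average block means, which is what the test
  oracles check. Bilinear was chosen over nearest-neighbour to avoid
  aliasing the fine texture; no interpolation scheme is canonical here.
* **PCA via the dual.** At 227-px resolution `C` would be a 51,529²
  matrix; the model is fitted with the thin SVD of `X` (equivalently the
  eigendecomposition of the small `X tX` problem), which provably agrees
  with the direct eigendecomposition of `C` on the nonzero spectrum — the
  equivalence is asserted against an `eigen()` oracle on small instances.
  No centering is applied by default (`C` is literally `t(X) X`);
  `center = TRUE` exists for conventional covariance PCA.
* **Linear SVM.** No SVM library is assumed: the package trains the primal
  squared-hinge objective `0.5 ||w||² + C Σ max(0, 1 - y w·x)²` with
  L-BFGS-B (deterministic, no subsampling), bias absorbed as a constant
  feature, one-vs-one voting with ties broken toward the earlier class.
  Kernel and coupling scheme follow the common toolbox default for this
  workflow (linear, pairwise); both are recorded in the model object. No
  feature scaling by default; z-scoring from training-fold statistics is
  an option.
* **Rounding for display.** Percentages print half-up to 2 decimals, AUC
  and J to 4, matching the conventions of published result tables. Exact
  .5 ties at the 4th decimal are asserted to half-a-unit tolerance rather
  than forcing a tie rule.

## Design decisions made where the design was open

* **AUC definition.** Every printed AUC in the reference two-class table
  equals `(sensitivity + specificity)/2` — the balanced accuracy of a
  hard-label classifier — except a single cell that instead repeats that
  row's accuracy and is treated as a typo (the regression test documents
  it). Because the definition is nowhere stated, reports carry both
  `auc_balanced` and `auc_rank` (trapezoidal/Mann–Whitney on decision
  scores) rather than guessing which one a reader wants.
* **LOOCV unit.** Published practice treats every *window* as a data
  point, although neighbouring windows of one subject share two thirds of
  their samples — window-level folds leak subject identity. Both units are
  implemented; `unit = "window"` mirrors the published protocol and its
  reports always embed a leakage warning, `unit = "subject"` is the honest
  generalization estimate and is what the end-to-end acceptance run uses.
* **PCA wiring.** A full-PC orthogonal transform preserves all pairwise
  geometry, so it cannot *add* class separability; folding rotated scores
  back into "images" additionally destroys the spatial locality that a
  convolutional feature extractor exploits. The pipeline test logs the
  measured A/B accuracy gap (raw vs PCA-enhanced) without asserting an
  ordering, the stage order with PCA on remains the `run_pipeline()`
  default for fidelity to the published flowchart, and the end-to-end
  acceptance criterion runs the raw wiring its stage list names.
* **Feature backends.** The published pipeline uses the fc7 activations of
  a pretrained AlexNet. Pretrained weights are a download and a deep
  learning runtime is a heavy dependency, so `alexnet-fc7` is declared
  (4096-d contract, ImageNet normalization recorded) but raises an
  actionable error; two deterministic offline backends — a seeded random
  convolutional network and a seeded random projection — carry all tests.
  Evaluation code is agnostic to backend identity and feature width.
* **Corrupt-record handling.** Reference cohorts drop some subjects
  without stating criteria; gaitrp only ever removes subjects through an
  explicit, validated exclusion list (`apply_exclusions()`), never an
  automatic detector, so any reduced cohort stays auditable.
* **Image export.** Images are exported as plain-text PGM (P2) at 8 bits,
  `value = round(255 * pixel)`; the classification path always uses the
  lossless arrays, never the quantized export.

## Known limitations

* The simulator is a phenomenological stand-in; none of its parameters were
  fitted to patient data.
* The published headline accuracies on the real cohort are not an
  acceptance surface here: reproducing them requires the external database
  and pretrained weights. The end-to-end criterion instead demands ≥ 90 %
  subject-wise LOOCV accuracy on the synthetic four-class cohort plus
  label-permutation controls at chance, which the test suite computes.
* Window-level LOOCV numbers, on any data, overstate generalization; see
  the leakage warning above.
* Only the linear kernel is implemented; the published workflow names the
  SVM but not its kernel, and nonlinear kernels would need a dedicated
  solver.

## Reproducibility

Every stochastic element — simulator, cohort seeds, backend weights — is
seed-derived, and `run_pipeline()` writes content-hashed stage artifacts:
re-running an identical configuration reproduces byte-identical
deterministic outputs, which the acceptance suite verifies with file
checksums.
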