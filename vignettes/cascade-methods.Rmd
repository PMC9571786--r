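---
title: "Methods: the two-stage Raman grading cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-stage Raman grading cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ramangrade` grades chondrogenic bone tumors from Raman spectra in two
binary stages: a 1D convolutional network separates benign-plus-low-grade
(EG1) from high-grade (G2G3) tissue on the spectra themselves, and a
residual 2D network separates enchondroma (E) from grade-1 chondrosarcoma
(G1) on synchrosqueezed wavelet scalograms of the spectra routed onward.
This vignette records the model choices, the tunable parameters and their
defaults, what the synthetic cohort simulator does and does not emulate,
and the numerical conventions a user re-deriving results should know.

## The cascade and its accuracy algebra

High-grade calls terminate at stage 1; E/G1 calls are decided at stage 2.
A spectrum of true class E is counted correct only if stage 1 routes it
onward *and* stage 2 labels it E, so per-class accuracies compose
multiplicatively:

$$\mathrm{Acc}^f_{G2G3} = \mathrm{Acc}^1_{G2G3}, \qquad
  \mathrm{Acc}^f_{E} = \mathrm{Acc}^2_{E}\,\mathrm{Acc}^1_{EG1}, \qquad
  \mathrm{Acc}^f_{G1} = \mathrm{Acc}^2_{G1}\,\mathrm{Acc}^1_{EG1},$$

and the overall accuracy is the class-count-weighted mean. These
identities are asserted inside every `cascade_report`, not merely
documented. `aggregate_final_accuracy()` has two rounding modes because
published accuracy tables print percentages: `fraction_counts` (default)
converts a printed percentage back to the nearest integer count of
correct samples over the class size before multiplying — 83.3% of 24 is
20/24, and the combination of 100, 100, 100 and 83.3 over counts
(31, 24, 99) gives 97.4%, matching printed-table arithmetic —
while `printed_products` multiplies the percentages as given. Empirical
reports built from a run (`report_from_cascade()`) use exact fractions
and therefore `printed_products`.

Stage 2 is evaluated on the true-E/G1 samples that stage 1 actually
routed onward; samples lost at stage 1 are charged to their class through
the product. A G2G3 spectrum misrouted to stage 2 cannot be recovered —
the cascade is asymmetric by design.

## Stage 1: the 1D network

Architecture: one 1D convolution (1 input channel, 4 output channels,
kernel length 6, no padding, unit stride, ReLU), max pooling (kernel 3,
stride 3), then dense layers 1024, 256, 128, each followed by batch
normalization (applied after the affine map, before the activation) and
ReLU, and one output logit. On the default 1601-point grid the conv+pool
stage yields 532 positions × 4 channels. Training: Adam
(β = 0.9/0.999, ε = 1e-8), learning rate 1e-4, weight decay 0.01, batch
32, binary cross entropy, a weighted random sampler drawing each class
with equal probability, and two on-the-fly augmentations — additive
Gaussian noise with σ proportional to each spectrum's peak (default
0.05×) and integer spectral shifts uniform on [−s, s] grid steps with
s = 5 (≈ ±10 cm⁻¹ on the default grid), emulating calibration error.
Shift vacancies are filled with the edge value: on z-scored spectra,
zero-filling would fabricate band edges. The epoch default is 150; no
per-epoch checkpoint selection is performed — training length is the
convergence control (the engine keeps a single weight state).

A probability of exactly 0.5 predicts the positive (EG1) class, so
confusion matrices are reproducible.

## The time–frequency transform

The continuous wavelet transform uses the analytic generalized Morse
family, $\hat\Psi(\omega)\propto\omega^\beta e^{-\omega^\gamma}$ on
$\omega>0$, peak-normalized, with defaults γ = 3, β = 60 (the common
"gmw" shape), 64 log-spaced voices per octave, and an automatic scale
range from the Nyquist-peaked scale to wavelets spanning roughly a
quarter of the signal. Signals are reflection-padded to the next power of
two ≥ 2n and transformed as per-scale frequency-domain products; a direct
quadrature of the transform integral is the test oracle and agrees to
1e-6 relative error.

Synchrosqueezing estimates each cell's instantaneous frequency from the
phase derivative $\mathrm{Re}(\partial_b W / (2\pi i\,W))$ and reassigns
the cell to the nearest of the (log-spaced, one per voice) frequency
bins. The package's reassignment convention is energy-conserving: the
output cell carries $\sqrt{\sum |W|^2}$ of its contributors with the
phase of their complex sum, so total squared magnitude is exactly
preserved when no threshold mask is applied. The classical complex-sum
accumulator is carried alongside on the object and used by
`invert_cwt()`, which reconstructs via the one-sided Morlet-style
formula with a numerically integrated admissibility constant. Round-trip
relative L2 error is ≤ 5% for signals band-limited within the scale
range — note that an isolated smooth bump is *not* band-limited in this
sense (it carries energy below the lowest analyzed frequency, which no
scale sum can recover); the invertibility tests therefore use
Gabor-atom signals.

Rendering to the 2D classifier's input min-max normalizes the magnitude
per image, applies the fixed compression $\log1p(50x)/\log1p(50)$
(scalogram dynamic range is dominated by low-frequency baseline energy),
maps through the classic 64-anchor piecewise-linear JET colormap and
bilinearly resizes to 224×224×3. Normalizing before compressing makes
the render invariant to positive rescaling of the magnitudes; a constant
scalogram maps to the value-0 color (dark blue).

## Stage 2: the residual image classifier

`build_transfer_model()` builds the 18-layer residual topology — 7×7
stride-2 stem, 3×3 stride-2 max pool, four stages of two basic blocks
with channel doubling and stride-2 entries, global average pooling,
dropout p = 0.2, linear head sized to the task — so a 224×224 input
yields a 7×7 final feature map. Squeeze-and-excitation gates
(`"senet"`) and a compact compound-scaled variant (`"efficientnet"`,
one SE block per stage at 1.25× width) are pluggable alternatives. All
layers are trainable. There is no pretrained-weight source in this
implementation: `base_width` scales the channel counts (canonical 64)
so the same topology trains from He initialization on a CPU; the
published fine-tuning learning rate 5e-7 remains the config default, but
training from random initialization uses a larger rate (the package's
tests use 1e-3). Two-class training minimizes the cross entropy of the
softmax pair, which equals the binary cross entropy of the positive-class
probability.

Image augmentations follow the 1D philosophy: random crop with offsets
up to 2% of each axis (4 px at 224) resized back, a sharpness factor
drawn uniformly from [0.8, 1.2] (blend against a 3×3 binomial blur),
per-image z-scoring, then additive Gaussian noise σ = 0.1 on the
normalized values (noise after normalization, so its scale is
well-defined). Prediction z-scores each image, softmaxes the logits, and
breaks exact ties toward the lowest class index.

## The synthetic cohort simulator

The clinical spectra behind the motivating study are not
redistributable, so `generate_cohort()` fabricates cohorts with the same
*structure*: 400 spectra from 10 patients (3/3/4 per class), 69/76/101
training and 31/24/99 test spectra for E/G1/G2G3, and
one-patient-per-class-out splits (a patient's spectra never straddle
splits). Each spectrum is a sum of Lorentzian bands (default FWHM
10–22 cm⁻¹) whose grade multipliers encode the reported biochemistry:
collagen 728/830/1206 and chondroitin sulfate 1380 decrease strictly
E→G1→G2G3; hydroxyapatite 960 peaks at G1 (calcification); a
nucleic-acid surrogate increases with grade and is placed at the
canonical DNA/RNA bands 785 and 1578 cm⁻¹ (a simulator convention — the
trend is reported, the band positions are not); amide I 1660 and the CH
stretch 2935 are grade-neutral realism. On top sit a grade-dependent
quadratic fluorescence baseline, a decaying-exponential Rayleigh-scatter
tail anchored at the low-wavenumber edge (amplitude 2, decay 100 cm⁻¹),
and white noise (σ = 0.02).

Variability has three levels, all log-normal/Gaussian:

* **patient** — amplitude (σ = 0.15 log) and calibration offset
  (σ = 1.5 cm⁻¹), drawn once per patient, which is what makes
  patient-wise splits harder than random splits;
* **measurement spot** — amplitude (σ = 0.10 log) and jitter
  (σ = 0.5 cm⁻¹) per spectrum, reflecting that Raman maps sample many
  regions per section with substantial spot-to-spot intensity variation;
* **instrument** — the Rayleigh-tail amplitude varies per spectrum
  (σ = 0.2 log) independently of the tissue signal.

The spot-level terms matter: with purely patient-level effects a
network can encode patient identity (a constant amplitude factor against
a fixed instrument tail is a patient fingerprint), which no real Raman
map exhibits, and held-out-patient accuracy collapses for the wrong
reason.

`band_contrast` ∈ [0, 1] scales the grade dependence of every band
multiplier *and* of the fluorescence amplitudes toward their
across-grade means: at 1 the cohort is the study condition, at 0 all
classes are exchangeable and any classifier floors at the class prior.
The simulator does **not** emulate cosmic-ray spikes, detector
saturation, paraffin residue, water bands, or intra-tumor grade
heterogeneity; passing tests demonstrate that the pipeline recovers
planted band structure under realistic nuisance variation, not clinical
performance.

## Baselines

PCA (fit on training data only, 30 components), RBF-kernel SVM with
C = 1 and γ = 1/(n_features · Var(X)) (one-vs-one for three classes),
LDA with the SVD solver at rank tolerance 1e-4 and no shrinkage, a
multilayer perceptron (hidden layers 256 and 64, ReLU, same Adam family;
architecture is a package choice), and the stage-1 CNN with a multiclass
head. Each runs in straight three-class mode or as a drop-in cascade
stage (`fit_baseline_stage()`). If the training features are constant,
every method predicts the majority class rather than erroring.

## Explainability

`compute_cam()` forms the class activation map
$\sum_k w_{k,c} F_k$ from the final feature maps and the head weights,
min-max normalized; min-max makes the map invariant to positive
rescaling of the head weights (an additive shift of the weights is
*not* absorbed — it adds a multiple of the channel-sum map).
`overlay_cam()` upsamples bilinearly, smooths with a Gaussian of
σ = 2 px, JET-colors and alpha-blends. Because the transform's
translation axis follows the wavenumber axis, CAM columns map
proportionally onto wavenumber intervals
(`cam_to_wavenumber_interval()`, threshold 0.6 of the normalized map);
this correspondence is a stated convention, exact only up to the
wavelet's time support. The headline property test plants a single
discriminative band (hydroxyapatite 960 cm⁻¹) and requires the salient
interval to contain it.

## Numerical and protocol choices

* Z-scoring uses the population standard deviation; constant spectra map
  to zeros and are flagged `degenerate` instead of erroring, so batch
  pipelines do not abort. Normalization is per spectrum (per-dataset
  statistics would leak the test set through the training mean).
* The engine behind both networks is plain R: im2col convolutions on
  BLAS matrix products, batch normalization with running statistics
  (momentum 0.1, ε = 1e-5), Adam with coupled weight decay on weights
  and batch-norm scales. Gradients are verified against finite
  differences in the test suite.
* All randomness flows through explicit seeds; two runs of
  `run_full_pipeline()` from one seed produce identical reports.
* Desk-scale protocol used by the heavy end-to-end tests: the full
  400-spectrum default cohort, 16 voices per octave, 112×112 images
  (the topology is size-agnostic through global pooling; 112 gives a
  4×4 final feature map), `base_width = 8`, 30 stage-1 epochs and 4
  stage-2 epochs at learning rate 1e-3 — sizes chosen from the
  convergence traces of the training losses. At this protocol stage-1
  test accuracy exceeds 90% and full-cascade three-class accuracy
  exceeds 85% at default contrast, degrading monotonically as
  `band_contrast` → 0.

## Known limitations

The absence of pretrained weights means stage 2 cannot reproduce
transfer learning's data efficiency; the published fine-tuning regime
(lr 5e-7 on ImageNet features) is representable in configuration but not
executable offline. The pure-R engine is CPU-bound — canonical width 64
at 224×224 trains at minutes per epoch — and supports exactly the layer
set the cascade needs. Accuracies measured on synthetic cohorts say
nothing quantitative about clinical spectra; the analytic recombination
of the published tables (`scripts/acceptance.R`) is exact, but the
generative claims are structural only. G2-vs-G3 sub-classification is
out of scope, mirroring the clinical collapse of those grades.
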