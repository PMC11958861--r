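---
title: "Translating structural MRI to synaptic-density PET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating structural MRI to synaptic-density PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Synaptic vesicle glycoprotein 2A (SV2A) PET with [¹¹C]UCB-J measures synaptic
density in vivo, but PET is expensive, involves radiation, and is unavailable
at most sites. Gray-matter morphometry from ordinary T1-weighted MRI is known
to co-vary with synaptic density, which raises the question whether a
convolutional network can learn a voxelwise mapping from T1 intensity
patterns to the SV2A PET distribution volume ratio (DVR),

$$\mathrm{DVR} = \frac{BP_{ND} + 1}{BP_{ND}[\mathrm{Cb}] + 1},$$

where $BP_{ND}$ is the non-displaceable binding potential and
$BP_{ND}[\mathrm{Cb}]$ its arithmetic mean over a cerebellar reference
region, so that reference tissue has DVR 1 by construction
(`compute_dvr()`).

`dvrnet` implements this pipeline end to end: a synthetic phantom cohort
generator (clinical SV2A data are not publicly distributable, so a fully
known ground truth stands in), deterministic preprocessing, a symmetric 3D
convolutional encoder–decoder trained on random patches, tiled whole-volume
inference, the image-quality metrics, and the cross-validated evaluation
designs.

## The phantom generator

`make_phantom()` builds one synthetic participant from nested ellipsoids:
a ventricular CSF core, a white-matter shell, a gray-matter ribbon whose
outer boundary is modulated by a low-order angular harmonic (so volumes have
reproducible, subject-specific structure beyond radial symmetry), and an
outer CSF rim, all inside a head ellipsoid with semi-axes 0.44 of the grid
and per-subject ±3 % axis jitter. A toy atlas labels the inferior cap of the
head as the cerebellum-analog reference region and partitions the rest into
11 azimuthal wedges named for regions studied in the SV2A literature
(frontal, insula, hippocampus, amygdala, occipital, parietal, precuneus,
putamen, pallidum, temporal, anterior cingulate), so that every ROI of the
regional analysis exists and is exercisable.

The synaptic-density analog is a known linear function of local gray-matter
density,

$$BP_{ND}(v) = b_0 + g\,\cdot\,\mathrm{GM}(v)\,\cdot\,m_{r(v)},$$

with baseline $b_0$ (`base_bpnd`, default 0.5), gain $g$
(`gm_to_sv2a_gain`, default 3.5, giving cortical $BP_{ND}\approx 4$ against
a white-matter floor of 0.5, the scale reported for [¹¹C]UCB-J), and a
diagnosis-specific regional multiplier $m_r \in (0,1]$ per atlas ROI.
Disease effects (`disease_effects()`) follow the qualitative literature: AD
carries the strongest and most widespread reductions (hippocampus 0.78,
temporal/amygdala 0.85, plus global gray-matter atrophy 0.92 whose lost GM
probability is reassigned to CSF so structural and synaptic changes
co-vary); SZ and CUD carry milder frontal/limbic reductions. The SZ/CUD
multipliers are configurable defaults, not quantitative claims.

The T1-like volume is a per-tissue intensity mixture (WM 1.0, GM 0.7,
CSF 0.25) under a smooth random linear bias field (±5 %) plus Gaussian
noise (SD 0.02). Measurement noise on $BP_{ND}$ follows a count-statistics
analogy: voxel SD $= \sigma_0/\sqrt{\mathrm{dose}}$ with
$\sigma_0$ (`noise_scale`) = 0.6, clipped at zero. Injected doses draw from
a truncated normal matching a typical [¹¹C]UCB-J cohort
(mean 15.71, SD 4.32 mCi); low-dose participants draw uniformly below the 5 mCi
threshold. At a 2.5 mCi analog this yields ≈10 % voxel noise on cortical
$BP_{ND}$ — a deliberately conservative "high-noise" regime (see
Limitations).

What the phantoms do *not* emulate: MR sequence physics, PET spatial
correlation of noise (scanner PSF), kinetic modelling error, motion, or
realistic cortical folding. Passing the package's tests therefore
demonstrates the correctness and internal consistency of the pipeline and
the learnability of a known GM→SV2A mapping at desk scale — not clinical
performance.

## Preprocessing

Brain masks combine the three tissue probabilities at a threshold of 0.5
(`combine_brain_mask()`), the conventional choice. Resampling
(`resample_to_grid()`) is separable nearest-neighbour (labels) or trilinear
(intensities) interpolation under the package's coordinate convention
(world = index × voxel size, 0-based, axis-aligned grids; registration is
assumed done upstream). Network inputs are masked T1 volumes divided by
their within-mask 99th-percentile intensity (`normalize_t1()`), which
bounds inputs near 1 and stabilises the L2 optimisation; the divisor is
recorded on the returned volume.

## The network

`network_config()` describes a symmetric valid-padding architecture: four
strided 3D convolutions with channel ladder 32/64/128/256 (downsampling by
stride 2), four stride-2 transposed convolutions with the mirrored ladder,
and a final stride-1 single-channel convolution, all with 3×3×3 kernels and
a rectifier after every convolutional operation. Down/up-sampling is by
stride rather than pooling, since only convolutional and transposed
convolutional layers appear in the design. The output layer is rectified by
default (DVR is physically non-negative); `final_relu = FALSE` disables it.

Valid padding means the output is smaller than the input:
$\lfloor (n-k)/s \rfloor + 1$ per strided convolution, $(n-1)s + k$ per
transposed convolution, $n-k+1$ for the output layer (`output_shape()`
returns the full per-layer trace and rejects inadmissible inputs naming the
failing layer). An input can therefore not map exactly "back to its own
size"; training targets are centre-cropped to the valid output shape
(offset $\lfloor (in-out)/2 \rfloor$ per axis) and whole-volume inference
handles margins by tiling. Weights use fan-in-scaled Gaussian
initialisation with a recorded seed; parameter counts follow the closed
form $\sum_\ell (k^3 c_{in} c_{out} + c_{out})$.

The layers are implemented in the package via an im2col/col2im lowering
(Rcpp) feeding BLAS matrix products, with analytic backpropagation verified
against finite differences in the test suite; a transposed convolution is
computed exactly as the adjoint of the corresponding strided convolution.

## Training

`train()` follows the reference full-scale schedule: random 64³ patches (the same crop
window applied to the T1 input and DVR target), batch 4, 100 steps per
epoch — 400 patches per epoch — 150 epochs, Adam (moments 0.9/0.999) at an
initial learning rate of 0.001 with staircase decay by 0.99 every 100 steps
(`lr_at()`). Patch corners are uniform over all fitting positions; each
step draws its source participants uniformly with replacement. The loss is
the unmasked voxel mean squared error (background is already zeroed by
preprocessing). Validation loss over a fixed set of patches is monitored
per epoch but never used for model selection: final-epoch weights are
returned (no early stopping). The whole run is reproducible from the
config seed.

## Whole-volume inference

`plan_tiles()` covers a volume with pairwise-disjoint output windows
(count = ⌈axis / output-tile⌉ per axis, trailing tile cropped to the
remainder) — non-overlap in *output* space is what prevents visible seams
from double-written voxels. Two further choices matter for valid-padding
networks and are worth spelling out:

* **Input windows stay inside the volume.** Only the small valid-padding
  margin is padded (mirror by default, zero optional); each tile's input
  window is shifted, where necessary, to lie within that padded grid, so
  input windows may overlap near the trailing edge. The alternative —
  padding the volume by up to a full tile — feeds the network wide bands of
  synthetic content it has never seen, and we found predictions degrade
  sharply on such out-of-distribution windows.

* **Tiles default to the training patch size, with an overlap-tile margin.**
  The strided encoder collapses a 32³ training patch to a *single*
  bottleneck position; a larger inference window (say 64³) produces a 2³
  bottleneck whose transposed-convolution overlap-add regime the trained
  weights have never operated in, and the computed function genuinely
  differs. `predict_case()` therefore tiles at the recorded training patch
  size. Because valid-padding outputs are least reliable near the window
  border (no image context beyond it), only a central crop of each tile's
  output is kept (`margin` in `plan_tiles()`) — the classic overlap-tile
  strategy; output windows remain disjoint and exactly covering.
  `select_tile_margin()` picks the margin by scoring whole-volume
  predictions of the *validation* cases against their measured (noisy) DVR,
  the only reference real data would offer — a standard model-selection
  step that touches no test data.

At full scale the reference setting — training at 64³ (bottleneck 2³, so
the overlap-add regime is trained) and a single 240×240×160 inference patch
covering the whole brain — avoids internal tile borders altogether; the
package reproduces that configuration when asked
(`plan_tiles(c(256,256,207), c(240,240,160), cfg)`).

## Metrics

The four image-quality formulas are implemented in their literal form: masked MSE; the
*global-moment* SSIM
$\frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}{(\mu_x^2+\mu_y^2+c_1)(\sigma_x^2+\sigma_y^2+c_2)}$
computed from single masked means, population variances and covariance with
$c_i = (k_i L)^2$, $k_1 = 0.01$, $k_2 = 0.03$, and $L$ the within-mask
dynamic range of the ground truth (falling back to 1 when the truth is
constant, so the constants still stabilise the degenerate case) — a
windowed local-SSIM variant is available behind the `window` argument for
comparison; signed percentage bias
$100\,(\mu_{x_R} - \mu_{y_R})/\mu_{x_R}$ (positive = undershoot); Pearson
correlation over masked voxels; and joint histograms with the closed-form
least-squares line. Evaluation is within the brain mask by default, since
the images are brain-masked upstream. Group comparisons use Welch's
two-sided two-sample t-test (`group_ttest()`), the robust default where no
variant is specified; the pooled-variance form is switchable. All metrics
reject shape mismatches rather than broadcasting.

## Evaluation designs

`make_folds()` implements stratified k-fold cross-validation with the
low-dose-always-test rule: low-dose participants appear in every fold's
test set and never in training or validation. The reference full-scale sizes
(130/7/23 from 160 participants with 5 fixed test members) cannot form a
disjoint exact-coverage partition across 10 folds (155 eligible ≠ 10 × 18
unique slots), so two modes exist: by default test sets rotate over a
diagnosis-stratified partition of the eligible participants (guaranteed
coverage, near-equal sizes), and in strict mode test sets are topped up by
resampling so every fold has exactly the stated sizes, a participant then
possibly being tested more than once — consistent with low-dose
participants being "evaluated repeatedly". Training sets are allocated to
cohort diagnosis proportions by largest remainder, which keeps every train
set within one participant of exact proportionality.
`leave_one_disease_out()` trains on three diagnostic groups and tests on
the fourth. `run_crossval()` re-initialises weights freshly per fold (seed
offset by fold index), audits id disjointness, and aggregates per-group and
per-ROI mean ± SD tables with normal-dose and low-dose strata never mixed.
`denoising_comparison()` scores, per low-dose case, the measured-noisy DVR
and the prediction against the noiseless reference — a comparison only
synthetic data permit.

## The scaled-down study

The desk-scale experiment run by `scripts/acceptance.R` and the end-to-end
tests uses 24 phantoms on 48³ grids at 3 mm (ratio HC:SZ:AD:CUD = 12:4:4:4,
3 low-dose), a reduced ladder (8/16/32/64), 32³ patches, batch 2, 30 epochs
× 50 steps (3 000 optimisation steps, 6 000 patches), a 16/2/6 split with
the low-dose cases test-only, and 5 extra held-out low-dose phantoms for
the denoising comparison. These sizes keep the full study — simulation,
training, tiled inference, scoring — within minutes on one CPU core.

Two observed limitations of this reduced configuration are worth recording,
because they are properties of the configuration rather than of the method:

* **A 64-number bottleneck.** At patch 32³ the reduced encoder compresses
  each window to a single 1³×64 code from which the decoder must paint the
  entire 29³ output (there are no skip connections). Subject anatomy is
  recoverable from such a code only approximately, and window placements
  that are rare under uniform corner sampling (e.g. volume-corner windows)
  remain visibly undertrained after 3 000 steps. Whole-brain agreement
  therefore saturates below what the per-window interior achieves. The
  full-scale configuration (patch 64³, ladder to 256: a 2³×256 code) is
  16-fold richer at the bottleneck.

* **DVR normalisation tempers low-dose noise.** Dividing by the reference
  mean (+1) shrinks the chosen voxel noise
  (σ₀ = 0.6 → DVR noise SD ≈ 0.12 at 2.5 mCi), so the measured low-dose DVR
  is already close to the clean reference (MSE ≈ 0.013). Beating it
  requires whole-brain prediction accuracy beyond what the reduced
  configuration reaches, and the denoising comparison reports that
  honestly. The noise scale was fixed once as a conservative choice and is
  deliberately not revisited.

## Numerical choices

Volumes are double precision throughout and NIfTI files are written as
doubles, so write/read round-trips are bit-exact. Mirror padding reflects
without repeating the edge sample and survives pads wider than the volume.
Tissue probabilities are renormalised only where their sum exceeds 1.
`percent_bias` rejects a zero ground-truth region mean with a distinct
error; `compute_dvr` rejects an empty reference region; empty ROIs yield
flagged rows rather than silent omissions. Per-case phantom seeds derive
from the cohort seed and a 31-ary string hash of the participant id, so any
case regenerates bit-identically in isolation.
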