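---
title: "Methods: stroke lesion segmentation with a multi-loss U-Net, dense CRF and TTP postprocessing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stroke lesion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

strokeseg implements a complete desk-scale pipeline for ischemic stroke
lesion segmentation on multimodal brain MRI, together with the evaluation
metrics and the clinical small-vessel-disease scoring that typically
accompany such a study. This vignette is the package's own account of the
models it implements, the parameters that matter, the numerical choices
made, and what the synthetic phantom experiments do and do not demonstrate.

## The segmentation model

### Encoder–decoder network

The segmentation network is a U-shaped fully convolutional
encoder–decoder. Each encoder stage applies two 3×3 convolutions

$$a_j^{n} = f\Big(\sum_{i \in M_j} a_i^{n-1} \cdot k_{ij}^{n} + b_j^{n}\Big),$$

with ReLU activation $f$, followed by 2×2 max-pooling
$a_j^{n} = f(\beta_j^{n}\,\mathrm{down}(a_j^{n-1}) + b_j^{n})$ with the
multiplicative bias $\beta$ fixed at 1 and the pooling bias at 0 (both are
rarely trained in practice; the downsampling function is max over 2×2
windows in ceil mode). The decoder mirrors the encoder: nearest-neighbour
2× upsampling, a **centered crop layer** that clips the upsampled map to
the matching encoder feature size, channel concatenation with the skip
connection, and two further convolutions. The crop layer is what lets the
network segment images of any size: odd spatial dimensions survive the
pool/upsample round trip because the decoder output is clipped back to the
encoder grid at every stage.

Two 1×1-convolution softmax heads produce per-pixel class probabilities

$$P(d = j \mid c) = \frac{e^{\omega_j^T c}}{\sum_{l=1}^{k} e^{\omega_l^T c}},$$

one at full resolution (main head) and one on the penultimate decoder
stage (the bottleneck when depth is 1), upsampled to input size. Both are
trained with the multinomial cross-entropy

$$J(\omega) = -\frac{1}{m}\sum_{i=1}^{m}\sum_{j=1}^{k}
  \mathbf{1}\{d^i = j\}\,\log p(j \mid c^i),$$

and the total loss is the fixed convex combination
$0.8\,J_\text{main} + 0.2\,J_\text{aux}$. The auxiliary head shortens the
gradient path into the deep layers, which is the stated purpose of the
multi-loss structure (mitigating vanishing gradients); its placement on
the penultimate decoder stage is this package's concrete reading of an
otherwise unlocalized description, and the head weights are exposed in the
configuration.

Training uses Adam with learning rate 0.0001, first-moment decay 0.9,
L2 regularization 0.0005 and at most 21,000 iterations; all biases start
at zero and weights use seeded He-normal initialization. "Momentum 0.9"
is interpreted as Adam's first-moment decay (an SGD momentum reading
cannot apply once Adam is chosen), and the regularization coefficient as
L2 weight decay on convolution weights (not biases). Batch size, which
the reference setup leaves unstated, defaults to 8.

Two numerical choices matter in practice:

* **Input normalization.** Each input channel is z-scored per slice
  before entering the network. Raw MR intensities are arbitrary-unit
  values in the tens to hundreds; against He-initialized weights they
  produce initial logits of magnitude $10^1$–$10^2$ and an initial loss
  in the tens, from which Adam recovers slowly and unreliably. Unit-scale
  inputs make convergence fast and seed-robust. Normalization is applied
  identically at training and prediction time and can be disabled in the
  architecture configuration.
* **Log clamping.** Probabilities entering any logarithm are clamped at
  $10^{-12}$, so losses and unary energies are always finite.

The network is 2-D and slice-wise; volumes are processed slice by slice
and reassembled. The postprocessing stage is explicitly three-dimensional
(see below), which is where the pipeline's 3-D reasoning lives. This
split keeps training tractable on a single CPU while preserving the 3-D
character of the component analysis.

## Fully connected CRF refinement

The network's probability map is refined by a fully connected conditional
random field over all voxels with Gibbs distribution
$p(Y = c \mid I) = e^{-E(c \mid I)}/Z(I)$ and energy

$$E(c \mid I) = \sum_i \omega_i(c_i) + \sum_{i<j} \omega_{ij}(c_i, c_j).$$

One sign convention note: the source description equates the *negative*
energy with the sum of potentials, which combined with $p \propto e^{-E}$
would make high-potential labelings the most probable. This package
follows the standard convention — energy is the sum of potentials and low
energy means high probability — and documents the discrepancy here rather
than resolving it silently both ways.

The unary potential is the negative log of the network probability
(its functional form is otherwise unspecified; $-\log p$ is the choice
consistent with the Gibbs distribution). The binary potential is the
Potts-modulated two-kernel Gaussian

$$\omega_{ij}(c_i, c_j) = \mu(c_i, c_j)\Big[
  \omega_1 \exp\big(-\tfrac{|p_i - p_j|^2}{2\sigma_\alpha^2}
                    -\tfrac{|I_i - I_j|^2}{2\sigma_\beta^2}\big)
  + \omega_2 \exp\big(-\tfrac{|p_i - p_j|^2}{2\sigma_\gamma^2}\big)\Big]$$

with $\mu(c_i, c_j) = \mathbf{1}\{c_i \neq c_j\}$. The intensity field
$I$ is a designated reference channel of the modality stack (the first
network input channel by default, configurable): the appearance kernel
needs image intensities, even though the surrounding text also calls $I$
the network output. Defaults, which the source does not provide, are
$\omega_1 = \omega_2 = 1$, $\sigma_\alpha = \sigma_\gamma = 3$ voxels,
$\sigma_\beta = 10$ intensity units, 5 iterations; positions are measured
in voxel indices.

Inference is plain **mean-field with exact dense pairwise sums** — no
permutohedral-lattice approximation. The update, in its Potts form, is

$$Q_i(c) \propto \exp\Big(-\omega_i(c) - \sum_{j \neq i} k_{ij}\,(1 - Q_j(c))\Big),$$

normalized per voxel each iteration. Exact sums are $O(N^2)$ but entirely
feasible at desk scale (a 64×64 slice needs a 4096² kernel matrix), and
they make the solver *testable*: on instances of at most 12 voxels the
package enumerates the full labeling space, and the test suite verifies
that Gibbs probabilities normalize to 1 and that the mean-field MAP
agrees with the exhaustive minimum-energy labeling in at least 90 of 100
seeded random attractive instances (mean field is an approximation; on a
small fraction of instances it settles in a different basin, which is the
known and documented behaviour of the algorithm, not a defect). When both
kernel weights are zero there is no coupling and the input distribution
is analytically the fixed point, so refinement short-circuits to the
exact identity instead of round-tripping through $\exp(\log p)$.

## Connected-component postprocessing

The refined mask is screened twice, in order, on its 3-D connected
components (26-connectivity by default; 6 and 18 available):

1. **Mean-TTP screen** (threshold $\omega_1 = 100$ gray values): a
   component whose mean time-to-peak lies strictly on the removal side of
   the threshold is deleted. The source text removes components with mean
   TTP *above* the threshold, but ischemic tissue peaks late — elevated
   TTP is the lesion signature — so the literal reading deletes the
   lesion itself. The package default removes components *below* the
   threshold (keep high-TTP tissue); `ttp_removal_side = "above"`
   restores the literal reading. Components exactly at the threshold are
   retained.
2. **Relative-volume screen** (threshold $\omega_2 = 0.1$): components
   smaller than one tenth of the largest component are deleted. The
   source states the trigger as an equality ($v(n)/V_\text{max} =
   \omega_2$) and reuses the symbol $\omega_1$ for its value; both are
   read as typos — an exact-equality trigger fires on a measure-zero
   event — and the strict inequality $v(n)/V_\text{max} < \omega_2$ is
   used, so a ratio of exactly 0.1 survives. The largest component
   (ratio 1) always survives.

Both screens only remove voxels, so postprocessing output is always a
subset of its input.

## Evaluation metrics

Five metrics are computed per prediction/truth pair: Dice
$2TP/(2TP+FP+FN)$, precision $TP/(TP+FP)$, recall $TP/(TP+FN)$, the
Hausdorff distance

$$HD(E, F) = \max\Big(\max_{e \in E}\min_{f \in F} D(e,f),\;
                      \max_{f \in F}\min_{e \in E} D(e,f)\Big),$$

and the average symmetric surface distance
$ASSD(E,F) = \tfrac{1}{2}\big(ASD(E,F) + ASD(F,E)\big)$, where $ASD$ —
never defined in the source — is taken as the standard directional mean
nearest-point distance. Boundary point sets are the centres of foreground
voxels with at least one background face-neighbour, in physical
millimetres (0-based index × spacing): clinical slices are anisotropic
(5 mm thickness in the emulated protocol), so index-space distances would
be wrong. Metrics with a zero denominator raise explicit errors (or `NA`
inside the batch report) rather than a silent 0, which would corrupt
averages.

## CSVD burden score and MoCA classification

The total cerebral small vessel disease score awards one point each for:
deep WMH Fazekas 2–3 and/or periventricular WMH Fazekas 3; ≥ 1
microbleed; basal-ganglia perivascular spaces grade 2–4; ≥ 1 lacuna —
total 0–4. The Fazekas scale is handled as its two 0–3 subscales, which
expresses the combined 0–6 criterion losslessly. A MoCA total strictly
below 26 is classified as cognitive impairment; exactly 26 — left
unassigned by a "lower than 26"/"higher than 26" rule — is classified
not-impaired (strict `<`). A follow-up gain of more than two points is
flagged as improvement.

## The phantom generator

Real stroke cohorts and challenge datasets are not reproducible at desk
scale, so the package generates multimodal phantoms with known ground
truth: axis-aligned ellipsoidal lesions (semi-axes drawn uniformly from a
configurable range, merged by union, always fully inside the grid) on the
five channels of a typical stroke protocol — T1, T2, FLAIR, DWI, TTP.
Default tissue means (arbitrary units) follow the qualitative contrast of
each sequence: lesions are hypointense on T1 (70 vs 100), hyperintense on
T2/FLAIR/DWI (120/130/140 vs 80/70/60), and late-peaking on TTP (120 vs
60, noise SD 8) so that healthy and ischemic tissue fall on opposite
sides of the TTP screen's threshold of 100, as in perfusion physiology.
Channel noise is i.i.d. Gaussian (SD 5), the standard desk-scale
stand-in absent any stated noise model. Generation is bit-reproducible
given a seed, and per-sample seeds derive deterministically from a master
seed.

What the phantoms deliberately do **not** model: anatomy, partial-volume
effects, bias fields, registration error, non-ellipsoidal lesion shape,
and realistic perfusion dynamics. Passing the end-to-end test therefore
demonstrates that the implementation is correct and that the pipeline can
recover lesions whose intensity statistics differ from background — it
does not certify clinical performance, and the headline figures of
GPU-scale clinical training are out of its reach by construction.

## Study conditions and reproducibility

The package's reduced end-to-end study — the configuration its
acceptance checks and `scripts/acceptance.R` run — uses 100 single-slice
64×64 phantoms for training and 20 held-out for evaluation, a depth-2,
base-8-channel network over the four anatomical channels, and 450 Adam
iterations at batch size 8 (well under the 21,000-iteration ceiling;
the phantom task converges in a few hundred iterations). On one CPU the
whole study runs in about three minutes and reaches a mean held-out Dice
above 0.95 before refinement; CRF plus postprocessing consistently
improves it further by cleaning boundary noise and spurious components.

Every stochastic stage — phantom placement and noise, weight
initialization, minibatch sampling — takes a seed derived from one master
seed, so `run_pipeline()` is bit-reproducible on one device. The run
manifest records the configuration hash, per-stage status and every
output file.

## Known limitations

* The network is 2-D slice-wise; truly volumetric context only enters
  through the 3-D postprocessing.
* Dense-sum CRF inference is quadratic in voxel count: fine for slices
  and small volumes, prohibitive for full clinical grids (where lattice
  approximations would be the tool of choice).
* CRF parameters are fixed, not learned.
* Mean-field inference is approximate; its MAP can differ from the
  global minimum-energy labeling on a small fraction of instances.
* The phantom generator's simplifications listed above.
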