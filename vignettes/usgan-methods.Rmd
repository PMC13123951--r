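---
title: "Switchable CycleGAN ultrasound enhancement: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switchable CycleGAN ultrasound enhancement: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Grey-scale B-mode liver ultrasound from an aged scanner shows lower
parenchymal contrast, reduced brightness, heavier speckle, and near-field
reverberation bands compared with a modern high-end machine. Because the two
devices image different patients at different times, no paired ground truth
exists: improving the old images is an *unpaired* image-to-image translation
problem between a low-quality domain X and a high-quality domain Y.

`usgan` implements a switchable cycle-consistent adversarial network for this
task, together with everything needed to exercise it at desk scale without
any patient data: a seeded synthetic phantom generator that reproduces the
qualitative domain gap, classical shock/bilateral filter baselines, and a
quantitative evaluation suite.

## The model

A conventional CycleGAN uses two generators, one per direction. Here a
*single shared generator* serves both directions; the direction is selected
by adaptive instance normalization (AdaIN) codes emitted by a small
code-generator network (the ACG). AdaIN re-normalizes each feature channel
`f` to target statistics `s`:

    AdaIN(f, s) = sigma(s) * (f - mu(f)) / (sigma(f) + eps) + mu(s)

with `mu`/`sigma` the per-channel spatial mean and population standard
deviation. Because the switch only modulates channel-wise statistics and
never introduces new spatial structure, the shared-generator design
constrains both mappings to one feature representation — the property that
makes it attractive for medical images, where hallucinated structure is the
main risk.

Training uses two cycles. Forward: `x -> G(x, code_f) -> G(., code_b)` must
reconstruct `x` (cycle-consistency, mean absolute error). Backward:
symmetric, starting from `y`. Identity passes (`G(y, code_f)` compared with
`y`, and `G(x, code_b)` with `x`) discourage unnecessary modification. Two
patch-level discriminators score realness in each domain; the generator+ACG
objective is

    total_G = l_adv + lambda_cycle * l_cycle + lambda_identity * l_iden.

All four networks are updated simultaneously by Adam at every step.

### Architecture

Only the block vocabulary of the generator is fixed by the method
(convolution, instance normalization, AdaIN-modulated layers, upsampling
blocks); the concrete layout is this package's choice:

* encoder: one stride-1 and two stride-2 3x3 convolution blocks with
  (non-affine) instance normalization and ReLU — total downsampling factor 4;
* body: `n_res_blocks` (default 4) residual blocks whose two normalizations
  are AdaIN-modulated — 8 modulated layers by default;
* decoder: two nearest-neighbour x2 upsampling + convolution blocks, then a
  3x3 output convolution.

The ACG is a two-layer fully connected network mapping the one-hot direction
tag to all per-layer (shift, scale) vectors; scales pass through `exp()` so
they are strictly positive by construction. The ACG conditions on nothing
but the direction switch. Discriminators are PatchGAN-style: four stride-2
4x4 convolutions and a final 3x3 scoring convolution, so a 256x256 input
yields a 16x16 grid of patch scores.

### The output head

The output convolution produces a residual that is bounded by `tanh` and
*added to the input image*, followed by a clamp to [0,1]:

    out = clamp01( x + tanh(r(x)) ).

An enhancement mapping is a perturbation of its input — the clinical claim
is precisely that structure is preserved while contrast/brightness change —
and the residual form makes the identity mapping available at
initialization. At desk scale (a few hundred steps) this is what lets the
cycle and identity terms start near their optimum, so training effort goes
into the adversarial contrast/brightness shift rather than into re-learning
the copy function. Without the skip, the same network needs far more steps
to reach comparable structure preservation.

### Numerical choices

* `eps = 1e-5` is added to the feature standard deviation inside every
  normalization (the textbook formula has no stabilizer, but constant
  channels do occur, e.g. in saturated regions); the backward pass floors
  the standard deviation at `1e-12` to keep the constant-channel gradient
  finite (it is exactly zero there).
* Population (biased) standard deviation over spatial positions, the
  standard AdaIN convention.
* Images live in [0,1] at every interface; networks see `2v - 1` internally.
* Weights are Gaussian(0, 0.02) (ACG output layer 0.01 so the two direction
  codes start near-identical but not equal); biases zero.
* Least-squares adversarial form by default (`mean((score - target)^2)`);
  a sigmoid cross-entropy form is one config switch away.
* Adam with learning rate `2e-4` and betas `(0.5, 0.999)`, no schedule, no
  replay buffer — the simplest faithful loop; both are noted extension
  points. Resuming a fit re-creates fresh optimizer moments.

### Defaults and scale

Desk-scale defaults are `base_channels = 16`, 64-pixel crops, batch size 1.
A 16-channel generator trains in minutes on one CPU while exhibiting every
qualitative property the tests assert (cycle-loss decrease, contrast gain,
structure preservation); widening to 32 channels and 384-pixel crops — the
scale appropriate for clinical-size training sets — is one configuration
key away (`--clinical-scale` on the command line). Inference at 256x256 is
a single feed-forward pass at any width.

## The phantom generator

`make_scene()` draws seeded geometry: a homogeneous parenchyma (echogenicity
0.55–0.65), hypoechoic lesion discs (0.10–0.30), and dark tubular vessels,
plus disjoint foreground (lesion) and background (parenchyma) masks used by
the metrics. `render_bmode()` multiplies the echogenicity map by mean-one
gamma speckle with `looks` the shape parameter — the standard multi-look
approximation of envelope statistics: seeded, mean-preserving, and
one-parameter — then convolves with a Gaussian point-spread function.

The low-quality domain applies, in order: contrast compression about
mid-grey (`gain = 0.6`), brightness offset (`-0.08`), extra speckle at 6
looks, blur (`sigma = 0.8 px`), and three additive reverberation bands
(amplitude 0.2) confined to the top quarter of the image — equally spaced
horizontal bands, since the clinical description of the artifact is
qualitative. These defaults are calibration choices, not measured device
properties: they are anchored to the printed magnitudes of the clinical
domain gap (foreground/background contrast ratio of roughly 50 on the
0–255 scale for the old device versus ~68 after enhancement, with global
mean intensity and standard deviation nearly unchanged), so that the
translation a well-trained model must learn is of comparable size to the
clinical one rather than far larger. X and Y
are rendered from *different* seeded scenes, so the dataset is unpaired by
construction (`paired = TRUE` exists for oracle tests only).

What the phantom does **not** emulate: acoustic wave propagation, RF-domain
processing, curved-probe fan geometry, depth-dependent attenuation or focus,
and patient anatomy. Passing the desk-scale tests therefore demonstrates
that the training loop and metrics behave as designed on a controlled domain
gap — not clinical performance on real liver images.

## Metrics

* **CR** `= 255 * |mean(fg) - mean(bg)|`. Contrast-ratio conventions vary
  in the ultrasound literature; the absolute mean difference on the 0–255
  scale is consistent with the reported clinical magnitudes (roughly 50–80),
  and this interpretation is stated here prominently.
* **CNR** `= |mean(fg) - mean(bg)| / sqrt(var(fg) + var(bg))` with
  population variances — the standard radiology definition.
* **Patch-wise SSIM**: plain SSIM (stabilizers `(0.01)^2`, `(0.03)^2` on the
  unit range, uniform window) per patch on a stride grid (defaults 16/8),
  averaged. With patch = image size it equals global SSIM.
* **First-order statistics** on [0,1]; entropy in bits over 256 bins;
  skewness of a constant image is defined as 0.
* **GLCM**: equal-width quantization of [0,1] into `levels` bins (default
  64, offset (0,1), symmetric); features use 0-based level indices;
  correlation of a degenerate (constant) matrix is defined as 1.
* **Frechet distance** with sample (n-1) covariances and a symmetrized
  matrix square root; tiny negative eigenvalues are clamped, near-singular
  products retried with 1e-10 jitter. The feature extractor is *pluggable*:
  the default is a seeded random-convolution summary (deterministic, no
  downloaded weights); users wanting the conventional Inception-based
  protocol can pass their own extractor function.

ROIs come from the phantom's ground-truth masks, from user-supplied
`<stem>_fg.png` / `<stem>_bg.png` files, or — as a documented fallback — from
intensity quartiles (darkest quartile as foreground, brightest as
background, matching the hypoechoic-lesion convention).

## Baselines

The shock filter is the sign-of-Laplacian form
`v <- v - dt * sign(Laplacian(smoothed v)) * |grad v|` with Gaussian
pre-smoothing spanning the stated 9-pixel mask (`sigma = (mask-1)/6`),
`dt = 0.1`, 5 iterations, mirror boundaries. The bilateral filter uses
`sigma_spatial = 3` px, `sigma_range = 0.1`, 9-pixel window. No attempt is
made to be bit-compatible with any particular reference implementation of
these filters; only the qualitative behaviour (edge sharpening;
edge-preserving smoothing) matters for the comparison, and the otherwise
unstated constants are documented defaults.

## Test and acceptance problem sizes

The suite exercises training at the sizes a single CPU handles in minutes:
200 steps on 8+8 synthetic 64x64 images for the efficacy properties
(cycle-loss decrease, contrast-ratio gain on held-out low-quality images,
mean patch-wise SSIM >= 0.6 between translated and input images), two
2-epoch runs for bit-reproducibility, and a 256x256 single pass for the
inference shape contract. Metric oracles run on exhaustive 8x8/16x16
fixtures. `scripts/acceptance.R` re-runs the same pipeline end to end from a
caller-supplied seed and writes every headline quantity as JSON.

## Known limitations

* Desk-scale GAN training is stochastic across seeds; the properties above
  are asserted under fixed seeds, and individual seeds can differ in how
  much contrast gain 200 steps deliver.
* The DICOM reader covers single-frame uncompressed little-endian
  monochrome files only — the archived B-mode export case — and rejects
  everything else explicitly.
* No learning-rate schedule, replay buffer, or multi-domain codes beyond
  the two-direction switch; alternative deep-learning translation models
  (contrastive, transformer- or steganography-based) are out of scope and
  enter only as external points of comparison.
* Checkpoints are R serialization files; portability across R versions
  follows base R's RDS guarantees.
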