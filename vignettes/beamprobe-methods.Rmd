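---
title: "Probing learned ultrasound beamformers for overfitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing learned ultrasound beamformers for overfitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamprobe)
```

## The problem

Deep networks trained to reconstruct ultrasound images from raw
radiofrequency (RF) channel data can overfit: they perform beautifully on
data resembling their training set and fail silently elsewhere. The usual
detection routes — loss monitoring during training, cross-validation,
inference on freshly curated test data — all need the training code, the
training data, or new acquisitions. When all you have is a trained network
and its input format, none of them apply.

The premise of this package is that a *true* beamformer maps any channel
data, physical or not, to the image a conventional delay-and-sum (DAS)
beamformer would produce from the same input. Artificial inputs that no
sane training set contains therefore separate beamformers from memorizers:
feed the network an input it cannot have seen, beamform the identical
input with the reference DAS, and compare. A network that answers with
something resembling its training imagery is overfit.

## The probes

Three artificial probes are generated in the shape of a single
0-degree plane-wave acquisition (`n_elements` x `n_samples`):

* **zeros** — every sample is a near-zero constant `epsilon = 1e-20`,
  except the single center sample (index `floor(dim / 2)` on each 0-based
  axis), which is 1. The exact zero is avoided because a perfectly zero
  image cannot be max-normalized; the unit center sample makes the
  expected image the back-projection of one isolated impulse.
* **ones** — the complement: all ones around a center sample of
  `epsilon`. The expected image is nearly uniformly bright.
* **gaussian** — i.i.d. draws from N(0, 1), min-max normalized to
  [0, 1] over the whole matrix. Normalization is global rather than
  per-row; that is the simplest reading of mapping the matrix into the
  same range as the binary probes, and per-row normalization would alter
  inter-channel amplitude relations. The probe resembles electronic noise
  with no target present.

The Gaussian probe takes an explicit seed (default 0) and downstream
metrics on it are treated as stochastic. A `custom` kind accepts any
user-supplied matrix in [0, 1], so evaluators can keep private probe
patterns — the protocol only works if the probes were genuinely unseen
during training, and a published pattern could in principle be trained
against.

## The reference beamformer

`beamform_das()` implements textbook single-plane-wave DAS: per-channel
analytic signal (Hilbert transform along time; complex IQ is used directly
with a demodulation-frequency phase rotation), linear interpolation at the
two-way delay

$$\tau(x, z; e) = \frac{z\cos\theta + x\sin\theta + \sqrt{(x - x_e)^2 + z^2}}{c},$$

uniform receive apodization, coherent summation, magnitude, and
normalization by the global maximum. Delays falling outside the recording
window contribute zero. Design choices worth stating:

* **Envelope before or after summation.** The analytic signal is formed
  per channel and the magnitude taken after summation — the common
  open-reference behavior, and it handles RF and IQ uniformly.
* **Apodization.** Uniform by default. The ones probe then reconstructs
  to an almost exactly uniform image (mean 0.99998, population std
  about 2e-4 under the default configuration), consistent with the
  near-unity, low-variance ground truth expected for that probe. An
  f-number mask is available in `beamform_config()` but is not the
  default.
* **Degenerate normalization.** A pre-normalization maximum at or below
  1e-30 returns an all-zero image with a `degenerate` flag instead of
  dividing by zero. This output-side guard replaces input-side epsilon
  tricks: the probes already carry `epsilon` so this guard only fires for
  pathological inputs.
* **No trainable parameters.** The whole pipeline is closed-form;
  `count_trainable_params(list())` is 0, the baseline against which
  network complexity is compared.

The default acquisition (`default_config()`) is a 128-element linear
array, 0.30 mm pitch, 5.208 MHz center frequency sampled at 4x
(20.832 MHz), 1540 m/s, 2048 RF samples, imaging grid spanning the array
laterally and 5-50 mm in depth at 0.25 mm spacing. These mimic a typical
L11-4v-class plane-wave acquisition; every value lives in the
configuration object and none is hard-coded in an algorithm.

## The metric suite

For a ground-truth image $x$ and network output $y$ over $N$ overlapping
pixels, all on max-normalized envelopes:

* mean and population (1/N) standard deviation of each envelope image;
* $\ell_1 = \frac{1}{N}\sum_n |x_n - y_n|$ and
  $\ell_2 = \frac{1}{N}\sum_n (x_n - y_n)^2$;
* NCC, the Pearson correlation
  $\sum_n (x_n-\mu_x)(y_n-\mu_y) / \sqrt{\sum_n (x_n-\mu_x)^2 \sum_n (y_n-\mu_y)^2}$,
  invariant to linear brightness and contrast changes;
* SSIM, $(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2) /
  ((\mu_x^2+\mu_y^2+C_1)(\sigma_x^2+\sigma_y^2+C_2))$ with
  $C_1 = (0.01 L)^2$, $C_2 = (0.03 L)^2$, $L = 1$.

SSIM defaults to the standard windowed form — the mean of the SSIM map
over 11x11 Gaussian-weighted windows ($\sigma = 1.5$ px) fully contained
in the image — because that is how the cited SSIM literature defines the
index; a `global` mode evaluates the collapsed formula once over the whole
image for sensitivity analysis. Metrics are computed on envelope images,
not log-compressed ones (the losses are defined on the normalized images);
callers can pass dB images explicitly if they want the dB-domain variant.
A zero-variance NCC input raises an error rather than returning NaN: a
constant network output is a finding, not a missing value (inside
`metric_report()` it is recorded as `NA` with the other metrics intact).

Every metric is cross-checked in the test suite against independent
brute-force loop oracles on randomly generated image pairs.

## The decision flow

`evaluate_network()` runs three stages and raises *flags*; the overall
verdict is `overfit-suspected` iff at least one flag is raised, and every
flag's rationale quotes the offending value and threshold.

1. **Baseline checkpoint** (optional): the network and the reference DAS
   beamform the same realistic data; NCC below `baseline_ncc_min = 0.8`
   flags. This automates the qualitative "does it look right on real
   data" checkpoint with a correlation floor; the images are still
   exported by `build_report()` for human review. Note that a memorizer
   typically *passes* this stage — that is precisely why artificial
   probes are needed.
2. **Mean checkpoint**: zeros-probe output mean at or above 0.08 flags
   (expected: close to the ground truth's near-zero mean); ones-probe
   mean at or below 0.07 flags (expected: close to 1). The
   Gaussian-probe mean is deliberately *not* a criterion — the
   min-max-normalized noise probe has no usable mean expectation, and
   structural metrics carry the information instead.
3. **Structural metrics**: for every probe, NCC at or below 0.8 or SSIM
   at or below 0.2 against the probe's own DAS ground truth flags.

All thresholds are empirical separations, not derived quantities; they are
fields of `detector_thresholds()` and should be tightened or relaxed as
evidence accumulates. Comparisons are inclusive at the boundary. Whether a
single flag should decide the verdict is genuinely open; the default is
any-flag (the conservative choice for a screening tool), and the verdict
object retains per-probe flags so a majority rule can be applied
downstream.

## Progressive channel removal

`removal_sweep()` interpolates between realistic and artificial inputs:
at fractions 0, 0.05, ..., 1, a random subset of
`round(f * n_elements)` element rows (rounding half away from zero; the
half case needs a rule and "nearest integer" does not state one) is
replaced by `1e-20`, both the reference DAS and the network beamform the
*same* degraded data, and NCC/SSIM are recorded. At 100% removal the
input is exactly the zeros probe — including its unit center sample — so
the sweep ends at the zeros-probe comparison.

Removal sets are nested by default (a seeded permutation's prefixes), so
consecutive fractions differ by the newly removed elements only and the
curves are comparable step to step; `nested = FALSE` draws fresh sets per
fraction. A faithful network's curve stays at NCC = 1 by construction; a
memorizer's curve decays as the ground truth degrades away from its
stored image and reaches its minimum at 100%, where the expected image
(the center-sample back-projection) is maximally unlike any training
image.

## The synthetic simulator

`simulate_channel_data()` produces single 0-degree plane-wave channel
data for scatterer phantoms: each scatterer contributes a
Gaussian-windowed sinusoid echo at the same two-way delay the beamformer
uses (one shared delay routine — any divergence between simulator and
beamformer is a test failure), with optional i.i.d. Gaussian electronic
noise. Defaults: 5.208 MHz pulse, 0.6 fractional bandwidth (-6 dB), unit
amplitudes for point phantoms, N(0, 1) amplitudes for speckle.

`make_speckle_phantom()` converts a density of 10 scatterers per
resolution cell into a count using a nominal cell of 0.3 mm (lateral,
one wavelength) by 0.2 mm (axial, the two-way FWHM of the 0.6-bandwidth
pulse). With the initial coarser axial estimate the realized density per
true cell fell below the fully developed speckle regime and the envelope
std/mean ratio ran high; the 0.2 mm figure follows from the pulse length,
and with it the beamformed envelope in a uniform region shows Rayleigh
statistics (std/mean within 0.05 of 0.5227), which the acceptance tests
verify.

What the simulator does *not* model: element directivity, attenuation,
multiple scattering, elevation focusing. Passing tests on simulated data
therefore demonstrate protocol correctness and the detector's behavioral
separation — not performance on any particular clinical acquisition.

## Mock networks and what the tests demonstrate

Two fixtures bracket the behavior space. `mock_faithful_net()` wraps the
reference DAS (bitwise, by default); `mock_memorizer_net()` ignores its
input and returns a stored image, exactly the failure mode of a network
that "beamforms" by reproducing training imagery. The behavioral
guarantee — over 20 seeds varying the Gaussian probe and the memorized
content, the faithful mock always passes and the memorizer is always
flagged at default thresholds — is the package's core test.

The faithful mock accepts a smooth multiplicative gain field (at most 5%
deviation, then re-normalized) to emulate benign calibration differences.
One subtlety dictates how it is used: on the *ones* probe the ground
truth is nearly structureless (population std around 2e-4), so any gain
field dominates the correlation and NCC collapses even though the network
is faithful in every meaningful sense — NCC on a near-constant image
measures the perturbation, not fidelity. The gain-field variant is
therefore exercised where structure dominates (NCC at or above 0.99 on a
speckle phantom), and the behavioral guarantee uses the exact wrapper.
Operationally: a real network flagged *only* by ones-probe NCC, with the
ones-probe mean and all other probes clean, deserves a look at the
exported images before condemnation.

## Numerical choices and problem sizes

* Center index on even-length axes: `floor(dim / 2)` (0-based); "center"
  needs a convention and this matches truncating integer division.
* Linear interpolation of the analytic signal at delay times;
  out-of-window delays contribute 0.
* Windowed SSIM uses only fully contained windows (no padding), so images
  must be at least the window size; smaller images raise an error.
* The zeros-probe ground truth is a thin (about 0.1 mm) iso-delay band.
  On the default 0.25 mm grid, raster quantization fragments the
  half-maximum set, so the single-connected-region property is checked on
  a grid that resolves the band (0.05 mm axial pixels, 8-connectivity).
* Tests run on reduced acquisitions (32-64 elements, 640-1024 samples,
  5-30 mm depth) chosen as the smallest sizes at which the probed
  properties are scale-free; the ones-probe ground-truth statistic and
  the zeros-probe connectivity check use the full default configuration.

## Limitations

The package evaluates *whether* a network reproduces reference behavior
on unseen inputs, not *how much* it overfits; a network blending several
memorized patterns can sit anywhere on the flag spectrum. Thresholds are
empirical and should be recalibrated for beamformers whose reference is
not plane-wave DAS. The container format is an RDS file with a fixed
field schema — lossless and validated, but R-specific; exporters to
array-container formats are a natural extension.
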