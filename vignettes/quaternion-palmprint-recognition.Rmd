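---
title: "Quaternion-matrix multispectral palmprint recognition: model and methods"
author: "qpalm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quaternion-matrix multispectral palmprint recognition: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpalm)
```

## The problem and the representation

A multispectral palmprint sensor captures four co-registered images of one
palm placement under near-infrared (NIR), red, green and blue illumination.
Different wavelengths penetrate different skin layers, so the four bands
carry partly complementary identity information. Classical systems treat
the bands as four separate biometrics and fuse either the images (averaging
before feature extraction) or the matching scores (comparing bands
independently and combining distances). Image-level fusion discards
band-specific structure; score-level fusion ignores the correlation between
bands at the pixel level.

`qpalm` instead encodes the four preprocessed region-of-interest (ROI)
images as a single quaternion-valued matrix

$$Q(x,y) = I(x,y) + R(x,y)\,i + G(x,y)\,j + B(x,y)\,k,$$

with the NIR image in the scalar part and the red, green and blue images on
the imaginary units $i, j, k$ of Hamilton's algebra
($i^2 = j^2 = k^2 = ijk = -1$). All subsequent linear algebra — centering,
covariance, eigendecomposition, projection — is carried out over the
quaternions, so cross-band structure is retained end to end. When fewer
than four illuminations are available the missing channel is the zero
matrix, and the representation degrades gracefully.

## Preprocessing

The pipeline assumes pre-cropped, co-registered ROIs (nominally
128 × 128); full ROI localisation from whole-hand images is a separate
problem and is out of scope — a `center_crop()` utility is provided for
slightly larger inputs. The fixed order is: per-band 256-bin histogram
equalization (removing global intensity differences between acquisitions;
a constant image is returned unchanged, since its CDF is degenerate),
block-mean downsampling by a factor of 2 to 64 × 64 (block means rather
than naive decimation, to avoid aliasing — the choice is recorded in the
model object so either behaviour is reproducible), and quaternion
construction. Both feature extractors consume the same 64 × 64 quaternion
image. The local texture feature would also be well defined at 128 × 128;
unifying the two sizes keeps one preprocessing path and one set of
settings, and the block grid of the texture descriptor is documented under
that convention.

## Global features: quaternion PCA

Vectorizing each training image row-major gives quaternion columns
$Q_1,\dots,Q_n$ of length $m = 64^2$, stacked as $S_{m\times n}$. The
$m \times m$ pixel covariance is intractable and rank-deficient for
$n \ll m$, so the model works with the small surrogate covariance of the
centered matrix $E = S - \bar S$:

$$C_{n\times n} = \tfrac{1}{n-1}\,E^{T*}E,$$

a quaternion Hermitian matrix ($T*$ is the conjugate transpose). Its
eigenstructure is obtained by a quaternion Householder reduction: at each
elimination step a quaternion Householder reflector annihilates the
entries below the first subdiagonal, and a unit-quaternion phase rotation
makes the surviving subdiagonal entry real and nonnegative. The result is
a real symmetric tridiagonal $B$ and a unitary quaternion $P$ with
$C = P^{T*} B P$, so the standard real symmetric solver finishes the job.
Eigenvectors lift back as $V_C = P^{T*} V_B$ and then to pixel space as
$V = E\,V_C$, whose columns are explicitly unit-normalized (the unnormalized
lift scales columns by eigenvalue magnitude, which would distort projection
magnitudes). The spectrum is rescaled by $(n-1)/(m-1)$; the factor is
uniform, so the energy ratio and the component count are unaffected by it,
and it is kept isolated in one function.

Correctness of the eigensolver is verified against an independent oracle:
the complex adjoint. Each entry $a+bi+cj+dk$ maps to the 2 × 2 complex
block $[[z_1, z_2], [-\bar z_2, \bar z_1]]$ with $z_1 = a+bi$,
$z_2 = c+di$; the map is a ring homomorphism, and a quaternion Hermitian
matrix maps to a $2n \times 2n$ complex Hermitian matrix whose real
eigenvalues appear with doubled multiplicity. The test suite checks the
Householder path against this oracle on hundreds of random Hermitian
matrices to 1e-8.

Component count $p$ is the smallest prefix of the descending spectrum
capturing an energy ratio of 90% by default (a balance of accuracy
against feature dimension); ties in the sort are stable, and a zero
spectrum (no training variance) is an explicit error rather than $p = 0$.
The feature of a sample $s$ is $f = \hat P^{T*}(s - \bar s)$ with
$\hat P$ the first $p$ unit eigenvectors. Subtracting the training mean
matches the centering used in fitting; because a common offset cancels in
differences, matching distances are identical either way, and the raw
projection is available via `center = FALSE`. With ratio 1.0 the
projection is an isometry on the span of the centered training data,
which the tests assert to relative 1e-6.

## Local features: quaternion wavelet block deviations

One-scale quaternion wavelet analysis of $Q = I + Ri + Gj + Bk$ produces
approximation coefficients through four separable double convolutions
with signed cross-channel mixing of the $(I, G)$ and $(R, B)$ pairs:

$$\mathrm{coef}^I = (I g_1)g_1 + (G g_2)g_1 + (G g_1)g_2 - (I g_2)g_2,$$

and correspondingly for the other three channels, where each
juxtaposition is one convolution pass — rows first, then columns, with
half-sample symmetric boundary padding (the axis order and padding are
fixed conventions; the underlying formulas specify only the convolutions).
Only the approximation subband is used: detail coefficients are noise
sensitive. Dyadic decimation (every second row and column, from the first)
is applied by default, as in a standard one-scale decomposition, and can
be disabled in `qdwt_config()`.

The filter pair $(g_1, g_2)$ ships as configurable coefficient vectors.
The defaults are this package's transcription of the published pair; the
printed source is typographically unreliable, so every structural property
the package relies on — zero preservation, the vanishing of the $(R, B)$
channel pair for pure-NIR input, real-linearity — is tested
filter-agnostically, and users can substitute any finite pair.

The texture descriptor divides the coefficient image into non-overlapping
$z \times z$ blocks ($z = 5$ by default, balancing stability against
feature dimension; incomplete edge blocks are discarded to avoid biased
small-sample statistics) and summarizes block $l$ by the quaternion of
per-channel population standard deviations
$\sigma_l = \sigma^I_l + \sigma^R_l i + \sigma^G_l j + \sigma^B_l k$.
Population (not sample) deviations make the worked examples deterministic.
With 64 × 64 inputs, decimation gives 32 × 32 coefficients and a 6 × 6
grid, $h = 36$ blocks.

## Matching and fusion

Distances between feature vectors are quaternion-vector Euclidean
distances, identical to Euclidean distance on the $4L$ real coordinates.
The two feature types live on different scales, so each distance is
divided by the population standard deviation of that distance type over
all unordered pairs of gallery samples (genuine and impostor pairs pooled
— the normalization needs only a scale, not label information; an
all-identical degenerate gallery floors the scale at 1e-12 with a
warning). The fused score is

$$d = w_{\mathrm{QPCA}}\,\bar d_{\mathrm{QPCA}} +
      w_{\mathrm{QDWT}}\,\bar d_{\mathrm{QDWT}},$$

with fixed weights 0.6/0.4. As a weighted sum of scaled Euclidean metrics
it is itself a pseudometric. Identification is nearest neighbour over the
gallery with ties broken by the lowest gallery index (deterministic and
test-friendly); the evaluator reports the rank-1 identification rate.
Verification-mode metrics (EER, ROC) are not computed.

Two baselines mirror the classical fusion schemes. Image-level fusion
averages the selected bands into one real image (placed on the scalar
channel) before feature extraction. Score-level fusion runs an independent
single-band pipeline per band, normalizes each band's distances by that
band's own gallery statistics, and averages the per-band fused scores with
equal weights — whether tuned or equal weights were used historically is
not documented, so equal weights are the neutral choice. A single-band run
is the quaternion scheme restricted to one band (the band keeps its
canonical channel; the other channels are zero-filled), which is also how
arbitrary band subsets are evaluated.

## The synthetic data generator

Real multispectral palm databases are proprietary, so the package ships a
generator of palm-like galleries whose parameters are the study
conditions the package is evaluated under:

* **Class structure.** Each palm is a class-specific texture built from a
  shared ridge field (sums of randomly phased oriented sinusoids, each
  amplitude-modulated by a smooth low-frequency envelope so that local
  ridge density varies across the palm, as it does on real skin) plus a
  few dark principal-line strokes, and three further private ridge fields.
  The four underlying fields are orthogonalized exactly (Gram–Schmidt on
  the flattened pixels) and mixed across bands through the Cholesky factor
  of a target correlation matrix, so the clean template's inter-band pixel
  correlations equal the target exactly. The default target is the
  empirical correlation structure of real devices (blue–green 0.7421,
  blue–NIR 0.4487, …); correlation targeting on the generated images is
  approximate to about ±0.05 once acquisition effects are added.
* **Acquisition model.** Each instance blends the class fields with fresh
  instance-specific *session texture* fields at relative weight
  `session_sd` (orthogonalized, and mixed through the same Cholesky
  factor — so session variation leaves the band correlations on target),
  then applies one global integer shift of at most `max_shift = 2` pixels
  (all four bands shift together: one hand placement yields four aligned
  captures), per-band gain/offset jitter (sd 0.04 / 0.02), additive
  Gaussian noise (sd 0.02), clipping, and 8-bit quantization so samples
  round-trip exactly through PNG files.
* **Protocol.** 20 palms × 12 acquisitions by default; the first six
  (session one) are enrolled as the gallery, the remaining six (session
  two) are probes — 120 gallery and 120 probe samples.

`session_sd = 0.75` is calibrated so that single-band rank-1 accuracies
fall below the fused accuracy, typically in the low-to-mid-90% range
reported for real multispectral palm databases (the exact level varies
with the random class draw); with weaker session variation every scheme
saturates at 100% and comparisons between schemes are meaningless. What
the generator does **not** emulate: real skin reflectance spectra, ROI
localisation failures beyond pure translation, rotation or non-rigid
deformation between bands, and sensor artifacts. One limitation matters
for interpreting results: the session-texture fields share the amplitude
statistics of the class fields, so local-variance (block-deviation)
features carry much less identity information here than on real palms —
the QDWT-only accuracy on synthetic galleries is far below device-level
reports, while the fused and global-feature accuracies behave
realistically. Passing the end-to-end tests therefore shows that the
pipeline recovers identity under controlled, correlation-faithful
conditions — not field performance on a physical device.

Every generator output is a pure function of the configuration and seed:
per-class and per-instance seeds are derived arithmetically from the
master seed, and generation never perturbs the caller's RNG stream.

## Numerical choices and degenerate inputs

* Quaternion arrays are stored as four parallel double-precision real
  arrays (struct of arrays); a quaternion matrix product is 16 real
  matrix products, and serialization is a four-slice array with channel
  order (a, b, c, d), bit-exact on round trip.
* Householder steps skip reflections when the sub-column below the
  subdiagonal is already negligible (relative to machine epsilon), and
  the input must be Hermitian to 1e-8 relative tolerance.
* Eigenvector phase is a genuine indeterminacy of the quaternion
  eigenproblem (any column may be right-multiplied by a unit quaternion);
  feature *distances* are invariant to it, which the tests assert.
* Constant-image equalization, all-zero spectra, empty galleries and
  probes, shape mismatches, infeasible correlation targets and shifts
  exceeding the template margin all raise explicit errors or documented
  degenerate behaviour rather than propagating silently.

## Problem sizes used by the test and acceptance runs

The shipped verification runs use galleries the package generates itself:
20 classes × (6 + 6) instances at 128 × 128 for the end-to-end and
correlation checks, 15 classes × 2 instances at 32 × 32 (30 vectors) for
the isometry check, and 200 random Hermitian matrices of order 2–16 for
the eigensolver oracle. These sizes exercise every code path at desk
scale; the published experiments behind the method used a 500-palm
database, which is private.

## A worked call

```{r example, eval = FALSE}
cfg <- synth_config(n_classes = 6, instances_per_class = 4,
                    image_size = 64, seed = 7)
ds <- generate_dataset(cfg)
rec <- palm_recognizer(ds$gallery, downsample_factor = 1)
summary(rec)
evaluate_accuracy(rec, ds$probe)
```

`summary()` reports the retained component count and captured eigenvalue
energy, the texture feature length, the fusion weights and the fitted
normalizer scales; `predict()` returns a per-probe report with the
predicted identity and the winning fused distance.
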