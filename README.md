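# qpalm — multispectral palmprint recognition with quaternion matrices

`qpalm` identifies palms from multispectral region-of-interest (ROI)
images captured under four illuminations — near-infrared (NIR), red,
green and blue. Instead of treating the bands as four separate biometrics
and fusing images or matching scores, the four co-registered images are
encoded as one quaternion-valued matrix

    Q(x, y) = I(x, y) + R(x, y)·i + G(x, y)·j + B(x, y)·k

over Hamilton's algebra (i² = j² = k² = ijk = −1), and all feature
extraction runs directly on that representation, so cross-band structure
is never discarded. Missing illuminations are zero-filled and the method
degrades gracefully.

Two features are extracted per sample and fused:

* **Quaternion PCA (global appearance).** The small n×n Hermitian
  surrogate covariance C = Eᵀ*E/(n−1) of the centered training matrix is
  reduced by quaternion Householder reflections to a real symmetric
  tridiagonal B with unitary quaternion P (C = Pᵀ*BP), solved with the
  standard real symmetric eigensolver, and lifted back to pixel space.
  Components are kept up to a 90% eigenvalue-energy ratio; the feature is
  f = P̂ᵀ*(s − s̄). The eigensolver is verified against the complex
  adjoint representation (a ring homomorphism to 2n×2n complex matrices)
  as an independent oracle.
* **Quaternion wavelet block deviations (local texture).** One-scale
  quaternion wavelet approximation coefficients via separable double
  convolutions with signed cross-channel mixing of the (I, G) and (R, B)
  channel pairs, then per-channel population standard deviations over
  non-overlapping 5×5 blocks.

Matching normalizes each feature's Euclidean distance by the population
standard deviation of all pairwise gallery distances, fuses with weights
0.6 (QPCA) and 0.4 (QDWT), and identifies by nearest neighbour (rank-1).
Single-band, image-level-fusion and score-level-fusion baselines are
built in, as is a synthetic generator of correlated multi-band palm-like
galleries (real multispectral palm databases are proprietary).

Intended users: biometrics and image-analysis researchers who want a
reproducible, fully testable reference implementation of quaternion
subspace + wavelet recognition with its classical fusion baselines.

## Worked example

```r
library(qpalm)

cfg <- synth_config(n_classes = 6, instances_per_class = 4,
                    image_size = 64, session_sd = 0.3, seed = 7)
ds  <- generate_dataset(cfg)          # 12 gallery + 12 probe samples
rec <- palm_recognizer(ds$gallery, downsample_factor = 1)
summary(rec)
#> Multispectral palmprint recognizer (quaternion scheme)
#>   gallery: 12 samples, 6 subjects
#>   bands: nir+red+green+blue
#>   QPCA components: 9 (94.4% eigenvalue energy)
#>   QDWT feature length: 36 blocks
#>   fusion weights: 0.60 QPCA + 0.40 QDWT
#>   normalizer sigma [nir+red+green+blue]: qpca = 8.373, qdwt = 0.05613

evaluate_accuracy(rec, ds$probe)
#> [1] 1

head(predict(rec, ds$probe), 3)
#>   probe    true predicted distance
#> 1     1 palm001   palm001 3.467345
#> 2     2 palm001   palm001 2.534074
#> 3     3 palm002   palm002 1.837685
```

(`session_sd = 0.3` is an easy acquisition regime; the default 0.75
emulates the harder session-to-session texture change of real two-session
protocols.)

Reading the output: the recognizer kept 9 quaternion principal components
(94.4% of the eigenvalue energy) and 36 block-deviation texture values per
sample; `sigma` are the gallery distance scales used for normalization.
Each probe row shows the nearest-gallery identity and the fused distance
of that match; `evaluate_accuracy()` is the fraction of probes whose
predicted identity is correct (here all 12).

On disk, datasets use the layout `<root>/<subject>/<instance>_<band>.png`
plus a `manifest.csv`; `write_dataset()` / `read_dataset()` produce and
consume it, and `save_recognizer()` / `load_recognizer()` persist fitted
models. A thin command-line front end with `synth`, `fit`, `evaluate` and
`match` subcommands ships in `inst/cli/qpalm.R`.

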