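Package: qpalm
Title: Multispectral Palmprint Recognition with Quaternion Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Represents co-registered multispectral palmprint regions of
    interest (near-infrared, red, green and blue bands) as a single
    quaternion-valued image and identifies palms by fused nearest-neighbour
    matching. Global appearance features come from quaternion principal
    component analysis, computed with the small-sample covariance trick and
    a quaternion Householder tridiagonalization whose eigenvalues are
    cross-checked against the complex adjoint representation. Local texture
    features are block standard deviations of one-scale quaternion wavelet
    approximation coefficients. Distances of the two feature types are
    normalized by training-set standard deviations and fused with fixed
    weights. Includes single-band, image-level-fusion and score-level-fusion
    baselines, and a synthetic generator of correlated multi-band palm-like
    galleries for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
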