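#' Default inter-band correlation target
#'
#' Pairwise pixel correlations between the four illumination bands of a
#' multispectral palm acquisition, as measured on real devices: nearby
#' wavelengths (blue/green) correlate strongly, distant ones (blue/NIR)
#' weakly. Order: NIR, red, green, blue. The matrix is symmetric, unit
#' diagonal and positive definite, so it admits a Cholesky factor for the
#' generator's linear mixing.
#' @return a 4 x 4 correlation matrix
#' @export
default_band_correlation <- function() {
  R <- matrix(c(1,      0.7470, 0.3690, 0.4487,
                0.7470, 1,      0.5060, 0.6829,
                0.3690, 0.5060, 1,      0.7421,
                0.4487, 0.6829, 0.7421, 1), 4L, 4L, byrow = TRUE)
  dimnames(R) <- list(band_names(), band_names())
  R
}

#' Synthetic dataset configuration
#'
#' Describes a palm-like multispectral gallery: per-class line/ridge
#' textures shared across bands with band-specific components mixed to
#' approximate a target inter-band correlation structure, plus intra-class
#' acquisition variation (global shift, per-band gain/offset jitter,
#' additive noise). Defaults emulate a two-session acquisition protocol:
#' 12 instances per palm, the first 6 (session one) enrolled as gallery
#' and the remaining 6 (session two) used as probes, on 128 x 128 ROIs.
#'
#' @param n_classes number of distinct palms (>= 2)
#' @param instances_per_class acquisitions per palm (>= 2; split evenly
#'   into gallery and probe sessions)
#' @param image_size ROI side length in pixels
#' @param band_correlation 4 x 4 symmetric positive-semidefinite target
#'   correlation matrix, unit diagonal, band order NIR/red/green/blue
#' @param noise_sd additive Gaussian noise standard deviation on the unit
#'   pixel scale
#' @param session_sd relative weight in `[0, 1)` of the instance-specific
#'   session texture blended into every underlying field before band
#'   mixing. It models the texture change between acquisition sessions
#'   (skin condition, contact pressure, residual illumination structure)
#'   that limits single-band matching on real devices; because it passes
#'   through the same band-mixing factor as the class texture it leaves
#'   inter-band correlations on target. `0` removes all session variation.
#' @param gain_sd,offset_sd standard deviations of the per-band
#'   multiplicative gain (around 1) and additive offset jitter emulating
#'   illumination drift between acquisitions
#' @param max_shift maximum absolute per-instance translation in pixels
#'   (one global shift for all four bands — the device captures the four
#'   illuminations in a single hand placement)
#' @param amp texture amplitude around the mid-gray level
#' @param seed integer master seed; every generator output is a pure
#'   function of the configuration and this seed
#' @return an object of class `synth_config`
#' @export
synth_config <- function(n_classes = 20L, instances_per_class = 12L,
                         image_size = 128L,
                         band_correlation = default_band_correlation(),
                         noise_sd = 0.02, session_sd = 0.75, max_shift = 2L,
                         amp = 0.16, gain_sd = 0.04, offset_sd = 0.02,
                         seed = 1L) {
  if (n_classes < 2L) stop("need at least 2 classes")
  if (instances_per_class < 2L) stop("need at least 2 instances per class")
  R <- band_correlation
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)) ||
      any(abs(diag(R) - 1) > 1e-8) || any(R < -1 - 1e-8) || any(R > 1 + 1e-8))
    stop("band correlation must be symmetric with unit diagonal and entries in [-1, 1]")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("band correlation matrix is not positive semidefinite")
  if (session_sd < 0 || session_sd >= 1) stop("session_sd must lie in [0, 1)")
  structure(list(n_classes = as.integer(n_classes),
                 instances_per_class = as.integer(instances_per_class),
                 image_size = as.integer(image_size),
                 band_correlation = R, noise_sd = noise_sd,
                 session_sd = session_sd, max_shift = as.integer(max_shift),
                 amp = amp, gain_sd = gain_sd, offset_sd = offset_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# run expr under a derived seed without disturbing the caller's RNG stream
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed, kept inside 32-bit integer range
derive_seed <- function(seed, class_id, instance = 0L) {
  as.integer((as.double(seed) * 1000003 + class_id * 8191 + instance * 131) %% 2147483647)
}

# oriented sinusoidal ridge field on an s x s grid, standardized. Each
# wave is amplitude-modulated by a smooth low-frequency envelope so the
# local ridge density varies across the palm, as it does on real skin —
# this spatial variance structure is what block-deviation texture
# descriptors discriminate on.
ridge_field <- function(s, n_waves) {
  xs <- matrix(seq_len(s), s, s)
  ys <- t(xs)
  f <- matrix(0, s, s)
  for (w in seq_len(n_waves)) {
    theta <- stats::runif(1, 0, pi)
    freq <- stats::runif(1, 0.04, 0.25)      # cycles per pixel
    phase <- stats::runif(1, 0, 2 * pi)
    th_e <- stats::runif(1, 0, pi)
    fr_e <- stats::runif(1, 0.008, 0.03)     # envelope wavelength 33-125 px
    ph_e <- stats::runif(1, 0, 2 * pi)
    env <- 1 + sin(2 * pi * fr_e * (cos(th_e) * xs + sin(th_e) * ys) + ph_e)
    f <- f + stats::runif(1, 0.5, 1) * env *
      sin(2 * pi * freq * (cos(theta) * xs + sin(theta) * ys) + phase)
  }
  standardize_field(f)
}

# a few dark principal-line strokes: Gaussian-profile bands along slanted
# quadratic curves
line_strokes <- function(s, n_lines = 3L) {
  xs <- matrix(seq_len(s) / s, s, s)
  ys <- t(xs)
  f <- matrix(0, s, s)
  for (l in seq_len(n_lines)) {
    theta <- stats::runif(1, 0, pi)
    u <- cos(theta) * xs + sin(theta) * ys
    v <- -sin(theta) * xs + cos(theta) * ys
    c0 <- stats::runif(1, 0.25, 0.75)
    curv <- stats::runif(1, -0.6, 0.6)
    width <- stats::runif(1, 0.01, 0.025)
    dist <- u - c0 - curv * (v - 0.5)^2
    f <- f - stats::runif(1, 0.8, 1.2) * exp(-dist^2 / (2 * width^2))
  }
  f
}

standardize_field <- function(f) {
  f <- f - mean(f)
  s <- stats::sd(as.vector(f))
  if (s < 1e-12) f else f / s
}

# residualize the columns of X (after the first `fixed` ones) against all
# previous columns and re-standardize: exactly uncorrelated unit-sd fields
gram_schmidt_fields <- function(X, s, fixed = 1L) {
  for (k in (fixed + 1L):ncol(X)) {
    for (j in seq_len(k - 1L)) {
      X[, k] <- X[, k] - sum(X[, k] * X[, j]) / sum(X[, j]^2) * X[, j]
    }
    X[, k] <- as.vector(standardize_field(matrix(X[, k], s, s)))
  }
  X
}

#' Per-class multispectral template
#'
#' Builds the class-specific palm-like texture of one subject: a shared
#' ridge-and-principal-line field plus three band-private ridge fields,
#' orthogonalized (Gram-Schmidt on the flattened fields, so the underlying
#' components are exactly uncorrelated) and mixed through the Cholesky
#' factor of the target correlation matrix, making the pixelwise
#' inter-band correlations of the clean template match
#' `cfg$band_correlation` exactly. Templates carry a margin of `max_shift`
#' pixels on each side so instance shifts crop without wrapping.
#' Deterministic given `(class_id, cfg$seed)`.
#' @param class_id integer class index
#' @param cfg a [synth_config]
#' @return an object of class `palm_template`: the four underlying class
#'   fields (`fields`, pixels x 4), the rendered clean band images
#'   (`bands`, margin-extended), and the grid side `size`
#' @export
make_class_template <- function(class_id, cfg) {
  local_seed(derive_seed(cfg$seed, class_id), {
    s <- cfg$image_size + 2L * cfg$max_shift
    shared <- standardize_field(ridge_field(s, 6L) + 1.6 * line_strokes(s))
    fields <- list(shared, ridge_field(s, 5L), ridge_field(s, 5L), ridge_field(s, 5L))
    X <- gram_schmidt_fields(vapply(fields, as.vector, numeric(s * s)), s)
    U <- chol(cfg$band_correlation)       # R = U'U, so cor(X %*% U) = R
    Y <- 0.5 + cfg$amp * (X %*% U)
    bands <- lapply(seq_len(4L), function(b) matrix(Y[, b], s, s))
    names(bands) <- band_names()
    structure(list(fields = X, bands = bands, size = s, chol = U),
              class = "palm_template")
  })
}

#' Draw one acquisition instance from a class template
#'
#' Builds the acquisition as the class fields blended with fresh
#' instance-specific session-texture fields at weight `cfg$session_sd`
#' (orthogonalized against the class fields, then mixed across bands
#' through the template's Cholesky factor, so the blend preserves both
#' unit field variance and the target inter-band correlations). On top of
#' the blended texture it applies one global integer shift (shared by all
#' bands, wrap-free crop from the template margin), per-band gain and
#' offset jitter, additive Gaussian noise of standard deviation
#' `cfg$noise_sd`, clipping to the unit interval, and 8-bit quantization
#' so instances round-trip exactly through PNG files. Deterministic given
#' `(template, cfg, instance_seed)`.
#' @param template output of [make_class_template]
#' @param cfg a [synth_config]
#' @param label subject label to attach
#' @param instance acquisition index
#' @param instance_seed integer seed for this instance
#' @param drop_bands optional character vector of bands to omit from the
#'   sample (emulating missing illuminations)
#' @return a [palm_sample]
#' @export
sample_instance <- function(template, cfg, label, instance, instance_seed,
                            drop_bands = NULL) {
  margin <- cfg$max_shift
  side <- cfg$image_size
  s <- template$size
  if (s < side + 2L * margin)
    stop("shift margin larger than the template allows")
  local_seed(instance_seed, {
    w <- cfg$session_sd
    if (w > 0) {
      fresh <- vapply(1:4, function(k) as.vector(ridge_field(s, 5L)), numeric(s * s))
      FS <- gram_schmidt_fields(cbind(template$fields, fresh), s, fixed = 4L)[, 5:8]
      fields <- sqrt(1 - w^2) * template$fields + w * FS
    } else fields <- template$fields
    Y <- 0.5 + cfg$amp * (fields %*% template$chol)
    dx <- if (margin > 0L) sample.int(2L * margin + 1L, 1L) - margin - 1L else 0L
    dy <- if (margin > 0L) sample.int(2L * margin + 1L, 1L) - margin - 1L else 0L
    rows <- (margin + 1L + dx):(margin + side + dx)
    cols <- (margin + 1L + dy):(margin + side + dy)
    bands <- lapply(seq_len(4L), function(b) {
      tm <- matrix(Y[, b], s, s)[rows, cols]
      gain <- 1 + if (cfg$gain_sd > 0) stats::rnorm(1, 0, cfg$gain_sd) else 0
      offset <- if (cfg$offset_sd > 0) stats::rnorm(1, 0, cfg$offset_sd) else 0
      img <- 0.5 + gain * (tm - 0.5) + offset
      if (cfg$noise_sd > 0) img <- img + matrix(stats::rnorm(side * side, 0, cfg$noise_sd), side, side)
      img <- pmin(pmax(img, 0), 1)
      round(img * 255) / 255            # 8-bit quantization
    })
    names(bands) <- band_names()
    if (!is.null(drop_bands)) bands <- bands[setdiff(names(bands), drop_bands)]
    palm_sample(bands, label = label, instance = instance)
  })
}

#' Generate a gallery/probe dataset
#'
#' For each class, builds the template and draws
#' `cfg$instances_per_class` instances; the first half (session one)
#' becomes the enrolled gallery, the second half (session two) the probe
#' set. Fully reproducible: identical configurations give byte-identical
#' datasets.
#' @param cfg a [synth_config]
#' @return list with elements `gallery` and `probe`, each a list of
#'   [palm_sample] objects
#' @export
generate_dataset <- function(cfg) {
  n_sess1 <- cfg$instances_per_class %/% 2L + cfg$instances_per_class %% 2L
  gallery <- list(); probe <- list()
  for (cl in seq_len(cfg$n_classes)) {
    tmpl <- make_class_template(cl, cfg)
    label <- sprintf("palm%03d", cl)
    for (inst in seq_len(cfg$instances_per_class)) {
      smp <- sample_instance(tmpl, cfg, label, inst,
                             derive_seed(cfg$seed, cl, inst))
      if (inst <= n_sess1) gallery[[length(gallery) + 1L]] <- smp
      else probe[[length(probe) + 1L]] <- smp
    }
  }
  list(gallery = gallery, probe = probe)
}

#' Mean inter-band correlation of a sample set
#'
#' Averages, over samples, the pairwise Pearson correlation between
#' flattened band images. Requires all four bands in every sample.
#' @param samples list of [palm_sample] objects
#' @return symmetric 4 x 4 matrix with unit diagonal, band order
#'   NIR/red/green/blue
#' @export
band_correlation <- function(samples) {
  if (!length(samples)) stop("empty sample list")
  acc <- matrix(0, 4L, 4L)
  for (s in samples) {
    if (!all(band_names() %in% names(s$bands)))
      stop("band_correlation requires all four bands in every sample")
    X <- vapply(band_names(), function(b) as.vector(s$bands[[b]]),
                numeric(length(s$bands[[1L]])))
    acc <- acc + stats::cor(X)
  }
  R <- acc / length(samples)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  dimnames(R) <- list(band_names(), band_names())
  R
}

#' Write a dataset to a PNG directory tree with a manifest
#'
#' Lays samples out as `<root>/<subject>/<instance>_<band>.png` (8-bit
#' grayscale) and writes `manifest.csv` with columns
#' `subject, instance, band, path` — the layout [read_dataset] accepts.
#' @param samples list of [palm_sample] objects
#' @param root output directory (created if needed)
#' @return the manifest path, invisibly
#' @export
write_dataset <- function(samples, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in samples) {
    sub <- as.character(s$label)
    dir.create(file.path(root, sub), showWarnings = FALSE)
    for (b in names(s$bands)) {
      rel <- file.path(sub, sprintf("%s_%s.png", s$instance, b))
      png::writePNG(s$bands[[b]], file.path(root, rel))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sub, instance = as.character(s$instance), band = b,
        path = rel, stringsAsFactors = FALSE)
    }
  }
  manifest <- file.path(root, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
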