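#' Fit a multispectral palmprint recognizer
#'
#' The central fitting function of the package. Enrolls a gallery of
#' multispectral palm samples and returns a classed model that identifies
#' probes by nearest-neighbour search over fused feature distances.
#'
#' Under the default `"quaternion"` scheme the selected bands are encoded
#' as one quaternion image per sample (missing or deselected bands
#' zero-filled), from which two features are extracted: the global
#' quaternion-PCA projection and the local quaternion-wavelet block
#' standard deviations. Each feature's Euclidean distances are normalized
#' by the population standard deviation of all pairwise gallery distances
#' and fused with fixed weights (defaults 0.6 QPCA / 0.4 QDWT).
#'
#' Two classical baselines are available for comparison:
#' `"image_fusion"` averages the selected bands into a single real image
#' before feature extraction, and `"score_fusion"` runs an independent
#' single-band pipeline per band, normalizes each band's distances by its
#' own gallery statistics, and averages the per-band scores with equal
#' weights. A single-band run is the `"quaternion"` scheme with one band
#' selected.
#'
#' @param samples list of [palm_sample] gallery objects (the enrolled,
#'   labeled training set)
#' @param scheme `"quaternion"`, `"image_fusion"` or `"score_fusion"`
#' @param bands which bands to use, a subset of
#'   `c("nir", "red", "green", "blue")`
#' @param features `"both"`, `"qpca"` or `"qdwt"`
#' @param energy_ratio eigenvalue energy retained by the QPCA truncation
#'   (default 0.9)
#' @param qdwt a [qdwt_config]
#' @param weights a [fusion_weights] vector (used when `features = "both"`)
#' @param equalize,downsample_factor,crop preprocessing settings passed to
#'   [preprocess_sample]
#' @return an object of class `palm_recognizer`
#' @seealso [predict.palm_recognizer], [evaluate_accuracy]
#' @examples
#' cfg <- synth_config(n_classes = 3, instances_per_class = 4, image_size = 48,
#'                     max_shift = 1, seed = 7)
#' ds <- generate_dataset(cfg)
#' rec <- palm_recognizer(ds$gallery)
#' predict(rec, ds$probe)
#' @export
palm_recognizer <- function(samples, scheme = c("quaternion", "image_fusion", "score_fusion"),
                            bands = band_names(), features = c("both", "qpca", "qdwt"),
                            energy_ratio = 0.9, qdwt = qdwt_config(),
                            weights = fusion_weights(), equalize = TRUE,
                            downsample_factor = 2L, crop = NULL) {
  scheme <- match.arg(scheme)
  features <- match.arg(features)
  bands <- match.arg(bands, band_names(), several.ok = TRUE)
  if (!length(samples)) stop("empty gallery")
  if (!all(vapply(samples, inherits, TRUE, "palm_sample")))
    stop("samples must be palm_sample objects")
  prep <- list(equalize = equalize, downsample_factor = as.integer(downsample_factor),
               crop = crop)
  used <- switch(features, both = c("qpca", "qdwt"), qpca = "qpca", qdwt = "qdwt")
  labels <- vapply(samples, function(s) as.character(s$label), "")

  branch_bands <- if (scheme == "score_fusion") {
    avail <- bands[vapply(bands, function(b)
      any(vapply(samples, function(s) !is.null(s$bands[[b]]), TRUE)), TRUE)]
    if (!length(avail)) stop("no selected band is available in the gallery")
    as.list(avail)
  } else list(bands)

  branches <- lapply(branch_bands, function(bb) {
    imgs <- scheme_images(samples, scheme, bb, prep)
    fit_branch(imgs, used, energy_ratio, qdwt)
  })
  names(branches) <- vapply(branch_bands, paste, "", collapse = "+")

  structure(list(scheme = scheme, bands = bands, features = used,
                 weights = weights, qdwt_cfg = qdwt, energy_ratio = energy_ratio,
                 prep = prep, branches = branches, labels = labels,
                 n_gallery = length(samples), call = match.call()),
            class = "palm_recognizer")
}

# per-scheme quaternion images for a set of samples
scheme_images <- function(samples, scheme, bands, prep) {
  lapply(samples, function(s) {
    keep <- intersect(names(s$bands), bands)
    if (scheme == "image_fusion") {
      if (!length(keep)) stop("sample has none of the selected bands")
      avg <- Reduce(`+`, s$bands[keep]) / length(keep)
      s <- palm_sample(list(nir = avg), label = s$label, instance = s$instance)
    } else {
      if (!length(keep)) stop("sample has none of the selected bands")
      s$bands <- s$bands[keep]
    }
    preprocess_sample(s, equalize = prep$equalize,
                      downsample_factor = prep$downsample_factor, crop = prep$crop)
  })
}

# fit one feature branch (qpca model, gallery features, normalizer sigmas)
fit_branch <- function(imgs, used, energy_ratio, qdwt_cfg) {
  br <- list()
  if ("qpca" %in% used) {
    vecs <- lapply(imgs, vectorize_qimage)
    br$qpca_model <- fit_qpca(stack_qvectors(vecs), ratio = energy_ratio)
    br$f_qpca <- lapply(vecs, function(v) qpca_project(br$qpca_model, v))
    br$Fq <- embed_features(br$f_qpca)
  }
  if ("qdwt" %in% used) {
    br$f_qdwt <- lapply(imgs, function(im) qdwt_feature(im, qdwt_cfg))
    br$Fd <- embed_features(br$f_qdwt)
  }
  br$sigma <- vapply(used, function(ft) {
    M <- if (ft == "qpca") br$Fq else br$Fd
    s <- sd_pop(as.vector(stats::dist(M)))
    if (s < 1e-12) {
      warning("all gallery ", ft, " features identical; flooring sigma at 1e-12")
      s <- 1e-12
    }
    s
  }, 0)
  br
}

# probe features for one branch; returns embeddings
probe_branch <- function(br, imgs, used, qdwt_cfg) {
  out <- list()
  if ("qpca" %in% used) {
    out$Fq <- embed_features(lapply(imgs, function(im)
      qpca_project(br$qpca_model, vectorize_qimage(im))))
  }
  if ("qdwt" %in% used) {
    out$Fd <- embed_features(lapply(imgs, function(im) qdwt_feature(im, qdwt_cfg)))
  }
  out
}

# fused probe x gallery distance matrix for one branch
branch_dist <- function(br, pr, used, weights) {
  w <- if (length(used) == 2L) c(qpca = weights[["qpca"]], qdwt = weights[["qdwt"]])
       else stats::setNames(1, used)
  D <- 0
  if ("qpca" %in% used)
    D <- D + w[["qpca"]] * cross_dist(pr$Fq, br$Fq) / br$sigma[["qpca"]]
  if ("qdwt" %in% used)
    D <- D + w[["qdwt"]] * cross_dist(pr$Fd, br$Fd) / br$sigma[["qdwt"]]
  D
}

#' Fused probe-gallery distance matrix
#'
#' @param object a `palm_recognizer`
#' @param newdata list of [palm_sample] probes
#' @return a `length(newdata)` x `n_gallery` matrix of fused distances
#'   (averaged over bands under the score-fusion scheme)
#' @export
distance_matrix <- function(object, newdata) {
  stopifnot(inherits(object, "palm_recognizer"))
  total <- 0
  for (i in seq_along(object$branches)) {
    bb <- if (object$scheme == "score_fusion") names(object$branches)[i] else object$bands
    imgs <- scheme_images(newdata, object$scheme, bb, object$prep)
    pr <- probe_branch(object$branches[[i]], imgs, object$features, object$qdwt_cfg)
    total <- total + branch_dist(object$branches[[i]], pr, object$features, object$weights)
  }
  total / length(object$branches)
}

#' Identify probe samples
#'
#' Nearest-neighbour identification of each probe against the enrolled
#' gallery under the model's scheme. Ties are broken by the lowest gallery
#' index.
#' @param object a `palm_recognizer`
#' @param newdata list of [palm_sample] probes
#' @param type `"report"` (default) for a data frame with predicted and
#'   true labels and the winning distance, `"label"` for the predicted
#'   label vector, `"distance"` for the full fused distance matrix
#' @param ... unused
#' @return see `type`
#' @export
predict.palm_recognizer <- function(object, newdata, type = c("report", "label", "distance"), ...) {
  type <- match.arg(type)
  if (!length(newdata)) stop("empty probe set")
  D <- distance_matrix(object, newdata)
  if (type == "distance") return(D)
  idx <- apply(D, 1L, which.min)  # first minimum: lowest-index tie-break
  pred <- object$labels[idx]
  if (type == "label") return(pred)
  data.frame(probe = seq_along(newdata),
             true = vapply(newdata, function(s) as.character(s$label), ""),
             predicted = pred,
             distance = D[cbind(seq_along(idx), idx)],
             stringsAsFactors = FALSE)
}

#' Rank-1 identification rate of a fitted recognizer
#'
#' @param object a `palm_recognizer`
#' @param probes list of labeled [palm_sample] probes
#' @return fraction of probes whose nearest gallery neighbour has the true
#'   label
#' @export
evaluate_accuracy <- function(object, probes) {
  rep <- predict(object, probes, type = "report")
  mean(rep$predicted == rep$true)
}

#' @export
print.palm_recognizer <- function(x, ...) {
  cat("Multispectral palmprint recognizer (", x$scheme, " scheme)\n",
      "  gallery: ", x$n_gallery, " samples, ",
      length(unique(x$labels)), " subjects\n",
      "  bands: ", paste(x$bands, collapse = "+"),
      "; features: ", paste(x$features, collapse = "+"), "\n", sep = "")
  invisible(x)
}

#' @export
summary.palm_recognizer <- function(object, ...) {
  br <- object$branches[[1L]]
  out <- list(scheme = object$scheme, bands = object$bands,
              features = object$features, n_gallery = object$n_gallery,
              n_subjects = length(unique(object$labels)),
              weights = object$weights, sigma = lapply(object$branches, `[[`, "sigma"))
  if (!is.null(br$qpca_model)) {
    m <- br$qpca_model
    out$n_components <- m$n_components
    out$energy_captured <- sum(m$eigenvalues[seq_len(m$n_components)]) / sum(pmax(m$eigenvalues, 0))
  }
  if (!is.null(br$f_qdwt)) out$qdwt_length <- length(br$f_qdwt[[1L]])
  class(out) <- "summary.palm_recognizer"
  out
}

#' @export
print.summary.palm_recognizer <- function(x, ...) {
  cat("Multispectral palmprint recognizer (", x$scheme, " scheme)\n", sep = "")
  cat("  gallery: ", x$n_gallery, " samples, ", x$n_subjects, " subjects\n", sep = "")
  cat("  bands: ", paste(x$bands, collapse = "+"), "\n", sep = "")
  if (!is.null(x$n_components))
    cat("  QPCA components: ", x$n_components,
        sprintf(" (%.1f%% eigenvalue energy)\n", 100 * x$energy_captured), sep = "")
  if (!is.null(x$qdwt_length))
    cat("  QDWT feature length: ", x$qdwt_length, " blocks\n", sep = "")
  if (length(x$features) == 2L)
    cat(sprintf("  fusion weights: %.2f QPCA + %.2f QDWT\n",
                x$weights[["qpca"]], x$weights[["qdwt"]]))
  for (nm in names(x$sigma)) {
    s <- x$sigma[[nm]]
    cat("  normalizer sigma [", nm, "]: ",
        paste(sprintf("%s = %.4g", names(s), s), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Scree plot of the quaternion PCA spectrum
#'
#' @param x a `palm_recognizer` fitted with QPCA features
#' @param ... passed to [graphics::plot]
#' @export
plot.palm_recognizer <- function(x, ...) {
  m <- x$branches[[1L]]$qpca_model
  if (is.null(m)) stop("model was fitted without QPCA features")
  ev <- pmax(m$eigenvalues, 0)
  graphics::plot(seq_along(ev), ev, type = "b", pch = 16,
                 xlab = "component", ylab = "eigenvalue",
                 main = "Quaternion PCA spectrum", ...)
  graphics::abline(v = m$n_components + 0.5, lty = 2)
  invisible(x)
}

#' Persist and restore a fitted recognizer
#'
#' The archive holds the training mean, quaternion projection matrix (four
#' channels), eigenvalue spectrum, component count, normalizer statistics
#' and all preprocessing settings; a save/load round trip is bit-exact.
#' @param object a `palm_recognizer`
#' @param path file path
#' @export
save_recognizer <- function(object, path) {
  stopifnot(inherits(object, "palm_recognizer"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_recognizer
#' @export
load_recognizer <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "palm_recognizer")) stop("file does not hold a palm_recognizer")
  obj
}
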