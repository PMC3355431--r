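#' Feature pair
#'
#' A matched pair of feature vectors for one sample: the global quaternion
#' PCA feature and the local quaternion wavelet block-deviation feature.
#' @param qpca length-p `qarr`
#' @param qdwt length-h `qarr`
#' @return list of class `feature_pair`
#' @export
feature_pair <- function(qpca, qdwt) {
  structure(list(qpca = as_qarr(qpca), qdwt = as_qarr(qdwt)),
            class = "feature_pair")
}

#' Per-feature Euclidean distances between two samples
#'
#' @param u,v `feature_pair` objects with matching feature lengths
#' @return named numeric vector `c(qpca = ..., qdwt = ...)`
#' @export
feature_distances <- function(u, v) {
  c(qpca = qvec_dist(u$qpca, v$qpca), qdwt = qvec_dist(u$qdwt, v$qdwt))
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# stack a list of qarr vectors into an n x 4L real matrix; Euclidean rows
# distance equals the quaternion vector distance exactly
embed_features <- function(flist) {
  do.call(rbind, lapply(flist, q_flatten))
}

# full pairwise Euclidean cross-distance between row sets
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Fit the distance normalizer from gallery features
#'
#' Computes the population standard deviation of each distance type over
#' all unordered pairs of training samples (genuine and impostor pairs
#' pooled). Probe distances are later divided by these scales so the two
#' feature types contribute comparably to the fused score. Degenerate
#' all-identical training features are floored at 1e-12 with a warning.
#' @param features list of `feature_pair` objects (at least 3)
#' @return list of class `dist_normalizer` with `sigma_qpca`, `sigma_qdwt`
#' @export
fit_normalizer <- function(features) {
  if (length(features) < 3L) stop("need at least 3 gallery entries to fit the normalizer")
  sig <- vapply(c("qpca", "qdwt"), function(ft) {
    D <- stats::dist(embed_features(lapply(features, `[[`, ft)))
    s <- sd_pop(as.vector(D))
    if (s < 1e-12) {
      warning("all training ", ft, " features identical; flooring sigma at 1e-12")
      s <- 1e-12
    }
    s
  }, 0)
  structure(list(sigma_qpca = sig[["qpca"]], sigma_qdwt = sig[["qdwt"]]),
            class = "dist_normalizer")
}

#' Fusion weights
#' @param qpca,qdwt nonnegative weights summing to 1 (defaults 0.6 / 0.4)
#' @return named numeric vector of class `fusion_weights`
#' @export
fusion_weights <- function(qpca = 0.6, qdwt = 0.4) {
  if (qpca < 0 || qdwt < 0 || abs(qpca + qdwt - 1) > 1e-9)
    stop("weights must be nonnegative and sum to 1")
  structure(c(qpca = qpca, qdwt = qdwt), class = "fusion_weights")
}

#' Fused matching score between two samples
#'
#' \eqn{d = w_{QPCA}\, d_{QPCA}/\sigma_{QPCA} + w_{QDWT}\,
#' d_{QDWT}/\sigma_{QDWT}} — a weighted sum of normalized Euclidean
#' distances, hence itself a pseudometric on feature pairs.
#' @param u,v `feature_pair` objects
#' @param norm a `dist_normalizer`
#' @param w a [fusion_weights] vector
#' @return nonnegative fused distance
#' @export
fused_distance <- function(u, v, norm, w = fusion_weights()) {
  d <- feature_distances(u, v)
  unname(w[["qpca"]] * d[["qpca"]] / norm$sigma_qpca +
         w[["qdwt"]] * d[["qdwt"]] / norm$sigma_qdwt)
}

#' Nearest-neighbour identification of one probe
#'
#' Scans the gallery for the entry with minimal fused distance; ties are
#' broken by the lowest gallery index so results are deterministic.
#' @param probe a `feature_pair`
#' @param entries list of gallery `feature_pair`s
#' @param labels gallery labels, parallel to `entries`
#' @param norm a `dist_normalizer`
#' @param w a [fusion_weights] vector
#' @return list with `label`, `distance`, `index`
#' @export
identify_nn <- function(probe, entries, labels, norm, w = fusion_weights()) {
  if (!length(entries)) stop("empty gallery")
  d <- vapply(entries, function(e) fused_distance(probe, e, norm, w), 0)
  i <- which.min(d)  # which.min takes the first minimum: lowest-index tie-break
  list(label = labels[[i]], distance = d[[i]], index = i)
}

#' Rank-1 identification rate over a probe set
#'
#' Matches every labeled probe against the gallery and reports the
#' fraction whose nearest gallery neighbour carries the true identity.
#' @param entries,labels gallery feature pairs and labels
#' @param probes list of `feature_pair`s
#' @param probe_labels true labels, parallel to `probes`
#' @param norm a `dist_normalizer`
#' @param w a [fusion_weights] vector
#' @return accuracy in `[0, 1]`
#' @export
rank1_accuracy <- function(entries, labels, probes, probe_labels, norm,
                           w = fusion_weights()) {
  if (!length(probes)) stop("empty probe set")
  pred <- vapply(probes, function(p) identify_nn(p, entries, labels, norm, w)$label,
                 labels[[1L]])
  mean(pred == unlist(probe_labels))
}
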