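rand_pair <- function(p = 6, h = 4) feature_pair(rand_qarr(p), rand_qarr(h))

test_that("per-feature distances are symmetric Euclidean distances", {
  set.seed(1)
  u <- rand_pair(); v <- rand_pair()
  expect_equal(unname(feature_distances(u, u)), c(0, 0))
  expect_equal(feature_distances(u, v), feature_distances(v, u))
  d <- feature_distances(u, v)
  expect_equal(d[["qpca"]], qvec_dist(u$qpca, v$qpca))
  expect_equal(d[["qdwt"]], qvec_dist(u$qdwt, v$qdwt))
  w <- feature_pair(rand_qarr(5), rand_qarr(4))
  expect_error(feature_distances(u, w), "equal length")
})

test_that("the normalizer is the population sd of all pairwise gallery distances", {
  set.seed(2)
  feats <- replicate(6, rand_pair(), simplify = FALSE)
  norm <- fit_normalizer(feats)
  # independent oracle: enumerate unordered pairs explicitly
  pairs <- combn(6, 2)
  dq <- apply(pairs, 2, function(ij) qvec_dist(feats[[ij[1]]]$qpca, feats[[ij[2]]]$qpca))
  dd <- apply(pairs, 2, function(ij) qvec_dist(feats[[ij[1]]]$qdwt, feats[[ij[2]]]$qdwt))
  expect_equal(norm$sigma_qpca, pop_sd(dq), tolerance = 1e-12)
  expect_equal(norm$sigma_qdwt, pop_sd(dd), tolerance = 1e-12)
  expect_error(fit_normalizer(feats[1:2]), "at least 3")
  # degenerate: all features identical -> floored sigma with a warning
  same <- replicate(3, feats[[1]], simplify = FALSE)
  w <- testthat::capture_warnings(n0 <- fit_normalizer(same))
  expect_length(w, 2)  # one floor warning per feature type
  expect_match(w, "flooring", all = TRUE)
  expect_equal(n0$sigma_qpca, 1e-12)
})

test_that("scaling all features rescales sigma and cancels in normalized distances", {
  set.seed(3)
  feats <- replicate(5, rand_pair(), simplify = FALSE)
  n1 <- fit_normalizer(feats)
  cfac <- 3.7
  scaled <- lapply(feats, function(f) feature_pair(f$qpca * cfac, f$qdwt * cfac))
  n2 <- fit_normalizer(scaled)
  expect_equal(n2$sigma_qpca, cfac * n1$sigma_qpca, tolerance = 1e-10)
  d1 <- fused_distance(feats[[1]], feats[[2]], n1)
  d2 <- fused_distance(scaled[[1]], scaled[[2]], n2)
  expect_equal(d2, d1, tolerance = 1e-10)
})

test_that("fused distance is the stated convex combination", {
  set.seed(4)
  u <- rand_pair()
  norm <- structure(list(sigma_qpca = 1, sigma_qdwt = 1), class = "dist_normalizer")
  expect_equal(fused_distance(u, u, norm), 0)
  # construct normalized distances (2, 1): weights (0.6, 0.4) -> 1.6
  a <- feature_pair(qarr(c(0, 0)), qarr(0))
  b <- feature_pair(qarr(c(2, 0)), qarr(1))
  expect_equal(fused_distance(a, b, norm, fusion_weights(0.6, 0.4)), 1.6)
  # normalized distances (1, 1) give 1 for any valid weights
  c1 <- feature_pair(qarr(c(1, 0)), qarr(1))
  expect_equal(fused_distance(a, c1, norm, fusion_weights(0.25, 0.75)), 1)
  expect_error(fusion_weights(0.7, 0.4), "sum to 1")
})

test_that("fused distance is a pseudometric", {
  set.seed(5)
  feats <- replicate(3, rand_pair(), simplify = FALSE)
  norm <- fit_normalizer(replicate(4, rand_pair(), simplify = FALSE))
  for (rep in 1:25) {
    u <- rand_pair(); v <- rand_pair(); w <- rand_pair()
    duv <- fused_distance(u, v, norm)
    expect_gte(duv, 0)
    expect_equal(duv, fused_distance(v, u, norm), tolerance = 1e-12)
    expect_lte(duv, fused_distance(u, w, norm) + fused_distance(w, v, norm) + 1e-12)
  }
})

test_that("identification agrees with a brute-force scan and breaks ties by index", {
  set.seed(6)
  entries <- replicate(50, rand_pair(), simplify = FALSE)
  labels <- sprintf("s%02d", seq_len(50))
  norm <- fit_normalizer(entries)
  for (rep in 1:10) {
    probe <- rand_pair()
    got <- identify_nn(probe, entries, labels, norm)
    # brute-force oracle: naive loop over every entry
    best_d <- Inf; best_i <- NA
    for (i in seq_along(entries)) {
      di <- fused_distance(probe, entries[[i]], norm)
      if (di < best_d) { best_d <- di; best_i <- i }
    }
    expect_equal(got$index, best_i)
    expect_equal(got$distance, best_d)
  }
  # probe equal to an entry -> that label at distance 0
  hit <- identify_nn(entries[[7]], entries, labels, norm)
  expect_equal(hit$label, "s07")
  expect_equal(hit$distance, 0)
  # exact ties resolve to the lowest gallery index
  dup <- entries
  dup[[20]] <- dup[[3]]
  tie <- identify_nn(dup[[3]], dup, labels, norm)
  expect_equal(tie$index, 3)
  expect_error(identify_nn(rand_pair(), list(), character(), norm), "empty gallery")
})

test_that("rank-1 accuracy is exact on self-matching and near chance on shuffled labels", {
  set.seed(7)
  entries <- replicate(30, rand_pair(), simplify = FALSE)
  labels <- sprintf("s%02d", seq_len(30))
  norm <- fit_normalizer(entries)
  expect_equal(rank1_accuracy(entries, labels, entries, labels, norm), 1.0)
  # random features against 20 classes: accuracy should sit near 1/20
  gal <- replicate(20, rand_pair(), simplify = FALSE)
  glab <- sprintf("c%02d", 1:20)
  probes <- replicate(200, rand_pair(), simplify = FALSE)
  plab <- sample(glab, 200, replace = TRUE)
  acc <- rank1_accuracy(gal, glab, probes, plab, fit_normalizer(gal))
  expect_lt(acc, 0.15)
  # common rescaling of both sigmas cannot change any ranking
  n2 <- structure(list(sigma_qpca = norm$sigma_qpca * 9, sigma_qdwt = norm$sigma_qdwt * 9),
                  class = "dist_normalizer")
  probes2 <- replicate(15, rand_pair(), simplify = FALSE)
  pred1 <- vapply(probes2, function(p) identify_nn(p, entries, labels, norm)$label, "")
  pred2 <- vapply(probes2, function(p) identify_nn(p, entries, labels, n2)$label, "")
  expect_identical(pred1, pred2)
  expect_error(rank1_accuracy(entries, labels, list(), character(), norm), "empty probe")
})

test_that("baseline schemes reduce to single-band runs in degenerate cases", {
  set.seed(8)
  base <- matrix(runif(64 * 64), 64, 64)
  mk <- function(lab, inst) {
    img <- pmin(pmax(base + matrix(rnorm(64 * 64, 0, 0.05 * inst + 0.02 * lab), 64, 64), 0), 1)
    palm_sample(list(nir = img, red = img, green = img, blue = img),
                label = paste0("s", lab), instance = inst)
  }
  samples <- unlist(lapply(1:3, function(l) lapply(1:2, function(i) mk(l, i))), recursive = FALSE)
  gal <- samples[c(1, 3, 5)]; pro <- samples[c(2, 4, 6)]
  # four identical bands: image-level fusion equals the single-NIR pipeline
  m_fuse <- palm_recognizer(gal, scheme = "image_fusion", downsample_factor = 1L)
  m_nir <- palm_recognizer(gal, scheme = "quaternion", bands = "nir", downsample_factor = 1L)
  expect_equal(distance_matrix(m_fuse, pro), distance_matrix(m_nir, pro), tolerance = 1e-10)
  # score fusion over a single band equals that band's pipeline
  m_score <- palm_recognizer(gal, scheme = "score_fusion", bands = "red", downsample_factor = 1L)
  m_red <- palm_recognizer(gal, scheme = "quaternion", bands = "red", downsample_factor = 1L)
  expect_equal(distance_matrix(m_score, pro), distance_matrix(m_red, pro), tolerance = 1e-10)
})
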