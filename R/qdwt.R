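#' Quaternion wavelet configuration
#'
#' Holds the two real analysis filters of the one-scale quaternion wavelet
#' decomposition together with the block size of the texture descriptor.
#' The filter pair drives the signed cross-channel mixing of the
#' approximation coefficients; the defaults are this package's
#' transcription of the published pair and are fully configurable — every
#' structural property of the transform (linearity, channel vanishing,
#' zero preservation) holds for any finite filter pair.
#'
#' @param g1,g2 numeric filter coefficient vectors (nonempty, finite)
#' @param z block side length of the standard-deviation descriptor
#'   (default 5, balancing stability against feature dimension)
#' @param decimate keep every second row/column (starting at the first)
#'   after filtering, as in a standard one-scale decomposition
#' @param boundary padding mode; only `"symmetric"` (half-sample edge
#'   reflection) is implemented
#' @return an object of class `qdwt_config`
#' @export
qdwt_config <- function(g1 = qdwt_default_g1(), g2 = qdwt_default_g2(),
                        z = 5L, decimate = TRUE, boundary = "symmetric") {
  if (!length(g1) || !length(g2) || !all(is.finite(g1)) || !all(is.finite(g2)))
    stop("filters must be nonempty and finite")
  if (z < 1L) stop("block size must be at least 1")
  boundary <- match.arg(boundary, "symmetric")
  structure(list(g1 = as.double(g1), g2 = as.double(g2), z = as.integer(z),
                 decimate = isTRUE(decimate), boundary = boundary),
            class = "qdwt_config")
}

#' Default quaternion wavelet filters
#'
#' The default low/high pair used by the approximation-coefficient mixing
#' formulas. Any other finite pair may be supplied through [qdwt_config].
#' @return numeric coefficient vector
#' @export
qdwt_default_g1 <- function() {
  c(0, 0, 0, 0, 0, 1 / (4 * sqrt(2)), 0, 3 / (4 * sqrt(2)), 1 / 2, 0, 0, 0, 0) / 2
}

#' @rdname qdwt_default_g1
#' @export
qdwt_default_g2 <- function() {
  c(0, 0, 0, 0, 0, 0, 0, -3 / (4 * sqrt(2)), 0, 3 / (4 * sqrt(2)), 0, 0, 0) / 2
}

# 1-D convolution of every row of X with g, centered 'same' output,
# half-sample symmetric padding. out[j] = sum_t g[t] * xp[j + L - t].
conv_rows <- function(X, g) {
  L <- length(g)
  W <- ncol(X)
  cc <- (L - 1L) %/% 2L          # right context
  padl <- L - 1L - cc            # left context
  if (W < L) stop("image smaller than the filter support")
  left <- if (padl > 0L) X[, padl:1L, drop = FALSE] else X[, 0L, drop = FALSE]
  right <- if (cc > 0L) X[, W:(W - cc + 1L), drop = FALSE] else X[, 0L, drop = FALSE]
  Xp <- cbind(left, X, right)
  out <- matrix(0, nrow(X), W)
  for (t in seq_len(L)) {
    if (g[t] != 0)
      out <- out + g[t] * Xp[, (L - t + 1L):(L - t + W), drop = FALSE]
  }
  out
}

# separable double convolution: first pass along rows, second along columns
filt2 <- function(X, grow, gcol) t(conv_rows(t(conv_rows(X, grow)), gcol))

decimate2 <- function(X) X[seq(1L, nrow(X), by = 2L), seq(1L, ncol(X), by = 2L), drop = FALSE]

#' One-scale quaternion wavelet approximation coefficients
#'
#' Applies the separable double convolutions with the signed cross-channel
#' mixing of the (NIR, green) and (red, blue) channel pairs:
#' \deqn{coef^I = (I g_1)g_1 + (G g_2)g_1 + (G g_1)g_2 - (I g_2)g_2}
#' \deqn{coef^R = (R g_1)g_1 + (B g_2)g_1 + (B g_1)g_2 - (R g_2)g_2}
#' \deqn{coef^G = -(I g_1)g_2 - (G g_2)g_2 - (G g_2)g_1 + (I g_1)g_1}
#' \deqn{coef^B = -(R g_1)g_2 - (B g_2)g_2 - (B g_2)g_1 + (R g_1)g_1}
#' where each juxtaposition is a convolution pass (rows first, then
#' columns) with symmetric boundary padding. Only the approximation
#' subband is produced — detail coefficients are noise-sensitive and are
#' not used by the texture descriptor. When `cfg$decimate` is TRUE every
#' second row and column (starting at the first) is kept after both
#' passes.
#' @param Q an H x W quaternion image (`qarr`)
#' @param cfg a [qdwt_config]
#' @return the coefficient quaternion image
#' @export
qdwt_approx <- function(Q, cfg = qdwt_config()) {
  Q <- as_qarr(Q)
  if (is.null(dim(Q))) stop("input must be a 2-D quaternion image")
  I <- Q$a; R <- Q$b; G <- Q$c; B <- Q$d
  g1 <- cfg$g1; g2 <- cfg$g2
  cI <- filt2(I, g1, g1) + filt2(G, g2, g1) + filt2(G, g1, g2) - filt2(I, g2, g2)
  cR <- filt2(R, g1, g1) + filt2(B, g2, g1) + filt2(B, g1, g2) - filt2(R, g2, g2)
  cG <- -filt2(I, g1, g2) - filt2(G, g2, g2) - filt2(G, g2, g1) + filt2(I, g1, g1)
  cB <- -filt2(R, g1, g2) - filt2(B, g2, g2) - filt2(B, g2, g1) + filt2(R, g1, g1)
  if (cfg$decimate) {
    cI <- decimate2(cI); cR <- decimate2(cR); cG <- decimate2(cG); cB <- decimate2(cB)
  }
  qarr(cI, cR, cG, cB)
}

#' Block standard-deviation texture features
#'
#' Partitions the coefficient image into non-overlapping z x z blocks
#' (row-major; incomplete edge blocks are discarded to avoid biased
#' small-sample statistics) and summarizes each block by the quaternion
#' \eqn{\sigma_l = \sigma(block^I) + \sigma(block^R) i + \sigma(block^G) j
#' + \sigma(block^B) k} of per-channel population standard deviations. The
#' feature vector concatenates \eqn{[\sigma_1, \ldots, \sigma_h]} over the
#' h complete blocks.
#' @param coef coefficient quaternion image from [qdwt_approx]
#' @param z block side length
#' @return a length-h `qarr` with attribute `grid = c(rows, cols)` of the
#'   block grid
#' @export
block_std_features <- function(coef, z = 5L) {
  coef <- as_qarr(coef)
  dm <- dim(coef)
  if (is.null(dm)) stop("coefficient input must be 2-D")
  z <- as.integer(z)
  nbr <- dm[1L] %/% z
  nbc <- dm[2L] %/% z
  if (nbr < 1L || nbc < 1L) stop("coefficient image smaller than one block")
  h <- nbr * nbc
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  chans <- lapply(c("a", "b", "c", "d"), function(ch) {
    M <- coef[[ch]]
    out <- numeric(h)
    l <- 0L
    for (br in seq_len(nbr)) {        # row-major block order
      rows <- ((br - 1L) * z + 1L):(br * z)
      for (bc in seq_len(nbc)) {
        cols <- ((bc - 1L) * z + 1L):(bc * z)
        l <- l + 1L
        out[l] <- sd_pop(M[rows, cols])
      }
    }
    out
  })
  f <- qarr(chans[[1L]], chans[[2L]], chans[[3L]], chans[[4L]])
  attr(f, "grid") <- c(nbr, nbc)
  f
}

#' Extract the local texture feature of a quaternion image
#'
#' Convenience composition of [qdwt_approx] and [block_std_features].
#' @param Q quaternion image
#' @param cfg a [qdwt_config]
#' @return a `qarr` feature vector
#' @export
qdwt_feature <- function(Q, cfg = qdwt_config()) {
  block_std_features(qdwt_approx(Q, cfg), cfg$z)
}
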