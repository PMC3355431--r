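#' Center a quaternion training matrix
#'
#' Columns of `S` are vectorized training samples. The per-row (per-pixel)
#' mean over the n columns is subtracted from every column, giving the
#' centered matrix E whose row means vanish.
#' @param S an m x n `qarr`, n >= 2
#' @return list with `S`, `mean` (m x 1 `qarr`) and `E` (m x n, centered)
#' @export
center_training <- function(S) {
  S <- as_qarr(S)
  n <- ncol(S$a)
  if (is.null(n) || n < 2L) stop("need at least 2 training samples")
  mean_q <- qarr(rowMeans(S$a), rowMeans(S$b), rowMeans(S$c), rowMeans(S$d))
  E <- qarr(S$a - mean_q$a, S$b - mean_q$b, S$c - mean_q$c, S$d - mean_q$d)
  list(S = S, mean = mean_q, E = E)
}

#' Small sample covariance of a centered quaternion matrix
#'
#' The n x n surrogate covariance \eqn{C = E^{T*} E / (n - 1)} used instead
#' of the intractable m x m pixel covariance when the number of training
#' samples n is much smaller than the pixel count m. C is quaternion
#' Hermitian by construction.
#' @param E centered m x n `qarr` from [center_training]
#' @return an n x n Hermitian `qarr`
#' @export
small_covariance <- function(E) {
  E <- as_qarr(E)
  n <- ncol(E$a)
  C <- q_matmul(q_ct(E), E) / (n - 1)
  # enforce exact Hermitian symmetry against roundoff
  Ch <- q_ct(C)
  (C + Ch) / 2
}

#' Householder tridiagonalization of a quaternion Hermitian matrix
#'
#' Reduces an n x n quaternion Hermitian matrix C to a real symmetric
#' tridiagonal matrix B with nonnegative off-diagonal, together with the
#' unitary quaternion matrix P of accumulated transformations, such that
#' \eqn{C = P^{T*} B P}. Each elimination step applies a quaternion
#' Householder reflector that annihilates the sub-column below the first
#' subdiagonal, followed by a unit-quaternion phase rotation that makes the
#' surviving subdiagonal entry real and nonnegative. Because B is real, its
#' eigendecomposition is handled by the standard real symmetric solver and
#' lifted back through P.
#' @param C an n x n quaternion Hermitian `qarr` (checked to `tol`)
#' @param tol Hermitian-deviation tolerance
#' @return list with `B` (real symmetric tridiagonal matrix) and `P`
#'   (n x n unitary `qarr`)
#' @export
householder_tridiagonalize <- function(C, tol = 1e-8) {
  A <- as_qarr(C)
  dm <- dim(A)
  if (is.null(dm) || dm[1L] != dm[2L]) stop("input must be square")
  n <- dm[1L]
  herm_dev <- max(q_abs(A - q_ct(A)))
  if (herm_dev > tol * max(1, max(q_abs(A))))
    stop("input is not Hermitian within tolerance (deviation ", signif(herm_dev, 3), ")")
  A <- (A + q_ct(A)) / 2
  P <- q_eye(n)
  if (n == 1L) return(list(B = matrix(A$a, 1L, 1L), P = P))
  eps0 <- .Machine$double.eps
  for (k in seq_len(n - 1L)) {
    rows <- (k + 1L):n
    if (length(rows) > 1L) {
      x <- A[rows, k]
      normx <- qvec_norm(x)
      # only reflect when something below the subdiagonal survives
      below <- qvec_norm(x[-1L])
      if (normx > eps0 && below > eps0 * max(1, normx)) {
        x1 <- x[1L]
        a1 <- q_abs(x1)
        phi <- if (a1 > eps0) x1 / a1 else qarr(1)
        v <- x
        v[1L] <- x1 + phi * normx
        vn2 <- qvec_norm(v)^2
        vcol <- qarr(matrix(v$a), matrix(v$b), matrix(v$c), matrix(v$d))
        # H = I - 2 v v^{T*} / |v|^2 ; Hermitian and unitary
        reflect_left <- function(M) {  # M <- H M
          w <- q_matmul(q_ct(vcol), M)
          M - q_matmul(vcol, w) * (2 / vn2)
        }
        A[rows, ] <- reflect_left(A[rows, ])
        A[, rows] <- q_ct(reflect_left(q_ct(A[, rows])))
        P[rows, ] <- reflect_left(P[rows, ])
      }
    }
    # phase rotation: make the subdiagonal entry real and nonnegative
    t1 <- A[k + 1L, k]
    tmod <- q_abs(t1)
    if (tmod > eps0) {
      psi <- q_conj(t1) / tmod     # unit quaternion, psi * t1 = |t1|
      A[k + 1L, ] <- q_mult_row(psi, A[k + 1L, ])
      A[, k + 1L] <- q_mult_col(A[, k + 1L], q_conj(psi))
      P[k + 1L, ] <- q_mult_row(psi, P[k + 1L, ])
    }
  }
  B <- A$a
  B[abs(row(B) - col(B)) > 1L] <- 0
  B <- (B + t(B)) / 2
  list(B = B, P = P)
}

# left-multiply every entry of a 1 x n qarr row by the scalar quaternion s
q_mult_row <- function(s, row) q_mult(s, row)

# right-multiply every entry of an n x 1 qarr column by the scalar quaternion s
q_mult_col <- function(col, s) q_mult(col, s)

#' Eigenpairs of the pixel covariance from the tridiagonal factor
#'
#' Solves the real symmetric tridiagonal eigenproblem for B, lifts the
#' eigenvectors back to the small quaternion covariance
#' (\eqn{V_C = P^{T*} V_B}), then to pixel space (\eqn{V = E V_C}), unit
#' normalizes the columns, and rescales the eigenvalue spectrum by
#' \eqn{(n-1)/(m-1)}. The rescaling is uniform, so energy ratios and
#' component selection are unaffected by it. Eigenvalues are returned in
#' descending order with columns ordered consistently (stable order from
#' the symmetric solver).
#' @param B real symmetric tridiagonal matrix from
#'   [householder_tridiagonalize]
#' @param P unitary `qarr` from the same factorization
#' @param E centered m x n training `qarr`
#' @return list with `V` (m x n `qarr`, unit columns), `D` (rescaled
#'   eigenvalues, descending), `V_C` and `D_C` (small-problem eigenpairs)
#' @export
eig_from_tridiagonal <- function(B, P, E) {
  E <- as_qarr(E)
  n <- ncol(E$a)
  m <- nrow(E$a)
  es <- eigen(B, symmetric = TRUE)      # descending by contract
  V_B <- es$vectors
  D_C <- es$values
  V_C <- q_matmul(q_ct(P), as_qarr(V_B))
  V <- q_matmul(E, V_C)
  # unit-normalize pixel-space eigenvector columns (zero columns left as-is)
  nrm <- sqrt(colSums(V$a^2 + V$b^2 + V$c^2 + V$d^2))
  scl <- ifelse(nrm > 1e-300, 1 / nrm, 0)
  V <- qarr(sweep(V$a, 2L, scl, `*`), sweep(V$b, 2L, scl, `*`),
            sweep(V$c, 2L, scl, `*`), sweep(V$d, 2L, scl, `*`))
  D <- D_C * (n - 1) / (m - 1)
  list(V = V, D = D, V_C = V_C, D_C = D_C)
}

#' Select the number of principal components by energy ratio
#'
#' Returns the smallest p whose leading eigenvalues capture at least
#' `ratio` of the total spectrum mass. With `ratio = 1` this is the count
#' of positive eigenvalues. An all-zero spectrum (zero training variance)
#' is an error.
#' @param D eigenvalues sorted descending
#' @param ratio energy ratio in (0, 1]
#' @return integer p
#' @export
select_components <- function(D, ratio = 0.9) {
  if (ratio <= 0 || ratio > 1) stop("energy ratio must lie in (0, 1]")
  D <- pmax(D, 0)  # clip tiny negative roundoff
  total <- sum(D)
  if (total <= 0) stop("degenerate all-zero eigenvalue spectrum: training samples have no variance")
  if (ratio == 1) return(sum(D > total * 1e-12))  # relative floor drops roundoff modes
  cums <- cumsum(D) / total
  which(cums >= ratio - 1e-12)[1L]
}

#' Fit a quaternion PCA model
#'
#' Full global-feature pipeline: center the training columns, form the
#' small n x n Hermitian covariance, tridiagonalize it with quaternion
#' Householder reflections, lift the eigenpairs to pixel space, and keep
#' the leading components that capture `ratio` of the eigenvalue energy
#' (default 90%, balancing accuracy against feature dimension).
#' @param S an m x n `qarr` whose columns are vectorized training samples,
#'   or a list of length-m `qarr` vectors
#' @param ratio energy ratio in (0, 1]
#' @return an object of class `qpca` with elements `mean` (length-m
#'   `qarr`), `projection` (m x p `qarr`, unit columns), `eigenvalues`
#'   (descending), `n_components`, `ratio`
#' @export
fit_qpca <- function(S, ratio = 0.9) {
  S <- stack_qvectors(S)
  ct <- center_training(S)
  C <- small_covariance(ct$E)
  hh <- householder_tridiagonalize(C)
  eg <- eig_from_tridiagonal(hh$B, hh$P, ct$E)
  p <- select_components(eg$D, ratio)
  structure(list(mean = ct$mean, projection = eg$V[, seq_len(p)],
                 eigenvalues = eg$D, n_components = p, ratio = ratio,
                 n_train = ncol(S$a), m = nrow(S$a)),
            class = "qpca")
}

# accept a list of equal-length qarr vectors or an m x n qarr matrix
stack_qvectors <- function(S) {
  if (is_qarr(S)) {
    if (is.null(dim(S))) stop("training input must be 2-D or a list of vectors")
    return(S)
  }
  if (!is.list(S) || length(S) < 2L) stop("need at least 2 training samples")
  lens <- vapply(S, length, 0L)
  if (length(unique(lens)) != 1L) stop("training vectors have inconsistent lengths")
  grab <- function(ch) vapply(S, function(v) as.vector(as_qarr(v)[[ch]]), numeric(lens[1L]))
  qarr(grab("a"), grab("b"), grab("c"), grab("d"))
}

#' @export
print.qpca <- function(x, ...) {
  cat("Quaternion PCA model: ", x$m, " pixels, ", x$n_train, " training samples\n",
      "  components kept: ", x$n_components, " (energy ratio ", x$ratio, ")\n", sep = "")
  invisible(x)
}

#' Project a sample onto the quaternion principal components
#'
#' Computes the global feature \eqn{f = \hat P^{T*}(s - \bar s)}. The
#' training mean is subtracted by default, consistent with the centering
#' used in fitting; a common offset cancels in feature distances, so
#' matching is unaffected by the choice, but centered projections make the
#' zero feature correspond to the training mean. Set `center = FALSE` to
#' project the raw sample.
#' @param model a `qpca` model
#' @param s a length-m `qarr` vector
#' @param center subtract the training mean first (default TRUE)
#' @return a length-p `qarr` feature vector
#' @export
qpca_project <- function(model, s, center = TRUE) {
  s <- as_qarr(s)
  if (length(s) != length(model$mean)) stop("sample length does not match the model")
  if (center) s <- s - model$mean
  scol <- qarr(matrix(s$a), matrix(s$b), matrix(s$c), matrix(s$d))
  f <- q_matmul(q_ct(model$projection), scol)
  qarr(as.vector(f$a), as.vector(f$b), as.vector(f$c), as.vector(f$d))
}
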