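#' Quaternion arrays
#'
#' A `qarr` stores a quaternion-valued scalar, vector, matrix or image as
#' four parallel double-precision real arrays of identical shape: the scalar
#' part `a` and the coefficients `b`, `c`, `d` of the imaginary units
#' \eqn{i, j, k} (Hamilton's relations \eqn{i^2 = j^2 = k^2 = ijk = -1}).
#' The struct-of-arrays layout keeps all channel arithmetic vectorized.
#' Scalars are simply the length-1 case; there is no separate scalar type.
#'
#' @param a,b,c,d numeric arrays of a common shape (vectors, matrices or
#'   higher arrays). `b`, `c`, `d` default to zero and are recycled from a
#'   scalar 0 to the shape of `a`.
#' @return an object of class `qarr`.
#' @examples
#' q <- qarr(1, 2, 3, 4)
#' q_abs(q)            # sqrt(30)
#' q_mult(q_unit_i(), q_unit_j())  # k
#' @export
qarr <- function(a, b = 0, c = 0, d = 0) {
  a <- as_channel(a)
  b <- match_channel(b, a)
  c <- match_channel(c, a)
  d <- match_channel(d, a)
  structure(list(a = a, b = b, c = c, d = d), class = "qarr")
}

as_channel <- function(x) {
  if (is.matrix(x) || is.array(x)) storage.mode(x) <- "double" else x <- as.double(x)
  x
}

match_channel <- function(x, ref) {
  if (length(x) == 1L && is.null(dim(x))) {
    out <- ref
    out[] <- as.double(x)
    return(out)
  }
  x <- as_channel(x)
  if (!identical(dim(x), dim(ref)) || length(x) != length(ref))
    stop("quaternion channels must share one shape")
  x
}

#' Coerce a real array to a purely real quaternion array
#' @param x numeric vector, matrix or `qarr` (returned unchanged)
#' @return a `qarr`
#' @export
as_qarr <- function(x) {
  if (is_qarr(x)) return(x)
  qarr(x)
}

#' @rdname qarr
#' @param x object to test
#' @export
is_qarr <- function(x) inherits(x, "qarr")

#' @export
dim.qarr <- function(x) dim(x$a)

#' @export
length.qarr <- function(x) length(x$a)

#' @export
print.qarr <- function(x, ...) {
  dm <- dim(x)
  shape <- if (is.null(dm)) paste0("length ", length(x)) else paste(dm, collapse = " x ")
  cat("<qarr ", shape, ">\n", sep = "")
  if (length(x) <= 8L) {
    fmt <- sprintf("%.4g%+.4gi%+.4gj%+.4gk", x$a, x$b, x$c, x$d)
    print(if (is.null(dm)) fmt else matrix(fmt, dm[1L], dm[2L]))
  }
  invisible(x)
}

#' Subset a quaternion array
#'
#' Indexing applies identically to all four channels; matrix subsets keep
#' `drop = FALSE` semantics so shapes stay explicit.
#' @param x a `qarr`
#' @param i,j indices
#' @param ... unused
#' @export
`[.qarr` <- function(x, i, j, ...) {
  if (missing(j) && is.null(dim(x$a))) {
    qarr(x$a[i], x$b[i], x$c[i], x$d[i])
  } else if (missing(j)) {
    qarr(x$a[i, , drop = FALSE], x$b[i, , drop = FALSE],
         x$c[i, , drop = FALSE], x$d[i, , drop = FALSE])
  } else if (missing(i)) {
    qarr(x$a[, j, drop = FALSE], x$b[, j, drop = FALSE],
         x$c[, j, drop = FALSE], x$d[, j, drop = FALSE])
  } else {
    qarr(x$a[i, j, drop = FALSE], x$b[i, j, drop = FALSE],
         x$c[i, j, drop = FALSE], x$d[i, j, drop = FALSE])
  }
}

#' @export
`[<-.qarr` <- function(x, i, j, ..., value) {
  value <- as_qarr(value)
  for (ch in c("a", "b", "c", "d")) {
    if (missing(j) && is.null(dim(x$a))) x[[ch]][i] <- value[[ch]]
    else if (missing(j)) x[[ch]][i, ] <- value[[ch]]
    else if (missing(i)) x[[ch]][, j] <- value[[ch]]
    else x[[ch]][i, j] <- value[[ch]]
  }
  x
}

#' Elementwise quaternion arithmetic via the Ops group generic
#'
#' `+` and `-` are channel-wise; `*` is the elementwise (Hamilton,
#' noncommutative) product; `/` divides by a real array only. Mixed
#' real/quaternion operands are promoted.
#' @param e1,e2 `qarr` or numeric operands
#' @export
Ops.qarr <- function(e1, e2) {
  op <- .Generic
  if (missing(e2)) {
    if (op == "-") return(qarr(-e1$a, -e1$b, -e1$c, -e1$d))
    if (op == "+") return(e1)
    stop("unary '", op, "' not defined for qarr")
  }
  if (op == "/") {
    if (is_qarr(e2)) stop("division by a quaternion is not defined; multiply by the inverse explicitly")
    return(qarr(e1$a / e2, e1$b / e2, e1$c / e2, e1$d / e2))
  }
  if (op %in% c("+", "-")) {
    p <- as_qarr(e1); q <- as_qarr(e2)
    f <- get(op)
    return(qarr(f(p$a, q$a), f(p$b, q$b), f(p$c, q$c), f(p$d, q$d)))
  }
  if (op == "*") return(q_mult(e1, e2))
  stop("'", op, "' not defined for qarr")
}

#' Quaternion conjugate
#' @param q a `qarr`
#' @return `qarr` with negated imaginary channels
#' @export
q_conj <- function(q) {
  q <- as_qarr(q)
  qarr(q$a, -q$b, -q$c, -q$d)
}

#' Elementwise quaternion modulus
#'
#' \eqn{|q| = \sqrt{a^2 + b^2 + c^2 + d^2}}, the square root of
#' \eqn{q\,q^*}.
#' @param q a `qarr`
#' @return real array of the same shape
#' @export
q_abs <- function(q) {
  q <- as_qarr(q)
  sqrt(q$a^2 + q$b^2 + q$c^2 + q$d^2)
}

#' Elementwise Hamilton product
#'
#' Noncommutative: `q_mult(p, q)` is generally different from
#' `q_mult(q, p)`. A length-1 operand broadcasts over the other.
#' @param p,q `qarr` or numeric operands of a common shape (or length 1)
#' @return `qarr`
#' @export
q_mult <- function(p, q) {
  p <- as_qarr(p); q <- as_qarr(q)
  if (length(p) != length(q) && length(p) != 1L && length(q) != 1L)
    stop("shape mismatch in quaternion product")
  if (length(p) == 1L && !is.null(dim(p$a))) p <- qarr(p$a[1L], p$b[1L], p$c[1L], p$d[1L])
  if (length(q) == 1L && !is.null(dim(q$a))) q <- qarr(q$a[1L], q$b[1L], q$c[1L], q$d[1L])
  qarr(p$a * q$a - p$b * q$b - p$c * q$c - p$d * q$d,
       p$a * q$b + p$b * q$a + p$c * q$d - p$d * q$c,
       p$a * q$c - p$b * q$d + p$c * q$a + p$d * q$b,
       p$a * q$d + p$b * q$c - p$c * q$b + p$d * q$a)
}

#' Unit imaginary quaternions
#' @return length-1 `qarr`
#' @export
q_unit_i <- function() qarr(0, 1, 0, 0)
#' @rdname q_unit_i
#' @export
q_unit_j <- function() qarr(0, 0, 1, 0)
#' @rdname q_unit_i
#' @export
q_unit_k <- function() qarr(0, 0, 0, 1)

#' Zero and identity quaternion matrices
#' @param nrow,ncol dimensions (`q_zeros`); `n` for the identity
#' @export
q_zeros <- function(nrow, ncol = nrow) qarr(matrix(0, nrow, ncol))

#' @rdname q_zeros
#' @param n matrix order
#' @export
q_eye <- function(n) qarr(diag(n))

#' Conjugate transpose of a quaternion matrix
#'
#' \eqn{(M^{T*})_{uv} = (M_{vu})^*}; applying it twice returns the input.
#' @param M a 2-D `qarr`
#' @return the n x m conjugate transpose
#' @export
q_ct <- function(M) {
  M <- as_qarr(M)
  if (is.null(dim(M))) stop("conjugate transpose requires a 2-D quaternion array")
  qarr(t(M$a), -t(M$b), -t(M$c), -t(M$d))
}

#' Quaternion matrix product
#'
#' Entry (u, v) is the ordered sum of Hamilton products
#' \eqn{\sum_w A_{uw} B_{wv}}; factor order is preserved because quaternion
#' multiplication is noncommutative. Implemented as 16 real matrix products.
#' @param A,B 2-D `qarr`s with agreeing inner dimensions (plain numeric
#'   matrices are promoted)
#' @return the m x n quaternion product
#' @export
q_matmul <- function(A, B) {
  A <- as_qarr(A); B <- as_qarr(B)
  if (is.null(dim(A))) A <- qarr(matrix(A$a, 1L), matrix(A$b, 1L), matrix(A$c, 1L), matrix(A$d, 1L))
  if (is.null(dim(B))) B <- qarr(matrix(B$a), matrix(B$b), matrix(B$c), matrix(B$d))
  if (ncol(A$a) != nrow(B$a)) stop("inner dimensions do not agree")
  qarr(A$a %*% B$a - A$b %*% B$b - A$c %*% B$c - A$d %*% B$d,
       A$a %*% B$b + A$b %*% B$a + A$c %*% B$d - A$d %*% B$c,
       A$a %*% B$c - A$b %*% B$d + A$c %*% B$a + A$d %*% B$b,
       A$a %*% B$d + A$b %*% B$c - A$c %*% B$b + A$d %*% B$a)
}

#' Complex adjoint of a square quaternion matrix
#'
#' Writes each entry \eqn{a + bi + cj + dk} as the complex pair
#' \eqn{(z_1, z_2) = (a + bi,\, c + di)} and maps it to the 2 x 2 complex
#' block \eqn{[[z_1, z_2], [-\bar z_2, \bar z_1]]}, giving a 2n x 2n complex
#' matrix. The map is a ring homomorphism, so it serves as an independent
#' oracle for quaternion eigenproblems: a quaternion Hermitian matrix maps
#' to a complex Hermitian matrix whose real eigenvalues occur in pairs.
#' @param M a square 2-D `qarr`
#' @return a 2n x 2n complex matrix
#' @export
complex_adjoint <- function(M) {
  M <- as_qarr(M)
  dm <- dim(M)
  if (is.null(dm) || dm[1L] != dm[2L]) stop("complex adjoint requires a square quaternion matrix")
  n <- dm[1L]
  z1 <- M$a + 1i * M$b
  z2 <- M$c + 1i * M$d
  out <- matrix(0 + 0i, 2L * n, 2L * n)
  r1 <- 2L * seq_len(n) - 1L
  r2 <- 2L * seq_len(n)
  out[r1, r1] <- z1
  out[r1, r2] <- z2
  out[r2, r1] <- -Conj(z2)
  out[r2, r2] <- Conj(z1)
  out
}

#' Euclidean distance between quaternion vectors
#'
#' \eqn{d(p, q) = \sqrt{\sum_l |p_l - q_l|^2}} — identical to the Euclidean
#' distance between the two vectors viewed as 4L real coordinates.
#' @param p,q `qarr` vectors of equal length
#' @return a nonnegative scalar
#' @export
qvec_dist <- function(p, q) {
  p <- as_qarr(p); q <- as_qarr(q)
  if (length(p) != length(q)) stop("quaternion vectors must have equal length")
  sqrt(sum((p$a - q$a)^2 + (p$b - q$b)^2 + (p$c - q$c)^2 + (p$d - q$d)^2))
}

#' Norm of a quaternion vector
#' @param q a `qarr`
#' @return \eqn{\sqrt{\sum_l |q_l|^2}}
#' @export
qvec_norm <- function(q) {
  q <- as_qarr(q)
  sqrt(sum(q$a^2 + q$b^2 + q$c^2 + q$d^2))
}

#' Flatten a quaternion vector to 4L real coordinates
#'
#' Channel-major layout `c(a, b, c, d)`; used to hand feature sets to real
#' Euclidean distance machinery, which is exact for quaternion vectors.
#' @param q a `qarr`
#' @return numeric vector of length `4 * length(q)`
#' @export
q_flatten <- function(q) {
  q <- as_qarr(q)
  c(as.vector(q$a), as.vector(q$b), as.vector(q$c), as.vector(q$d))
}

#' Serialize a quaternion array as a four-slice real array
#'
#' The container stacks the channels along a trailing dimension in the
#' documented order (a, b, c, d); `qarr_from_container` inverts it. The
#' round trip is bit-exact.
#' @param q a `qarr`
#' @return a real array with one extra trailing dimension of extent 4
#' @export
qarr_to_container <- function(q) {
  q <- as_qarr(q)
  dm <- dim(q)
  base <- if (is.null(dm)) length(q) else dm
  arr <- array(c(q$a, q$b, q$c, q$d), dim = c(base, 4L))
  dimnames(arr) <- c(rep(list(NULL), length(base)), list(c("a", "b", "c", "d")))
  arr
}

#' @rdname qarr_to_container
#' @param arr an array produced by `qarr_to_container`
#' @export
qarr_from_container <- function(arr) {
  dm <- dim(arr)
  nd <- length(dm)
  if (dm[nd] != 4L) stop("container must have a trailing dimension of extent 4")
  idx <- function(k) {
    slice <- do.call(`[`, c(list(arr), rep(list(quote(expr = )), nd - 1L), list(k)))
    if (nd == 2L) as.double(slice) else slice
  }
  qarr(idx(1L), idx(2L), idx(3L), idx(4L))
}
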