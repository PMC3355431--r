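test_that("training centering removes the per-pixel mean", {
  S <- qarr(matrix(c(1, 3), 1, 2))
  ct <- center_training(S)
  expect_equal(ct$mean$a, 2)
  expect_equal(as.vector(ct$E$a), c(-1, 1))
  # identical columns -> E = 0
  S2 <- qarr(matrix(1, 4, 3), matrix(2, 4, 3), matrix(0, 4, 3), matrix(-1, 4, 3))
  expect_lt(max(q_abs(center_training(S2)$E)), 1e-15)
  set.seed(1)
  E <- center_training(rand_qarr(10, 6))$E
  for (ch in c("a", "b", "c", "d"))
    expect_lt(max(abs(rowMeans(E[[ch]]))), 1e-10)
  expect_error(center_training(qarr(matrix(1, 3, 1))), "at least 2")
})

test_that("small covariance is Hermitian and matches the real case", {
  E0 <- qarr(matrix(0, 5, 4))
  expect_lt(max(q_abs(small_covariance(E0))), 1e-15)
  set.seed(2)
  E <- center_training(rand_qarr(12, 5))$E
  C <- small_covariance(E)
  expect_lt(max(q_abs(C - q_ct(C))), 1e-10)
  # purely real input reproduces the direct real computation: columns are
  # samples, rows are pixels, centering is per pixel across the samples
  X <- matrix(rnorm(40), 8, 5)
  Xc <- X - rowMeans(X)
  Creal <- small_covariance(center_training(as_qarr(X))$E)
  expect_equal(Creal$a, crossprod(Xc) / (ncol(X) - 1), tolerance = 1e-12)
  expect_lt(max(abs(Creal$b), abs(Creal$c), abs(Creal$d)), 1e-15)
})

test_that("Householder tridiagonalization matches hand-checked small cases", {
  one <- householder_tridiagonalize(qarr(matrix(5)))
  expect_equal(one$B, matrix(5, 1, 1))
  expect_equal(one$P$a, matrix(1, 1, 1))
  # [[2, i], [-i, 3]]: off-diagonal becomes |i| = 1, eigenvalues preserved
  C2 <- qarr(matrix(c(2, 0, 0, 3), 2, 2), matrix(c(0, -1, 1, 0), 2, 2))
  h2 <- householder_tridiagonalize(C2)
  expect_equal(h2$B, matrix(c(2, 1, 1, 3), 2, 2), tolerance = 1e-12)
  expect_equal(eigen(h2$B, symmetric = TRUE)$values, adjoint_eigenvalues(C2),
               tolerance = 1e-10)
  expect_error(householder_tridiagonalize(rand_qarr(3, 3)), "Hermitian")
})

test_that("tridiagonal factorization reconstructs, stays unitary and matches the adjoint oracle", {
  set.seed(3)
  for (n in c(2, 5, 8)) {
    H <- rand_hermitian(n)
    hh <- householder_tridiagonalize(H)
    expect_true(all(hh$B[abs(row(hh$B) - col(hh$B)) > 1] == 0))
    expect_true(all(hh$B[abs(row(hh$B) - col(hh$B)) == 1] >= 0))
    expect_lt(max(q_abs(q_matmul(q_ct(hh$P), hh$P) - q_eye(n))), 1e-8)
    rec <- q_matmul(q_ct(hh$P), q_matmul(as_qarr(hh$B), hh$P))
    expect_lt(max(q_abs(rec - H)), 1e-8)
    expect_equal(eigen(hh$B, symmetric = TRUE)$values, adjoint_eigenvalues(H),
                 tolerance = 1e-8)
  }
})

test_that("eigen-lifting satisfies the small-problem eigen equation", {
  set.seed(4)
  E <- center_training(rand_qarr(30, 6))$E
  C <- small_covariance(E)
  hh <- householder_tridiagonalize(C)
  eg <- eig_from_tridiagonal(hh$B, hh$P, E)
  expect_true(all(diff(eg$D) <= 1e-12))  # descending
  # C V_C = V_C diag(D_C)
  lhs <- q_matmul(C, eg$V_C)
  rhs <- eg$V_C
  for (ch in c("a", "b", "c", "d")) rhs[[ch]] <- sweep(rhs[[ch]], 2, eg$D_C, `*`)
  expect_lt(max(q_abs(lhs - rhs)), 1e-8)
  # pixel-space columns are unit norm (nondegenerate spectrum here)
  nz <- eg$D_C > 1e-10
  nrm <- sqrt(colSums(eg$V$a^2 + eg$V$b^2 + eg$V$c^2 + eg$V$d^2))
  expect_equal(nrm[nz], rep(1, sum(nz)), tolerance = 1e-10)
  # spectrum rescaling is the uniform (n-1)/(m-1) factor
  expect_equal(eg$D, eg$D_C * 5 / 29, tolerance = 1e-14)
})

test_that("energy-ratio component selection follows the cumulative spectrum", {
  expect_equal(select_components(c(9, 1), 0.90), 1)
  expect_equal(select_components(c(5, 3, 2), 0.90), 3)  # 5+3 = 80% < 90%
  expect_equal(select_components(c(5, 3, 2, 0), 1.0), 3)
  expect_error(select_components(c(0, 0), 0.9), "degenerate")
  expect_error(select_components(c(3, 1), 1.5), "ratio")
  # nondecreasing in the ratio
  set.seed(5)
  D <- sort(rexp(10), decreasing = TRUE)
  ps <- vapply(seq(0.1, 1, by = 0.1), function(r) select_components(D, r), 0L)
  expect_true(all(diff(ps) >= 0))
})

test_that("fitting and projection follow the model contract", {
  set.seed(6)
  S <- rand_qarr(40, 8)
  model <- fit_qpca(S)
  expect_equal(model$ratio, 0.9)
  expect_true(model$n_components >= 1 && model$n_components <= 8)
  # projection columns are unit norm
  P <- model$projection
  expect_equal(sqrt(colSums(P$a^2 + P$b^2 + P$c^2 + P$d^2)),
               rep(1, model$n_components), tolerance = 1e-10)
  # the training mean projects to the zero feature
  f0 <- qpca_project(model, model$mean)
  expect_lt(qvec_norm(f0), 1e-10)
  expect_equal(length(qpca_project(model, S[, 1])), model$n_components)
  expect_error(qpca_project(model, rand_qarr(10)), "length")
  # two samples -> rank 1 -> a single component at any ratio
  m2 <- fit_qpca(rand_qarr(20, 2), ratio = 1.0)
  expect_equal(m2$n_components, 1)
  # identical samples -> zero-variance spectrum is an explicit error
  same <- rand_qarr(15)
  expect_error(fit_qpca(list(same, same, same)), "degenerate")
})

test_that("full-energy projection is an isometry on centered training data", {
  set.seed(7)
  n <- 12
  S <- rand_qarr(60, n)
  model <- fit_qpca(S, ratio = 1.0)
  feats <- lapply(seq_len(n), function(i) qpca_project(model, S[, i]))
  ct <- center_training(S)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    din <- qvec_dist(ct$E[, i], ct$E[, j])
    dft <- qvec_dist(feats[[i]], feats[[j]])
    expect_equal(dft, din, tolerance = 1e-6)
  }
})

test_that("feature distances ignore per-column unit-quaternion phases", {
  set.seed(8)
  S <- rand_qarr(30, 5)
  model <- fit_qpca(S, ratio = 1.0)
  # right-multiply one projection column by a random unit quaternion
  u <- rand_qarr(1); u <- u / q_abs(u)
  twisted <- model
  col1 <- twisted$projection[, 1]
  twisted$projection[, 1] <- q_mult(col1, u)
  s1 <- S[, 2]; s2 <- S[, 4]
  d0 <- qvec_dist(qpca_project(model, s1), qpca_project(model, s2))
  d1 <- qvec_dist(qpca_project(twisted, s1), qpca_project(twisted, s2))
  expect_equal(d1, d0, tolerance = 1e-10)
})
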