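# random quaternion fixtures, built in code at test time

rand_qarr <- function(n, m = NULL) {
  draw <- function() if (is.null(m)) stats::rnorm(n) else matrix(stats::rnorm(n * m), n, m)
  qarr(draw(), draw(), draw(), draw())
}

rand_hermitian <- function(n) {
  A <- rand_qarr(n, n)
  (A + q_ct(A)) / 2
}

# eigenvalues of a quaternion Hermitian matrix through the complex adjoint
# oracle: real, doubled multiplicity collapsed, descending
adjoint_eigenvalues <- function(H) {
  ev <- eigen(complex_adjoint(H), only.values = TRUE)$values
  ev <- sort(Re(ev), decreasing = TRUE)
  ev[seq(1L, length(ev), by = 2L)]
}

# a small easy-regime gallery/probe pair shared by a few tests: light
# session variation, low noise, small shift
easy_dataset <- function(n_classes = 5, seed = 42) {
  cfg <- synth_config(n_classes = n_classes, instances_per_class = 4,
                      image_size = 64, max_shift = 1, noise_sd = 0.01,
                      session_sd = 0.3, seed = seed)
  generate_dataset(cfg)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
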