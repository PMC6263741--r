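# Shared fixture builders. Everything is generated in code at test time.

# circular complex Gaussian matrix with E|n|^2 = sigma^2 per entry
rcnorm_mat <- function(rows, cols, sigma = 1) {
  (matrix(stats::rnorm(rows * cols), rows) +
     1i * matrix(stats::rnorm(rows * cols), rows)) * sigma / sqrt(2)
}

# random unit-norm complex dictionary (w2 x k)
random_dictionary <- function(w, k, seed = 1) {
  withr::local_seed(seed)
  A <- rcnorm_mat(w^2, k)
  nrm <- sqrt(colSums(Mod(A)^2))
  new_dictionary(sweep(A, 2, nrm, "/"), w)
}

# orthonormal complex dictionary from a QR factorization (k <= w2)
orthonormal_dictionary <- function(w, k, seed = 1) {
  withr::local_seed(seed)
  A <- rcnorm_mat(w^2, max(k, 2))
  Q <- qr.Q(qr(A))[, seq_len(k), drop = FALSE]
  new_dictionary(Q, w)
}

# plain reference OMP in R, independent of the compiled path: explicit
# residual, pseudo-inverse refit via qr.solve
reference_omp <- function(patch, D, delta, max_atoms) {
  r <- patch
  Q <- integer(0)
  alpha <- complex(0)
  while (Re(sum(Conj(r) * r)) > delta && length(Q) < max_atoms) {
    corr <- abs(Conj(t(D)) %*% r)
    j <- which(corr == max(corr))[1]
    if (j %in% Q) break
    Q <- c(Q, j)
    alpha <- qr.solve(D[, Q, drop = FALSE], patch)
    r <- patch - D[, Q, drop = FALSE] %*% alpha
  }
  list(support = Q, coefficients = alpha,
       residual_norm2 = Re(sum(Conj(r) * r)))
}

# tiny phase-only scene for solver tests
small_scene <- function(size = c(32, 32), kind = "gaussian", peak = 12) {
  psi <- make_phase_surface(kind, size, peak = peak)
  complex_scene(matrix(1, size[1], size[2]), psi)
}

# dense unitary 2-D DFT matrix acting on column-major vectorized images
dense_dft2 <- function(rows, cols) {
  Fm <- function(m) {
    w <- exp(-2i * pi / m)
    outer(0:(m - 1), 0:(m - 1), function(a, b) w^(a * b)) / sqrt(m)
  }
  kronecker(Fm(cols), Fm(rows))  # vec(F_r X F_c^T) = (F_c %x% F_r) vec(X)
}
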