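test_that("quaternary masks are reproducible draws from the 4-phase alphabet", {
  m <- generate_masks(3, c(16, 20), seed = 9)
  expect_identical(dim(m$phases), c(16L, 20L, 3L))
  expect_true(all(m$phases %in% c(0, pi / 2, -pi / 2, pi)))
  expect_equal(Mod(exp(1i * m$phases)), array(1, dim(m$phases)), tolerance = 1e-12)
  # all four symbols occur equiprobably (chi-squared goodness of fit)
  tab <- table(generate_masks(8, c(32, 32), seed = 9)$phases)
  expect_length(tab, 4)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
  expect_identical(generate_masks(3, c(16, 20), seed = 9), m)
  expect_false(identical(generate_masks(3, c(16, 20), seed = 10)$phases, m$phases))
  expect_error(generate_masks(0, c(8, 8)), "S")
})

test_that("propagation is unitary and inverted by backpropagation", {
  withr::local_seed(2)
  m <- generate_masks(1, c(17, 13), seed = 2)
  ph <- m$phases[, , 1]
  for (i in 1:5) {
    x <- rcnorm_mat(17, 13)
    u <- propagate(x, ph)
    expect_equal(sum(Mod(u)^2), sum(Mod(x)^2), tolerance = 1e-10)   # Parseval
    expect_equal(backpropagate(u, ph), x, tolerance = 1e-12)        # A^H A = I
  }
  # constant field through a zero-phase mask concentrates at the DC bin
  xc <- matrix(3 + 0i, 8, 8)
  u <- propagate(xc, matrix(0, 8, 8))
  expect_equal(Mod(u[1, 1]), sqrt(64) * 3, tolerance = 1e-10)
  expect_lt(max(Mod(u[-1])), 1e-10)
  expect_error(propagate(xc, matrix(0, 4, 4)), "shape")
})

test_that("observation models match their distributions", {
  sc <- small_scene(c(12, 12))
  m <- generate_masks(2, c(12, 12), seed = 3)

  nl <- observe(sc$field, m, "noiseless")
  y <- nl$z
  expect_true(all(y >= 0))
  expect_equal(sum(y), 2 * sum(Mod(sc$field)^2), tolerance = 1e-8)

  g0 <- observe(sc$field, m, "gaussian", sigma = 0, seed = 1)
  expect_equal(g0$z, y, tolerance = 1e-12)
  g <- observe(sc$field, m, "gaussian", sigma = 0.5, seed = 1)
  expect_false(all(g$z >= 0))  # negatives retained, not clipped

  p <- observe(sc$field, m, "poisson", chi = 2, seed = 1)
  expect_true(all(p$z >= 0))
  expect_equal(p$z, round(p$z))  # counts
  expect_identical(observe(sc$field, m, "poisson", chi = 2, seed = 1)$z, p$z)
  expect_error(observe(sc$field, m, "poisson", chi = 0), "chi")

  # mean identity: mean(z)/chi estimates y, pooled over pixels and repeats
  chi <- 5
  reps <- 200
  acc <- 0
  for (r in seq_len(reps))
    acc <- acc + observe(sc$field, m, "poisson", chi = chi, seed = 1000 + r)$z
  zbar <- acc / reps / chi
  se <- sqrt(y / chi / reps)  # per-pixel standard error of zbar
  frac_in <- mean(abs(zbar - y) <= 3 * pmax(se, 1e-12) + 1e-9)
  expect_gt(frac_in, 0.98)
  # Poisson variance tracks the mean where the clean intensity is constant:
  # a unit impulse object has an exactly flat spectrum
  xi <- matrix(0i, 16, 16); xi[5, 9] <- 4
  mi <- generate_masks(2, c(16, 16), seed = 6)
  zi <- observe(xi, mi, "poisson", chi = 40, seed = 2)$z  # lambda = 2.5 each
  expect_equal(var(as.vector(zi)), mean(zi), tolerance = 0.2)
})

test_that("global SNR follows the closed form and its invariances", {
  # unit impulse object: |A_s x|^2 is exactly uniform 1/n
  x <- matrix(0i, 10, 10); x[4, 7] <- 2
  m <- generate_masks(3, c(10, 10), seed = 4)
  chi <- 50
  expect_equal(snr_global(x, m, chi), 10 * log10(chi * 4 / 100), tolerance = 1e-10)
  # doubling chi adds 10 log10(2) dB
  expect_equal(snr_global(x, m, 2 * chi) - snr_global(x, m, chi),
               10 * log10(2), tolerance = 1e-10)
  # invariant under a global phase rotation of the object
  sc <- small_scene(c(16, 16))
  m2 <- generate_masks(4, c(16, 16), seed = 5)
  expect_equal(snr_global(sc$field * exp(1.3i), m2, 7),
               snr_global(sc$field, m2, 7), tolerance = 1e-10)
  expect_error(snr_global(matrix(0i, 8, 8), generate_masks(2, c(8, 8)), 1), "zero")
})

test_that("the conventional photon scaling maps to the unitary scale by n", {
  # chi = 1e-5 on a 100x100 unit-amplitude scene is the -7 dB photon regime
  expect_equal(chi_effective(1e-5, c(100, 100)), 0.1)
  sc <- small_scene(c(100, 100), kind = "truncated_gaussian")
  m <- generate_masks(12, c(100, 100), seed = 1)
  snr <- snr_global(sc$field, m, chi_effective(1e-5, c(100, 100)))
  expect_equal(snr, -7, tolerance = 0.3)
})

test_that("observation container round trips", {
  sc <- small_scene(c(12, 12))
  m <- generate_masks(2, c(12, 12), seed = 3)
  obs <- observe(sc$field, m, "poisson", chi = 3, seed = 8)
  f <- withr::local_tempfile(fileext = ".rds")
  write_observations(obs, m, f)
  back <- read_observations(f)
  expect_identical(back$observations$z, obs$z)
  expect_identical(back$masks$phases, m$phases)
})
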