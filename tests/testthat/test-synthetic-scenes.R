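test_that("phase surface families have their defining shapes", {
  size <- c(41, 41)  # odd: the grid centre is a pixel, where the peak sits
  g <- make_phase_surface("gaussian", size, peak = 7)
  expect_equal(max(g), 7, tolerance = 1e-10)
  expect_equal(unname(which(g == max(g), arr.ind = TRUE)[1, ]), c(21, 21))

  sp <- make_phase_surface("shear_plane", size, peak = 7)
  d2r <- diff(diff(sp))          # second differences along rows
  d2c <- t(diff(diff(t(sp))))    # and columns
  expect_lt(max(abs(d2r)), 1e-12)
  expect_lt(max(abs(d2c)), 1e-12)

  q <- make_phase_surface("quadratic", size, peak = 7)
  expect_equal(max(q), 7, tolerance = 1e-6)
  d2q <- diff(diff(q))
  expect_lt(diff(range(d2q)), 1e-12)  # constant curvature

  m1 <- make_phase_surface("mountain", size, peak = 7, seed = 5)
  m2 <- make_phase_surface("mountain", size, peak = 7, seed = 5)
  expect_identical(m1, m2)  # seeded, bit-reproducible
  expect_false(identical(m1, make_phase_surface("mountain", size, peak = 7, seed = 6)))
  expect_equal(range(m1), c(0, 7), tolerance = 1e-10)

  expect_error(make_phase_surface("volcano", size), "arg")
})

test_that("octant truncation zeroes exactly the even-indexed octants", {
  size <- c(41, 41)
  g <- make_phase_surface("gaussian", size, peak = 12)
  tg <- make_phase_surface("truncated_gaussian", size, peak = 12)
  # independent octant computation about the grid centre
  u <- outer(rep(1, 41), (1:41) - 21)
  v <- outer((1:41) - 21, rep(1, 41))
  oct <- floor((atan2(v, u) %% (2 * pi)) / (pi / 4)) %% 8
  removed <- oct %% 2 == 0
  expect_true(all(tg[removed] == 0))
  expect_identical(tg[!removed], g[!removed])
})

test_that("amplitude coupling groups follow their formulas", {
  psi <- make_phase_surface("gaussian", c(24, 24), peak = 6)
  a1 <- couple_amplitude(psi, 1)
  expect_true(all(a1 == 1))

  ind <- matrix(seq(-1, 2, length.out = 576), 24)
  a2 <- couple_amplitude(psi, 2, independent_amplitude = ind)
  expect_true(all(a2 > 0))
  expect_equal(diff(range(a2)), diff(range(ind)))  # shift only

  a3 <- couple_amplitude(psi, 3, k0 = 1, k1 = 1)
  expect_equal(a3[which.max(abs(psi))], 2)  # k0 + k1 at the |psi| maximizer
  # monotone in |psi|: sorting by |psi| sorts amplitude
  ord <- order(abs(psi))
  expect_true(all(diff(a3[ord]) >= -1e-12))

  # psi = 0 -> 1 + |cos 0| = 2: truncated surface has exact zeros
  tg <- make_phase_surface("truncated_gaussian", c(25, 25), peak = 6)
  a4t <- couple_amplitude(tg, 4, k0 = 1, k1 = 1)
  expect_true(all(a4t[tg == 0] == 2))

  expect_error(couple_amplitude(psi, 2), "independent_amplitude")
  expect_error(couple_amplitude(matrix(0, 4, 4), 3), "degenerate")
  expect_error(couple_amplitude(psi, 5), "group")
})

test_that("the nine-scene suite has the documented pairings and invariants", {
  suite <- make_test_suite(c(32, 32), peak = 12, seed = 3)
  expect_length(suite, 9)
  expect_identical(vapply(suite, function(s) s$group, integer(1)),
                   c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L))
  # row 1: constant amplitude, truncated-Gaussian phase (has zeroed octants)
  expect_true(all(suite[[1]]$amplitude == 1))
  expect_gt(mean(suite[[1]]$phase == 0), 0.3)
  # row 3: mountain amplitude on a shear-plane phase, strictly positive
  expect_gt(diff(range(suite[[3]]$amplitude)), 0.5)
  expect_true(all(suite[[3]]$amplitude > 0))
  for (s in suite) {
    expect_equal(s$field, s$amplitude * exp(1i * s$phase))
    expect_equal(Mod(s$field), s$amplitude, tolerance = 1e-12)
    expect_equal(Arg(s$field), wrap_phase(s$phase), tolerance = 1e-12)
  }
  # reproducibility of the whole suite
  suite2 <- make_test_suite(c(32, 32), peak = 12, seed = 3)
  expect_identical(suite, suite2)
})

test_that("prior training scenes cover the full surface and its quadrants", {
  pr <- gaussian_prior_scenes(c(31, 31), peak = 12)
  expect_length(pr, 5)
  g <- pr[[1]]$phase
  expect_equal(max(g), 12, tolerance = 1e-10)
  quarters <- Reduce(`+`, lapply(pr[2:5], function(s) s$phase))
  expect_equal(quarters, g)  # the four quadrant cuts tile the full surface
  for (s in pr) expect_true(all(s$amplitude == 1))
})

test_that("scene TIFF round trip preserves amplitude and phase", {
  sc <- complex_scene(matrix(runif(400, 0.5, 2.5), 20),
                      make_phase_surface("gaussian", c(20, 20), peak = 9))
  f <- withr::local_tempfile(fileext = ".tif")
  save_scene(sc, f, meta = list(kind = "gaussian", peak = 9, seed = 1))
  sc2 <- load_scene(f)
  expect_equal(sc2$amplitude, sc$amplitude, tolerance = 1e-6)
  expect_equal(sc2$phase, sc$phase, tolerance = 1e-6)
  meta <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_identical(meta$kind, "gaussian")
})
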