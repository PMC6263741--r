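# scalar objectives the sensor updates are proximity operators of
poisson_obj <- function(b, v, z, gamma, chi)
  b^2 * chi - z * log(pmax(b^2 * chi, 1e-300)) + (b - Mod(v))^2 / gamma
gaussian_obj <- function(b, v, z, gamma, sigma)
  (b^2 - z)^2 / sigma^2 + (b - Mod(v))^2 / gamma

test_that("the Poisson sensor update matches its closed form and limits", {
  # hand case: v = 2, z = 4, gamma = chi = 1 -> b = (2 + sqrt(36)) / 4 = 2
  u <- sensor_update_poisson(2 + 0i, 4, 1, 1)
  expect_equal(Mod(u), 2, tolerance = 1e-12)
  # gamma -> 0 collapses to |v|
  expect_equal(Mod(sensor_update_poisson(3i, 7, 1e-12, 1)), 3, tolerance = 1e-6)
  # chi -> infinity with exact counts gives the magnitude root sqrt(z/chi)
  chi <- 1e8; y <- 2.37
  u2 <- sensor_update_poisson(1 + 1i, y * chi, 1, chi)
  expect_equal(Mod(u2), sqrt(y), tolerance = 1e-3)
  # phase of v is always retained; dark pixels shrink but keep phase
  v <- 0.8 * exp(0.9i)
  u3 <- sensor_update_poisson(v, 0, 2, 3)
  expect_equal(Arg(u3), 0.9, tolerance = 1e-12)
  expect_error(sensor_update_poisson(v, -1, 1, 1), "nonnegative")
})

test_that("the noiseless sensor update replaces magnitudes exactly", {
  expect_equal(sensor_update_noiseless(1i, 4), 2i, tolerance = 1e-12)
  expect_equal(sensor_update_noiseless(0.5 + 0i, 0), 0 + 0i)
  v <- 2 * exp(0.3i)
  expect_equal(sensor_update_noiseless(v, 4), 2 * exp(0.3i), tolerance = 1e-12)
  expect_error(sensor_update_noiseless(1i, -1), "nonnegative")
})

test_that("the Gaussian Cardan update solves its cubic and limits", {
  # gamma -> 0: b -> |v|
  expect_equal(Mod(sensor_update_gaussian(2 - 1i, 3, 1e-12, 1)), sqrt(5),
               tolerance = 1e-6)
  # penalty -> 0 (sigma^2/(2 gamma) tiny), z = 9: b -> 3
  expect_equal(Mod(sensor_update_gaussian(1 + 0i, 9, 1e12, 1)), 3, tolerance = 1e-5)
  # sigma^2/(2 gamma) = 1, z = 2, |v| = 3: b solves b^3 - b - 3 = 0
  u <- sensor_update_gaussian(3 + 0i, 2, 0.5, 1)
  b <- Mod(u)
  expect_lt(abs(b^3 - b - 3), 1e-9)
  # and that root is the scalar objective's minimizer on a fine grid
  grid <- seq(0, 6, length.out = 20001)
  expect_lte(gaussian_obj(b, 3, 2, 0.5, 1), min(gaussian_obj(grid, 3, 2, 0.5, 1)) + 1e-8)
  # negative observations are legal
  un <- sensor_update_gaussian(1 + 1i, -2, 1, 1)
  expect_true(is.finite(Mod(un)) && Mod(un) >= 0)
  # v = 0 with C >= 0 gives b = 0
  expect_equal(Mod(sensor_update_gaussian(0 + 0i, 0.1, 1, 1)), 0)
})

test_that("both proximal updates beat a grid search on random scalars", {
  withr::local_seed(42)
  grid01 <- seq(0, 1, length.out = 5000)
  for (i in 1:40) {
    v <- rcnorm_mat(1, 1)[1, 1] * 2
    z <- rpois(1, 2); gamma <- runif(1, 0.05, 20); chi <- runif(1, 0.05, 5)
    b <- Mod(sensor_update_poisson(v, z, gamma, chi))
    bmax <- 2 * (Mod(v) + sqrt(max(z / chi, 1)) + 1)
    expect_lte(poisson_obj(b, v, z, gamma, chi),
               min(poisson_obj(grid01 * bmax, v, z, gamma, chi)) + 1e-6)
    zg <- rnorm(1, 2, 2); sigma <- runif(1, 0.1, 3)
    bg <- Mod(sensor_update_gaussian(v, zg, gamma, sigma))
    bmaxg <- 2 * (Mod(v) + sqrt(abs(zg)) + 1)
    expect_lte(gaussian_obj(bg, v, zg, gamma, sigma),
               min(gaussian_obj(grid01 * bmaxg, v, zg, gamma, sigma)) + 1e-6)
  }
})

test_that("the object update solves the normal equations exactly", {
  withr::local_seed(9)
  rows <- 8; cols <- 8; n <- rows * cols; S <- 3; w <- 3
  F2 <- dense_dft2(rows, cols)
  for (rep in 1:3) {
    masks <- generate_masks(S, c(rows, cols), seed = 200 + rep)
    grid <- patch_grid(c(rows, cols), w)
    mu <- multiplicity_map(grid)
    us <- array(rcnorm_mat(rows, cols * S), dim = c(rows, cols, S))
    patch_sum <- rcnorm_mat(rows, cols)
    gamma <- runif(1, 0.5, 5); beta <- runif(1, 0.01, 1)
    x <- object_update(us, masks, patch_sum, mu, gamma, beta)
    # dense oracle: assemble sum A^H A/(bg) + sum R^H R and the RHS
    bg <- beta * gamma
    lhs <- diag(as.vector(mu)) + 0i
    rhs <- as.vector(patch_sum) + 0i
    for (s in seq_len(S)) {
      As <- F2 %*% diag(as.vector(exp(1i * masks$phases[, , s])))
      lhs <- lhs + Conj(t(As)) %*% As / bg
      rhs <- rhs + Conj(t(As)) %*% as.vector(us[, , s]) / bg
    }
    resid <- lhs %*% as.vector(x) - rhs
    expect_lt(sqrt(sum(Mod(resid)^2)) / sqrt(sum(Mod(rhs)^2)), 1e-10)
  }
  # limits: no patch contribution and mu = 0 -> mean backprojection
  masks <- generate_masks(S, c(rows, cols), seed = 7)
  us <- array(rcnorm_mat(rows, cols * S), dim = c(rows, cols, S))
  bp <- matrix(0i, rows, cols)
  for (s in seq_len(S)) bp <- bp + backpropagate(us[, , s], masks$phases[, , s])
  x0 <- object_update(us, masks, matrix(0i, rows, cols), matrix(0, rows, cols),
                      gamma = 1, beta = 1e-12)
  expect_equal(x0, bp / S, tolerance = 1e-6)
})

test_that("the full solver runs, converges noiselessly, and validates inputs", {
  sc <- small_scene(c(32, 32), "truncated_gaussian")
  m <- generate_masks(12, c(32, 32), seed = 5)
  obs <- observe(sc$field, m, "noiseless")
  cfg <- dlpr_config("noiseless", "gsf", iterations = 60, seed = 1)
  fit <- dlpr(obs, m, cfg, truth = sc)
  expect_s3_class(fit, "dlpr_result")
  expect_equal(nrow(fit$history), 60)
  expect_lt(tail(fit$history$rmse, 1), 1e-2)
  # objective is monitored and non-increasing in nearly every step
  dobj <- diff(fit$history$objective)
  expect_gte(mean(dobj <= 1e-8 * abs(fit$history$objective[-1]) + 1e-12), 0.95)
  # mode mismatch and missing prior are rejected
  expect_error(dlpr(obs, m, dlpr_config("poisson", "gsf", chi = 1)), "mode")
  expect_error(dlpr(obs, m, dlpr_config("noiseless", "prior_plugged")), "prior")
})

test_that("solver variants only differ in the object-plane step", {
  sc <- small_scene(c(24, 24))
  m <- generate_masks(6, c(24, 24), seed = 3)
  obs <- observe(sc$field, m, "poisson", chi = 5, seed = 4)
  # a gsf run and a dlpr run share the identical first backprojection:
  # with a single iteration and the patch model disabled by an enormous
  # sensor weight, the two estimates coincide
  cfg_g <- dlpr_config("poisson", "gsf", chi = 5, iterations = 1, seed = 1)
  cfg_d <- dlpr_config("poisson", "dlpr", chi = 5, iterations = 1, seed = 1,
                       w = 6, k = 16, T_iters = 1, eta = 8,
                       beta = 1e-15)  # patch weight -> 0
  f_g <- dlpr(obs, m, cfg_g)
  f_d <- dlpr(obs, m, cfg_d)
  expect_equal(f_d$x, f_g$x, tolerance = 1e-9)
})

test_that("estimate writer produces a readable pair", {
  sc <- small_scene(c(16, 16))
  m <- generate_masks(4, c(16, 16), seed = 2)
  obs <- observe(sc$field, m, "noiseless")
  fit <- dlpr(obs, m, dlpr_config("noiseless", "gsf", iterations = 5, seed = 1))
  base <- withr::local_tempfile()
  write_estimate(fit, base)
  expect_true(file.exists(paste0(base, ".tif")))
  est <- readRDS(paste0(base, ".rds"))
  expect_equal(est$x, fit$x)
})
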