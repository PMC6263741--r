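#' Solver configuration
#'
#' Collects all hyperparameters of the phase-retrieval engine. Penalty
#' weights default to `gamma = n/chi`, `beta = chi/1000` for Poissonian
#' observations and `gamma = n*sigma^2/10`, `beta = 0.01/sigma^2` for
#' Gaussian observations, where `n` is the pixel count of the image; both
#' give `beta*gamma = n/1000`. With `n` pixels the unitary spectral samples
#' carry `1/n` of the conventional intensity unit, so `n/chi` is numerically
#' the familiar `1/chi` heuristic quoted on the conventional scale (e.g.
#' `1e5` for `chi = 1e-5` at 100 x 100). This calibration makes the sensor
#' proximal step a near-projection onto the observed magnitudes and gives
#' the patch sparse model the dominant weight in the object update, which is
#' the regime in which dictionary filtering pays off at heavy noise; see the
#' methods vignette for the analysis. Since `gamma` and `beta` depend on the
#' image size, `NULL` values are resolved when [dlpr()] sees the data.
#'
#' Other defaults: `S = 12` masks, `w = 10` patches at unit stride,
#' `mu = 0.96` coding quantile, 20 outer iterations, C-ODL parameters
#' `T_iters = 30`, `eta = 64`, `lambda = 0.11`, `k = 128`.
#'
#' @param mode observation model: `"poisson"`, `"gaussian"`, `"noiseless"`.
#' @param variant `"dlpr"` (in-loop dictionary learning), `"prior_plugged"`
#'   (fixed pre-trained dictionary), or `"gsf"` (sensor filtering only; no
#'   object-plane sparse model).
#' @param chi Poisson photon scaling (per unit intensity on the unitary
#'   scale; see [chi_effective()]).
#' @param sigma Gaussian intensity-noise standard deviation.
#' @param gamma,beta quadratic penalty weights; `NULL` (default) resolves
#'   per the calibration above once the image size is known.
#' @param init `"auto"` (flat field for noisy modes, spectral for
#'   noiseless), `"flat"` (unit field), or `"spectral"` (power iterations on
#'   the data-weighted normal operator). All choices are deterministic.
#' @param S number of masks.
#' @param w,stride patch size and stride.
#' @param iterations outer iterations (default 20).
#' @param lambda,T_iters,eta,k C-ODL parameters.
#' @param mu chi-squared quantile for the OMP tolerance.
#' @param max_atoms OMP support cap (default `min(w^2, 30)`).
#' @param seed integer seed for all solver-internal randomness.
#' @return object of class `dlpr_config`.
#' @export
dlpr_config <- function(mode = c("poisson", "gaussian", "noiseless"),
                        variant = c("dlpr", "prior_plugged", "gsf"),
                        chi = NULL, sigma = NULL,
                        gamma = NULL, beta = NULL,
                        init = c("auto", "flat", "spectral"),
                        S = 12L, w = 10L, stride = 1L,
                        iterations = 20L,
                        lambda = 0.11, T_iters = 30L, eta = 64L, k = 128L,
                        mu = 0.96, max_atoms = NULL, seed = 1L) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  init <- match.arg(init)
  if (mode == "poisson" && (is.null(chi) || chi <= 0))
    stop("poisson mode requires `chi` > 0", call. = FALSE)
  if (mode == "gaussian" && (is.null(sigma) || sigma <= 0))
    stop("gaussian mode requires `sigma` > 0", call. = FALSE)
  if (!is.null(gamma) && gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (!is.null(beta) && beta <= 0) stop("`beta` must be positive", call. = FALSE)
  if (mu <= 0 || mu >= 1) stop("`mu` must lie in (0, 1)", call. = FALSE)
  max_atoms <- as.integer(max_atoms %||% min(w^2, 30L))
  structure(list(mode = mode, variant = variant, chi = chi, sigma = sigma,
                 gamma = gamma, beta = beta, init = init, S = as.integer(S),
                 w = as.integer(w), stride = as.integer(stride),
                 iterations = as.integer(iterations), lambda = lambda,
                 T_iters = as.integer(T_iters), eta = as.integer(eta),
                 k = as.integer(k), mu = mu, max_atoms = max_atoms,
                 seed = as.integer(seed)),
            class = "dlpr_config")
}

# fill in size-dependent defaults; n = pixel count
resolve_config <- function(config, n) {
  # Noisy modes: beta*gamma = n/1000, making the sparse model the dominant
  # term of the object update. Noiseless: the magnitude data are exact, so
  # the sensor coupling dominates (beta*gamma = 1e-3) and the sparse model
  # acts only as a mild regularizer.
  gamma <- config$gamma %||% switch(config$mode,
    poisson = n / config$chi,
    gaussian = n * config$sigma^2 / 10,
    noiseless = 1
  )
  beta <- config$beta %||% switch(config$mode,
    poisson = config$chi / 1000,
    gaussian = 0.01 / config$sigma^2,
    noiseless = 1 / 1000
  )
  init <- if (config$init == "auto") {
    if (config$mode == "noiseless") "spectral" else "flat"
  } else config$init
  config$gamma <- gamma; config$beta <- beta; config$init <- init
  config
}

#' @export
print.dlpr_config <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "auto" else sprintf("%g", v)
  cat(sprintf("<dlpr_config> %s / %s: S=%d w=%d iters=%d gamma=%s beta=%s k=%d init=%s\n",
              x$mode, x$variant, x$S, x$w, x$iterations, fmt(x$gamma),
              fmt(x$beta), x$k, x$init))
  invisible(x)
}

#' Sensor-plane proximal update, Poissonian observations
#'
#' Elementwise proximity operator of the Poisson negative log-likelihood
#' `|u|^2 chi - z log(|u|^2 chi)` scaled by `gamma/2`: the phase of `v` is
#' kept and the magnitude becomes
#' `b = (|v| + sqrt(|v|^2 + 4 z gamma (1 + gamma chi))) / (2 (1 + gamma chi))`.
#'
#' @param v complex array (forward-propagated wavefront).
#' @param z nonnegative counts, same shape.
#' @param gamma penalty weight (> 0).
#' @param chi photon scaling (> 0).
#' @return complex array `u` with `angle(u) == angle(v)`.
#' @export
sensor_update_poisson <- function(v, z, gamma, chi) {
  if (gamma <= 0 || chi <= 0) stop("`gamma` and `chi` must be positive", call. = FALSE)
  if (any(z < 0)) stop("`z` must be nonnegative", call. = FALSE)
  av <- Mod(v)
  c1 <- 1 + gamma * chi
  b <- (av + sqrt(av^2 + 4 * z * gamma * c1)) / (2 * c1)
  b * exp(1i * Arg(v))
}

#' Sensor-plane update, noiseless observations
#'
#' Classical magnitude replacement: `u = sqrt(y) * exp(1i * angle(v))`. Where
#' `v = 0` the zero-phase convention gives `u = sqrt(y)`.
#'
#' @param v complex array.
#' @param y clean intensities (>= 0), same shape.
#' @return complex array.
#' @export
sensor_update_noiseless <- function(v, y) {
  if (any(y < 0)) stop("`y` must be nonnegative", call. = FALSE)
  sqrt(y) * exp(1i * Arg(v))
}

#' Sensor-plane proximal update, Gaussian observations
#'
#' Elementwise proximity operator of `(|u|^2 - z)^2 / sigma^2` scaled by
#' `gamma/2`: the magnitude `b` is the nonnegative root of the depressed
#' cubic `b^3 + C b + D = 0` with `C = sigma^2/(2 gamma) - z` and
#' `D = -sigma^2/(2 gamma) |v|` (the largest real root, which is the
#' objective minimizer; `b = 0` when `v = 0` and `C >= 0`). Solved in closed
#' form (Cardano / trigonometric branch) with a final Newton polish.
#'
#' @param v complex array.
#' @param z real observations (negative values allowed), same shape.
#' @param gamma penalty weight (> 0).
#' @param sigma noise standard deviation (> 0).
#' @return complex array `u` with the phase of `v`.
#' @export
sensor_update_gaussian <- function(v, z, gamma, sigma) {
  if (gamma <= 0 || sigma <= 0) stop("`gamma` and `sigma` must be positive", call. = FALSE)
  cpen <- sigma^2 / (2 * gamma)
  p <- cpen - z
  q <- -cpen * Mod(v)
  b <- cardan_largest_root(p, q)
  b * exp(1i * Arg(v))
}

# Largest real root of t^3 + p t + q = 0, vectorized; for the sensor update
# q <= 0, so the largest real root is the nonnegative minimizer.
cardan_largest_root <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  disc <- (q / 2)^2 + (p / 3)^3
  t <- numeric(length(p))
  one <- disc >= 0
  if (any(one)) {
    s <- sqrt(disc[one])
    cbrt <- function(x) sign(x) * abs(x)^(1 / 3)
    t[one] <- cbrt(-q[one] / 2 + s) + cbrt(-q[one] / 2 - s)
  }
  if (any(!one)) {
    pp <- p[!one]; qq <- q[!one]
    r <- sqrt(-pp / 3)
    arg <- pmin(pmax((3 * qq) / (2 * pp) * sqrt(-3 / pp), -1), 1)
    t[!one] <- 2 * r * cos(acos(arg) / 3)
  }
  # Newton polish (guarded); keeps accuracy uniform across branches
  for (i in 1:2) {
    f <- t^3 + p * t + q
    fp <- 3 * t^2 + p
    ok <- abs(fp) > 1e-12
    t[ok] <- t[ok] - f[ok] / fp[ok]
  }
  pmax(t, 0)
}

#' Object-plane least-squares update
#'
#' Exact minimizer of the quadratic coupling between the sensor-plane
#' estimates and the patch sparse model:
#' `x = [ (1/(beta gamma)) sum_s A_s^H u_s + sum_i R_i^H D alpha_i ] /
#'      [ S/(beta gamma) + mu_j ]` elementwise, where `mu_j` is the pixel
#' multiplicity. This solves the normal equations of
#' `min_x (1/gamma) sum_s ||u_s - A_s x||^2 + beta sum_i ||R_i x - D alpha_i||^2`
#' exactly, because `A_s^H A_s = I` (unitary propagation) and the patch
#' normal operator is diagonal.
#'
#' @param us `rows x cols x S` complex array of sensor-plane estimates.
#' @param masks the `mask_set`.
#' @param patch_sum complex image `sum_i R_i^H D alpha_i` (unnormalized patch
#'   back-placement; zero matrix if no sparse model).
#' @param mu pixel multiplicity matrix (see [multiplicity_map()]).
#' @param gamma,beta penalty weights.
#' @return complex image matrix.
#' @export
object_update <- function(us, masks, patch_sum, mu, gamma, beta) {
  stopifnot(inherits(masks, "mask_set"))
  S <- masks$S
  bg <- beta * gamma
  if (bg <= 0) stop("`beta * gamma` must be positive", call. = FALSE)
  acc <- matrix(0i, masks$shape[1], masks$shape[2])
  for (s in seq_len(S)) acc <- acc + backpropagate(us[, , s], mask_phase(masks, s))
  (acc / bg + patch_sum) / (S / bg + mu)
}

# Deterministic spectral initializer for coded diffraction patterns: the
# leading eigenvector of (1/S) sum_s A_s^H diag(yhat_s) A_s approximated by a
# fixed number of power iterations from an all-ones start (no randomness),
# rescaled so ||x||^2 matches the energy estimate mean_s sum(yhat_s).
spectral_init <- function(yhat, masks, power_iters = 30L) {
  shape <- masks$shape
  v <- matrix(1 + 0i, shape[1], shape[2])
  for (p in seq_len(power_iters)) {
    acc <- matrix(0i, shape[1], shape[2])
    for (s in seq_len(masks$S)) {
      ph <- mask_phase(masks, s)
      acc <- acc + backpropagate(yhat[, , s] * propagate(v, ph), ph)
    }
    nrm <- sqrt(sum(Mod(acc)^2))
    if (nrm == 0) return(v)  # degenerate (all-dark) data: keep flat field
    v <- acc / nrm
  }
  energy <- mean(apply(yhat, 3, sum))
  v * sqrt(energy)
}

# Eq.-style data-term value for monitoring (mode-specific likelihood part)
data_term <- function(us, z, mode, chi, sigma) {
  switch(mode,
    poisson = {
      i2 <- pmax(Mod(us)^2 * chi, 1e-300)
      sum(i2 - z * log(i2))
    },
    gaussian = sum((Mod(us)^2 - z)^2) / sigma^2,
    noiseless = 0
  )
}

#' Dictionary-learning phase retrieval
#'
#' The alternating-minimization engine. Each outer iteration: (1) forward
#' propagation `v_s = A_s x`; (2) sensor-plane proximal filtering (Poisson,
#' Gaussian, or exact magnitude replacement); (3) backprojection
#' `x_half = (1/S) sum_s A_s^H u_s`; (4) unless `variant = "gsf"`: estimate
#' the residual noise level of `x_half`, calibrate the OMP tolerance, update
#' the dictionary by online learning on patches of `x_half` (skipped for
#' `prior_plugged`, which uses the supplied dictionary), sparse-code all
#' patches; (5) combine sensor and patch information in the exact object
#' update ([object_update()]); `gsf` instead takes `x <- x_half`.
#'
#' Initialization is a deterministic spectral estimate: a fixed number of
#' power iterations (all-ones start) on the data-weighted normal operator
#' `(1/S) sum_s A_s^H diag(z_s/chi) A_s`, rescaled to the energy the
#' observations imply. The whole solve is reproducible: the only randomness
#' is the seeded batch sampling inside the dictionary-learning step.
#'
#' @param obs an `observation_set`.
#' @param masks the matching `mask_set`.
#' @param config a `dlpr_config` (its `mode` must match `obs$noise_model`).
#' @param prior a `dlpr_dictionary`; required when
#'   `config$variant == "prior_plugged"`.
#' @param truth optional `complex_scene`; when supplied, per-iteration
#'   wrapped-phase RMSE (after global phase alignment) is recorded.
#' @param verbose print per-iteration diagnostics to stderr.
#' @return object of class `dlpr_result`: list with `x` (complex estimate),
#'   `dictionary` (final `dlpr_dictionary` or `NULL` for gsf), and `history`
#'   (data frame: iteration, objective, sigma_x, delta, mean_atoms, rmse).
#' @export
dlpr <- function(obs, masks, config, prior = NULL, truth = NULL, verbose = FALSE) {
  stopifnot(inherits(obs, "observation_set"), inherits(masks, "mask_set"),
            inherits(config, "dlpr_config"))
  if (obs$noise_model != config$mode)
    stop("`config$mode` does not match the observation noise model", call. = FALSE)
  if (config$variant == "prior_plugged") {
    if (is.null(prior)) stop("prior_plugged variant requires `prior`", call. = FALSE)
    stopifnot(inherits(prior, "dlpr_dictionary"))
  }
  if (any(obs$shape != masks$shape) || obs$S != masks$S)
    stop("observations and masks disagree", call. = FALSE)
  shape <- masks$shape; S <- masks$S
  z <- obs$z
  config <- resolve_config(config, prod(shape))
  chi <- config$chi; sigma <- config$sigma
  gamma <- config$gamma; beta <- config$beta

  x <- if (config$init == "flat") {
    matrix(1 + 0i, shape[1], shape[2])
  } else {
    # spectral: power iterations on the data-weighted normal operator
    # (1/S) sum_s A_s^H diag(yhat_s) A_s from an all-ones start
    yhat <- switch(config$mode,
      poisson = pmax(z, 0) / chi,
      gaussian = pmax(z, 0),
      noiseless = pmax(z, 0)
    )
    spectral_init(yhat, masks)
  }

  use_patches <- config$variant != "gsf"
  if (use_patches) {
    grid <- patch_grid(shape, config$w, config$stride)
    mu_map <- multiplicity_map(grid)
  }
  D <- if (config$variant == "prior_plugged") prior else NULL
  cstate <- NULL

  hist <- data.frame(iteration = integer(), objective = numeric(),
                     sigma_x = numeric(), delta = numeric(),
                     mean_atoms = numeric(), rmse = numeric())
  truth_wrapped <- if (!is.null(truth)) wrap_phase(truth$phase) else NULL

  check_finite <- function(m, step, it) {
    if (any(!is.finite(Re(m))) || any(!is.finite(Im(m))))
      stop(sprintf("non-finite iterate at iteration %d, step '%s'", it, step),
           call. = FALSE)
  }

  vs <- us <- array(0i, dim = c(shape, S))
  for (it in seq_len(config$iterations)) {
    for (s in seq_len(S)) vs[, , s] <- propagate(x, mask_phase(masks, s))
    check_finite(vs, "forward propagation", it)
    us <- switch(config$mode,
      poisson = sensor_update_poisson(vs, z, gamma, chi),
      gaussian = sensor_update_gaussian(vs, z, gamma, sigma),
      noiseless = sensor_update_noiseless(vs, z)
    )
    check_finite(us, "sensor filtering", it)
    x_half <- matrix(0i, shape[1], shape[2])
    for (s in seq_len(S)) x_half <- x_half + backpropagate(us[, , s], mask_phase(masks, s))
    x_half <- x_half / S
    check_finite(x_half, "backprojection", it)

    sx <- NA_real_; delta <- NA_real_; mean_atoms <- NA_real_; patch_obj <- 0
    if (!use_patches) {
      x_new <- x_half
    } else {
      P <- extract_patches(x_half, grid)
      sx <- estimate_noise_std(x_half)
      delta <- omp_tolerance(sx, config$w, config$mu)
      if (config$variant == "dlpr") {
        fit <- codl(P, k = config$k, T_iters = config$T_iters, eta = config$eta,
                    lambda = config$lambda, seed = config$seed + it,
                    D_init = NULL, state = cstate, return_state = TRUE)
        D <- fit$dictionary; cstate <- fit$state
      }
      cp <- code_patches(P, D, delta, config$max_atoms, return_codes = FALSE)
      mean_atoms <- mean(cp$n_atoms)
      # a patch the coder declares unrepresentable (empty code) passes
      # through unfiltered: zeroing it would bleed energy out of the
      # iterate, and once enough patches go dark the backprojections
      # decohere and the solver traps itself in a dark state
      dead <- cp$n_atoms == 0L
      recon <- cp$reconstruction
      if (any(dead)) recon[, dead] <- P[, dead]
      patch_sum <- patch_backproject(recon, grid)
      x_new <- object_update(us, masks, patch_sum, mu_map, gamma, beta)
      check_finite(x_new, "object update", it)
      Pn <- extract_patches(x_new, grid)
      patch_obj <- beta * sum(Mod(Pn - recon)^2)
    }

    vres <- 0
    for (s in seq_len(S)) vres <- vres + sum(Mod(us[, , s] - vs[, , s])^2)
    objective <- data_term(us, z, config$mode, chi, sigma) + vres / gamma + patch_obj

    rmse <- NA_real_
    if (!is.null(truth)) {
      xa <- align_global_phase(x_new, truth$field)
      rmse <- rmse_phase(Arg(xa), truth_wrapped)
    }
    hist[it, ] <- list(it, objective, sx, delta, mean_atoms, rmse)
    if (verbose)
      message(sprintf("iter %2d: obj %.6g%s", it, objective,
                      if (is.na(rmse)) "" else sprintf(", rmse %.4f", rmse)))
    x <- x_new
  }

  structure(list(x = x, dictionary = D, history = hist, config = config),
            class = "dlpr_result")
}

#' @export
print.dlpr_result <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<dlpr_result> %s/%s, %d iterations, final objective %.6g%s\n",
              x$config$mode, x$config$variant, nrow(x$history), last$objective,
              if (is.na(last$rmse)) "" else sprintf(", rmse %.4f", last$rmse)))
  invisible(x)
}

#' Save an estimate as float TIFF (amplitude, wrapped phase) + RDS container
#'
#' The TIFF is a preview: the amplitude plane is scaled by its maximum and
#' the wrapped phase mapped from `[-pi, pi)` onto `[0, 1]` (the writer's
#' value range). The RDS container holds the exact complex estimate and the
#' iteration history.
#'
#' @param result a `dlpr_result`.
#' @param path base path; writes `<path>.tif` and `<path>.rds`.
#' @export
write_estimate <- function(result, path) {
  stopifnot(inherits(result, "dlpr_result"))
  amp <- Mod(result$x)
  if (max(amp) > 0) amp <- amp / max(amp)
  tiff::writeTIFF(list(amp, (Arg(result$x) + pi) / (2 * pi)),
                  paste0(path, ".tif"), bits.per.sample = 32L, reduce = FALSE)
  saveRDS(list(x = result$x, history = result$history,
               format = "dlpr-estimate-v1"), paste0(path, ".rds"))
  invisible(path)
}
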