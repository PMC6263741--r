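#' Wrap phase into [-pi, pi)
#'
#' The 2-pi modulo wrapping operator `W(psi) = mod(psi + pi, 2 pi) - pi`,
#' mapping absolute phase to interferometric phase. The boundary `pi` maps
#' to `-pi`.
#'
#' @param psi numeric array of phase values (radians).
#' @return array of the same shape with entries in `[-pi, pi)`.
#' @export
wrap_phase <- function(psi) {
  if (any(!is.finite(psi))) stop("`psi` must be finite", call. = FALSE)
  (psi + pi) %% (2 * pi) - pi
}

#' Remove the global phase ambiguity
#'
#' Intensity measurements determine a wavefront only up to a global unimodular
#' factor. This rotates the estimate by `exp(-1i * phi*)` with
#' `phi* = angle(sum(xhat * Conj(x_true)))`, the closed-form maximizer of
#' `Re <x_true, xhat * exp(-1i * phi)>`.
#'
#' @param xhat complex estimate (matrix).
#' @param x_true complex reference, same shape.
#' @return the aligned estimate; if the inner product is exactly zero the
#'   estimate is returned unchanged with a warning.
#' @export
align_global_phase <- function(xhat, x_true) {
  if (any(dim(xhat) != dim(x_true))) stop("shapes disagree", call. = FALSE)
  ip <- sum(xhat * Conj(x_true))
  if (Mod(ip) == 0) {
    warning("zero inner product: global phase is undetermined; returning unchanged")
    return(xhat)
  }
  xhat * exp(-1i * Arg(ip))
}

#' Wrapped-phase root-mean-square error
#'
#' `sqrt(mean(wrap(psi_hat - psi)^2))`: the per-pixel RMS of the wrapped
#' phase difference. Symmetric in its arguments, invariant to adding
#' multiples of 2 pi to either input, and bounded by pi.
#'
#' @param est estimated wrapped (or absolute) phase, numeric matrix.
#' @param truth reference phase, same shape.
#' @return scalar RMSE in radians.
#' @export
rmse_phase <- function(est, truth) {
  if (!is.matrix(est) || !is.matrix(truth) || any(dim(est) != dim(truth)))
    stop("`est` and `truth` must be matrices of the same shape", call. = FALSE)
  sqrt(mean(wrap_phase(est - truth)^2))
}

# one simulate-solve-evaluate pass; internal worker for run_experiment()
solve_scene <- function(scene, noise_model, chi = NULL, sigma = NULL,
                        variant = "dlpr", seed = 1L, prior = NULL,
                        iterations = 20L, S = 12L, align = TRUE, ...) {
  shape <- dim(scene$field)
  masks <- generate_masks(S, shape, seed = seed)
  obs <- observe(scene$field, masks, noise_model, chi = chi, sigma = sigma,
                 seed = seed + 1000L)
  cfg <- dlpr_config(mode = noise_model, variant = variant, chi = chi,
                     sigma = sigma, iterations = iterations, S = S,
                     seed = seed, ...)
  fit <- dlpr(obs, masks, cfg, prior = prior, truth = scene)
  xa <- if (align) align_global_phase(fit$x, scene$field) else fit$x
  list(fit = fit,
       rmse = rmse_phase(Arg(xa), wrap_phase(scene$phase)))
}

#' Run a simulation sweep
#'
#' For every combination of scene, noise level, variant and seed: simulate
#' the coded-diffraction observations, run the solver, align the global
#' phase, and compute the wrapped-phase RMSE. Noise levels for the Poisson
#' model are given on the conventional unnormalized-intensity scale and are
#' mapped through [chi_effective()] internally.
#'
#' @param scenes list of `complex_scene` objects (e.g. [make_test_suite()]).
#' @param noise_model `"poisson"`, `"gaussian"` or `"noiseless"`.
#' @param levels numeric vector of `chi` (Poisson, unnormalized scale) or
#'   `sigma` (Gaussian) values; ignored for `"noiseless"`.
#' @param variants character vector of solver variants.
#' @param seeds integer vector of replicate seeds.
#' @param prior dictionary for the `prior_plugged` variant.
#' @param iterations,S solver settings.
#' @param align apply global phase alignment before the RMSE (default TRUE).
#' @param out_csv optional path; results are written incrementally so a
#'   partial table survives a failure.
#' @param ... further arguments passed to [dlpr_config()].
#' @return data frame with columns scene, group, noise_model, chi_or_sigma,
#'   variant, seed, rmse, iterations.
#' @export
run_experiment <- function(scenes, noise_model, levels = NA, variants = "dlpr",
                           seeds = 1L, prior = NULL, iterations = 20L, S = 12L,
                           align = TRUE, out_csv = NULL, ...) {
  if (noise_model == "noiseless") levels <- NA
  rows <- list()
  flush_csv <- function(df) {
    if (!is.null(out_csv))
      utils::write.csv(df, out_csv, row.names = FALSE)
  }
  for (sc in seq_along(scenes)) {
    scene <- scenes[[sc]]
    n <- length(scene$field)
    for (lev in levels) {
      chi <- sigma <- NULL
      if (noise_model == "poisson") chi <- chi_effective(lev, n)
      if (noise_model == "gaussian") sigma <- lev
      for (variant in variants) {
        for (seed in seeds) {
          r <- solve_scene(scene, noise_model, chi = chi, sigma = sigma,
                           variant = variant, seed = seed,
                           prior = if (variant == "prior_plugged") prior else NULL,
                           iterations = iterations, S = S, align = align, ...)
          rows[[length(rows) + 1L]] <- data.frame(
            scene = sc, group = scene$group, noise_model = noise_model,
            chi_or_sigma = lev, variant = variant, seed = seed,
            rmse = r$rmse, iterations = iterations)
          flush_csv(do.call(rbind, rows))
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  flush_csv(df)
  df
}
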