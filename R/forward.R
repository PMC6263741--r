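#' Random quaternary phase masks
#'
#' Draws `S` pixelwise-random phase masks with phase values sampled i.i.d. and
#' equiprobably from \{0, pi/2, -pi/2, pi\}. Mask `s` defines the unitary
#' propagation operator `A_s = F M_s` where `F` is the unitary 2-D DFT and
#' `M_s = diag(exp(1i * phases_s))`.
#'
#' @param S number of masks (>= 1).
#' @param shape integer `(rows, cols)`.
#' @param seed integer seed; the draw is reproducible.
#' @return an object of class `mask_set`: list with `phases`
#'   (`rows x cols x S` array), `S`, `shape`, `seed`.
#' @export
generate_masks <- function(S, shape, seed = 1L) {
  if (!is.numeric(S) || length(S) != 1L || S < 1 || S != round(S))
    stop("`S` must be an integer >= 1", call. = FALSE)
  shape <- check_size(shape)
  alphabet <- c(0, pi / 2, -pi / 2, pi)
  phases <- with_seed(seed, {
    array(sample(alphabet, prod(shape) * S, replace = TRUE),
          dim = c(shape, S))
  })
  structure(list(phases = phases, S = as.integer(S), shape = shape,
                 seed = as.integer(seed)),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> S = %d masks of %d x %d (seed %d)\n",
              x$S, x$shape[1], x$shape[2], x$seed))
  invisible(x)
}

mask_phase <- function(masks, s) masks$phases[, , s, drop = TRUE]

#' Unitary coded propagation and its adjoint
#'
#' `propagate()` applies `A_s x = F (M_s x)` with the unitary DFT
#' (`fft(.)/sqrt(n)`); `backpropagate()` applies the adjoint
#' `A_s^H u = conj(M_s) F^H u`. Because both `F` and `M_s` are unitary,
#' `backpropagate(propagate(x)) == x` and both maps preserve the l2 norm.
#'
#' @param x,u complex matrix (object-plane wavefront / sensor-plane field).
#' @param phase real matrix of mask phases, same shape.
#' @return complex matrix of the same shape.
#' @export
propagate <- function(x, phase) {
  if (!is.matrix(x) || any(dim(x) != dim(phase)))
    stop("`x` and mask `phase` must be matrices of the same shape", call. = FALSE)
  stats::fft(exp(1i * phase) * x) / sqrt(length(x))
}

#' @rdname propagate
#' @export
backpropagate <- function(u, phase) {
  if (!is.matrix(u) || any(dim(u) != dim(phase)))
    stop("`u` and mask `phase` must be matrices of the same shape", call. = FALSE)
  exp(-1i * phase) * stats::fft(u, inverse = TRUE) / sqrt(length(u))
}

# clean intensities y_s = |A_s x|^2, rows x cols x S
clean_intensities <- function(x, masks) {
  y <- array(0, dim = c(dim(x), masks$S))
  for (s in seq_len(masks$S))
    y[, , s] <- Mod(propagate(x, mask_phase(masks, s)))^2
  y
}

#' Simulate noisy intensity observations
#'
#' Produces the observation stack `z_s` from the clean coded-diffraction
#' intensities `y_s = |A_s x|^2`. Under the Poissonian (photon-limited) model
#' `z_s[l] ~ Poisson(y_s[l] * chi)`, where `chi` scales intensity to expected
#' photon counts; under the Gaussian model `z_s[l] = y_s[l] + sigma * N(0,1)`
#' (negative samples are retained, not clipped); `noiseless` returns `z = y`.
#'
#' @param x complex object wavefront (matrix).
#' @param masks a `mask_set`.
#' @param noise_model `"poisson"`, `"gaussian"` or `"noiseless"`.
#' @param chi photons per unit intensity (Poisson; > 0). See [chi_effective()]
#'   for the correspondence with photon scalings quoted on the unnormalized
#'   spectral-intensity scale.
#' @param sigma intensity-noise standard deviation (Gaussian; >= 0).
#' @param seed integer seed.
#' @return an object of class `observation_set`: list with `z`
#'   (`rows x cols x S`), `noise_model`, `chi`, `sigma`, `S`, `shape`, `seed`.
#' @export
observe <- function(x, masks, noise_model = c("poisson", "gaussian", "noiseless"),
                    chi = NULL, sigma = NULL, seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(masks, "mask_set"))
  if (any(dim(x) != masks$shape)) stop("`x` does not match the mask shape", call. = FALSE)
  y <- clean_intensities(x, masks)
  z <- switch(noise_model,
    poisson = {
      if (is.null(chi) || chi <= 0) stop("poisson model requires `chi` > 0", call. = FALSE)
      with_seed(seed, array(stats::rpois(length(y), y * chi), dim = dim(y)))
    },
    gaussian = {
      if (is.null(sigma) || sigma < 0) stop("gaussian model requires `sigma` >= 0", call. = FALSE)
      with_seed(seed, y + sigma * array(stats::rnorm(length(y)), dim = dim(y)))
    },
    noiseless = y
  )
  structure(list(z = z, noise_model = noise_model,
                 chi = if (noise_model == "poisson") chi else NULL,
                 sigma = if (noise_model == "gaussian") sigma else NULL,
                 S = masks$S, shape = masks$shape, seed = as.integer(seed)),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  par <- switch(x$noise_model,
    poisson = sprintf("chi = %g", x$chi),
    gaussian = sprintf("sigma = %g", x$sigma),
    noiseless = "exact")
  cat(sprintf("<observation_set> %s (%s), S = %d, %d x %d\n",
              x$noise_model, par, x$S, x$shape[1], x$shape[2]))
  invisible(x)
}

#' Global sensor signal-to-noise ratio (dB) under Poisson noise
#'
#' For Poisson counts with mean `y * chi`, the per-pixel SNR (squared mean
#' over variance) is `y * chi`; pooling over all masks and pixels gives
#' `SNR_global = chi * sum(y^2) / sum(y)`, returned in dB.
#'
#' @inheritParams observe
#' @return scalar, dB.
#' @export
snr_global <- function(x, masks, chi) {
  if (chi <= 0) stop("`chi` must be positive", call. = FALSE)
  y <- clean_intensities(x, masks)
  sy <- sum(y)
  if (sy == 0) stop("all-zero intensity: SNR undefined", call. = FALSE)
  10 * log10(chi * sum(y^2) / sy)
}

#' Photon scaling on the unitary intensity scale
#'
#' Photon-count scalings for coded diffraction patterns are conventionally
#' quoted with intensities on the unnormalized spectral scale, where a
#' unit-amplitude scene has mean spectral intensity `n` (the pixel count).
#' This package propagates with the unitary DFT, under which the same scene
#' has mean spectral intensity 1; the equivalent photon scaling is therefore
#' `n * chi`. Use this mapping when reproducing studies that quote `chi`
#' values such as 1e-5 .. 1e-2 (sensor SNR -7 .. 23 dB on unit-amplitude
#' scenes).
#'
#' @param chi photon scaling quoted on the unnormalized intensity scale.
#' @param shape image shape `(rows, cols)` (or a scalar pixel count).
#' @return the equivalent `chi` for [observe()] under unitary propagation.
#' @export
chi_effective <- function(chi, shape) {
  n <- if (length(shape) > 1L) prod(check_size(shape)) else as.numeric(shape)
  chi * n
}

#' Save / load observations and masks as a single container
#'
#' Serializes an `observation_set` together with its `mask_set` (RDS
#' container).
#'
#' @param obs an `observation_set`.
#' @param masks the `mask_set` used to generate it.
#' @param path file path.
#' @export
write_observations <- function(obs, masks, path) {
  stopifnot(inherits(obs, "observation_set"), inherits(masks, "mask_set"))
  saveRDS(list(observations = obs, masks = masks, format = "dlpr-observations-v1"),
          path)
  invisible(path)
}

#' @rdname write_observations
#' @return `read_observations()`: list with `observations` and `masks`.
#' @export
read_observations <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "dlpr-observations-v1"))
    stop("not a dlpr observation container", call. = FALSE)
  x[c("observations", "masks")]
}
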