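#' Synthetic absolute-phase surfaces
#'
#' Generates the absolute phase \eqn{\psi} (in radians) of a test wavefront.
#' Five families are available:
#' \describe{
#'   \item{`gaussian`}{a centred Gaussian bump reaching `peak` radians at the
#'     image centre;}
#'   \item{`truncated_gaussian`}{the same bump with the four alternate angular
#'     octants (indexed 0--7 counterclockwise from the +x axis about the grid
#'     centre; even octants) set to zero, producing many sharp fringe
#'     discontinuities;}
#'   \item{`mountain`}{a seeded smooth random terrain, a sum of low-frequency
#'     harmonics rescaled to `[0, peak]`;}
#'   \item{`quadratic`}{a centred paraboloid with its maximum `peak` at the
#'     centre, decaying quadratically towards the corners;}
#'   \item{`shear_plane`}{an affine ramp with total excursion `peak` across the
#'     image diagonal.}
#' }
#'
#' @param kind one of `"gaussian"`, `"truncated_gaussian"`, `"mountain"`,
#'   `"quadratic"`, `"shear_plane"`.
#' @param size integer vector `(rows, cols)`.
#' @param peak maximum phase in radians (total ramp for `shear_plane`). The
#'   default of 12 rad gives the interferometric phase several fringes.
#' @param seed integer seed; only the `mountain` family is random.
#' @return a `rows x cols` numeric matrix of absolute phase values (radians).
#' @examples
#' psi <- make_phase_surface("gaussian", c(32, 32), peak = 6)
#' range(psi)
#' @export
make_phase_surface <- function(kind = c("gaussian", "truncated_gaussian",
                                        "mountain", "quadratic", "shear_plane"),
                               size, peak = 12, seed = 1L) {
  kind <- match.arg(kind)
  size <- check_size(size)
  if (peak <= 0) stop("`peak` must be positive", call. = FALSE)
  rows <- size[1]; cols <- size[2]
  # centred coordinates, normalized
  rc <- (seq_len(rows) - (rows + 1) / 2)
  cc <- (seq_len(cols) - (cols + 1) / 2)
  u <- matrix(rep(cc, each = rows), rows, cols) / ((cols - 1) / 2)  # x in [-1,1]
  v <- matrix(rep(rc, times = cols), rows, cols) / ((rows - 1) / 2) # y in [-1,1]
  psi <- switch(kind,
    gaussian = ,
    truncated_gaussian = {
      s2 <- (1 / 3)^2  # bump std 1/3 of the half-width: ~3 sigma to the border
      g <- peak * exp(-(u^2 + v^2) / (2 * s2))
      if (kind == "truncated_gaussian") {
        ang <- atan2(v, u) %% (2 * pi)
        octant <- floor(ang / (pi / 4)) %% 8
        g[octant %% 2 == 0] <- 0
      }
      g
    },
    mountain = with_seed(seed, {
      nh <- 12L
      fx <- stats::runif(nh, -2.5, 2.5)
      fy <- stats::runif(nh, -2.5, 2.5)
      ph <- stats::runif(nh, 0, 2 * pi)
      am <- stats::runif(nh, 0.3, 1)
      z <- matrix(0, rows, cols)
      for (m in seq_len(nh))
        z <- z + am[m] * cos(pi * (fx[m] * u + fy[m] * v) + ph[m])
      rescale01(z, 0, peak)
    }),
    quadratic = peak * (1 - (u^2 + v^2) / 2),
    shear_plane = peak * ((u + 1) / 2 + (v + 1) / 2) / 2
  )
  storage.mode(psi) <- "double"
  psi
}

#' Couple an amplitude image to a phase surface
#'
#' Builds the positive amplitude `a` of a test wavefront from its absolute
#' phase, following four amplitude-phase relationship groups:
#' group 1 -- invariant amplitude (all ones); group 2 -- amplitude independent
#' of the phase (a supplied image, shifted to be strictly positive); group 3 --
#' amplitude highly similar to the phase, `k0 + k1 * |psi| / max|psi|`;
#' group 4 -- amplitude less similar to the phase, `k0 + k1 * |cos(15 psi)|`.
#'
#' @param psi absolute-phase matrix (radians).
#' @param group integer in 1..4.
#' @param k0,k1 offset and gain of the coupling (groups 3 and 4).
#' @param independent_amplitude amplitude image for group 2 (required there).
#' @return a strictly positive numeric matrix, same shape as `psi`.
#' @export
couple_amplitude <- function(psi, group, k0 = 1, k1 = 1,
                             independent_amplitude = NULL) {
  stopifnot(is.matrix(psi), is.numeric(psi))
  if (!group %in% 1:4) stop("`group` must be 1, 2, 3 or 4", call. = FALSE)
  a <- switch(group,
    matrix(1, nrow(psi), ncol(psi)),
    {
      if (is.null(independent_amplitude))
        stop("group 2 requires `independent_amplitude`", call. = FALSE)
      a <- independent_amplitude
      if (!is.matrix(a) || any(dim(a) != dim(psi)))
        stop("`independent_amplitude` must match the shape of `psi`", call. = FALSE)
      if (min(a) <= 0) a <- a - min(a) + 1  # positivity shift: a must be in R+
      a
    },
    {
      mx <- max(abs(psi))
      if (mx == 0) stop("group 3 is degenerate when max|psi| = 0", call. = FALSE)
      k0 + k1 * abs(psi) / mx
    },
    k0 + k1 * abs(cos(15 * psi))
  )
  storage.mode(a) <- "double"
  a
}

#' Construct a complex scene (object wavefront with ground truth)
#'
#' A complex scene holds the wavefront `field = amplitude * exp(1i * phase)`
#' together with its ground-truth amplitude and absolute phase.
#'
#' @param amplitude strictly positive numeric matrix.
#' @param phase absolute-phase matrix (radians), same shape.
#' @param group amplitude-coupling group (1..4), kept as metadata.
#' @return an object of class `complex_scene` with elements `field`,
#'   `amplitude`, `phase`, `group`.
#' @export
complex_scene <- function(amplitude, phase, group = 1L) {
  stopifnot(is.matrix(amplitude), is.matrix(phase))
  if (any(dim(amplitude) != dim(phase)))
    stop("amplitude and phase must have the same shape", call. = FALSE)
  if (any(!is.finite(amplitude)) || any(!is.finite(phase)))
    stop("amplitude and phase must be finite", call. = FALSE)
  if (any(amplitude <= 0)) stop("amplitude must be strictly positive", call. = FALSE)
  structure(list(field = amplitude * exp(1i * phase),
                 amplitude = amplitude, phase = phase,
                 group = as.integer(group)),
            class = "complex_scene")
}

#' @export
print.complex_scene <- function(x, ...) {
  cat(sprintf("<complex_scene> %d x %d, group %d, peak phase %.3g rad\n",
              nrow(x$field), ncol(x$field), x$group, max(abs(x$phase))))
  invisible(x)
}

#' The nine-scene simulated test suite
#'
#' Builds the standard suite of nine complex test images: the two phase
#' surfaces with many fringes (truncated Gaussian and shear plane) crossed
#' with the four amplitude-coupling groups. Rows, in order:
#' constant/truncated-Gaussian (1), constant/shear-plane (1),
#' mountain/shear-plane (2), quadratic/truncated-Gaussian (2),
#' gaussian/shear-plane (2), similar/truncated-Gaussian (3),
#' similar/shear-plane (3), less-similar/truncated-Gaussian (4),
#' less-similar/shear-plane (4). Group-2 amplitude images are the named
#' surfaces rescaled onto `[1, 2]`.
#'
#' @param size integer `(rows, cols)`; default `c(100, 100)`.
#' @param peak peak phase (radians) of every surface.
#' @param seed integer seed (drives the mountain surfaces).
#' @return list of 9 `complex_scene` objects.
#' @export
make_test_suite <- function(size = c(100, 100), peak = 12, seed = 1L) {
  size <- check_size(size)
  tg <- make_phase_surface("truncated_gaussian", size, peak, seed)
  sp <- make_phase_surface("shear_plane", size, peak, seed)
  amp <- function(kind) rescale01(make_phase_surface(kind, size, peak, seed + 7L), 1, 2)
  rows <- list(
    list(phase = tg, group = 1L, a = NULL),
    list(phase = sp, group = 1L, a = NULL),
    list(phase = sp, group = 2L, a = amp("mountain")),
    list(phase = tg, group = 2L, a = amp("quadratic")),
    list(phase = sp, group = 2L, a = amp("gaussian")),
    list(phase = tg, group = 3L, a = NULL),
    list(phase = sp, group = 3L, a = NULL),
    list(phase = tg, group = 4L, a = NULL),
    list(phase = sp, group = 4L, a = NULL)
  )
  lapply(rows, function(r) {
    a <- couple_amplitude(r$phase, r$group, independent_amplitude = r$a)
    complex_scene(a, r$phase, r$group)
  })
}

#' Clean scenes for training a class-specific dictionary prior
#'
#' Returns the standard prior-training set for the truncated-Gaussian class:
#' a full Gaussian phase surface plus four scenes each retaining one quadrant
#' of that surface (zero phase elsewhere), all with unit amplitude. A
#' dictionary learned on patches of these scenes serves as the plug-in prior
#' for class-specific phase retrieval.
#'
#' @inheritParams make_test_suite
#' @return list of 5 `complex_scene` objects.
#' @export
gaussian_prior_scenes <- function(size = c(100, 100), peak = 12, seed = 1L) {
  size <- check_size(size)
  g <- make_phase_surface("gaussian", size, peak, seed)
  rows <- size[1]; cols <- size[2]
  rmid <- floor(rows / 2); cmid <- floor(cols / 2)
  quadrant <- function(rsel, csel) {
    q <- matrix(0, rows, cols)
    q[rsel, csel] <- g[rsel, csel]
    q
  }
  phases <- list(
    g,
    quadrant(1:rmid, 1:cmid),
    quadrant(1:rmid, (cmid + 1):cols),
    quadrant((rmid + 1):rows, 1:cmid),
    quadrant((rmid + 1):rows, (cmid + 1):cols)
  )
  lapply(phases, function(p) complex_scene(matrix(1, rows, cols), p, 1L))
}

#' Save / load a complex scene as float TIFF + JSON sidecar
#'
#' The amplitude and phase planes are written as two 32-bit float pages of a
#' single TIFF, each rescaled onto `[0, 1]` (the TIFF writer's value range);
#' the original plane ranges and any generation metadata go to
#' `<path>.json`, and [load_scene()] undoes the rescaling.
#'
#' @param scene a `complex_scene`.
#' @param path output TIFF path.
#' @param meta optional named list merged into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
save_scene <- function(scene, path, meta = list()) {
  stopifnot(inherits(scene, "complex_scene"))
  rng <- function(m) range(m)
  norm <- function(m) {
    r <- rng(m)
    if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else matrix(0, nrow(m), ncol(m))
  }
  tiff::writeTIFF(list(norm(scene$amplitude), norm(scene$phase)), path,
                  bits.per.sample = 32L, reduce = FALSE)
  side <- c(list(group = scene$group, rows = nrow(scene$field),
                 cols = ncol(scene$field),
                 amplitude_range = rng(scene$amplitude),
                 phase_range = rng(scene$phase)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_scene
#' @export
load_scene <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (length(pages) != 2L) stop("expected a 2-page TIFF (amplitude, phase)", call. = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  denorm <- function(m, r) r[1] + m * (r[2] - r[1])
  complex_scene(denorm(pages[[1]], side$amplitude_range),
                denorm(pages[[2]], side$phase_range),
                side$group %||% 1L)
}
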