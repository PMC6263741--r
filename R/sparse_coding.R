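#' Dictionary constructor
#'
#' A dictionary is a `w^2 x k` complex matrix of atoms, each constrained to
#' the unit l2 ball.
#'
#' @param atoms complex matrix (`w^2 x k`); columns with norm > 1 are rejected
#'   (use `normalize = TRUE` to scale every atom to unit norm).
#' @param w patch side length (`nrow(atoms)` must equal `w^2`).
#' @param normalize scale atoms to unit norm first.
#' @return object of class `dlpr_dictionary` with elements `atoms`, `w`, `k`.
#' @export
new_dictionary <- function(atoms, w, normalize = FALSE) {
  atoms <- as.matrix(atoms)
  if (!is.complex(atoms)) atoms <- atoms + 0i
  if (nrow(atoms) != w^2) stop("`atoms` must have w^2 rows", call. = FALSE)
  if (any(!is.finite(Re(atoms))) || any(!is.finite(Im(atoms))))
    stop("dictionary atoms must be finite", call. = FALSE)
  nrm <- sqrt(colSums(Mod(atoms)^2))
  if (normalize) {
    nz <- nrm > 0
    atoms[, nz] <- sweep(atoms[, nz, drop = FALSE], 2, nrm[nz], "/")
  } else if (any(nrm > 1 + 1e-8)) {
    stop("atom norms must be <= 1", call. = FALSE)
  }
  structure(list(atoms = atoms, w = as.integer(w), k = ncol(atoms)),
            class = "dlpr_dictionary")
}

#' @export
print.dlpr_dictionary <- function(x, ...) {
  cat(sprintf("<dlpr_dictionary> %d atoms of %d x %d patches\n", x$k, x$w, x$w))
  invisible(x)
}

#' Save / load a dictionary container
#'
#' @param dict a `dlpr_dictionary`.
#' @param path file path (RDS container).
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "dlpr_dictionary"))
  saveRDS(list(atoms = dict$atoms, w = dict$w, k = dict$k,
               format = "dlpr-dictionary-v1"), path)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "dlpr-dictionary-v1"))
    stop("not a dlpr dictionary container", call. = FALSE)
  new_dictionary(x$atoms, x$w)
}

#' Estimate the complex noise standard deviation of an image
#'
#' Robust estimate of the per-pixel complex noise level from pooled
#' horizontal and vertical first-order differences. The scaled median
#' absolute deviation (1.4826 * MAD) is applied separately to the real and
#' imaginary parts of the pooled differences, combined in quadrature, and
#' divided by sqrt(2) to undo the variance doubling of differencing. The
#' returned `sigma_x` satisfies `E|noise|^2 = sigma_x^2` for circular complex
#' Gaussian noise.
#'
#' @param x complex image matrix (>= 2 rows and columns).
#' @return scalar noise standard deviation.
#' @export
estimate_noise_std <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2L || ncol(x) < 2L)
    stop("`x` must be a matrix with at least 2 rows and 2 columns", call. = FALSE)
  dh <- x[, -1L, drop = FALSE] - x[, -ncol(x), drop = FALSE]
  dv <- x[-1L, , drop = FALSE] - x[-nrow(x), , drop = FALSE]
  d <- c(dh, dv)
  sr <- stats::mad(Re(d))
  si <- stats::mad(Im(d))
  sqrt(sr^2 + si^2) / sqrt(2)
}

#' Residual tolerance for OMP from a chi-squared quantile
#'
#' Under a circular complex Gaussian residual of per-pixel variance
#' `sigma_x^2`, the patch residual energy divided by `sigma_x^2 / 2` follows
#' a chi-squared law with `2 w^2` degrees of freedom; the OMP stopping level
#' is its `mu`-quantile: `delta = (sigma_x^2 / 2) * qchisq(mu, 2 w^2)`.
#'
#' @param sigma_x complex noise standard deviation (see [estimate_noise_std()]).
#' @param w patch side length.
#' @param mu quantile in (0, 1); 0.96 in all standard settings.
#' @return scalar tolerance on the squared residual norm.
#' @export
omp_tolerance <- function(sigma_x, w, mu = 0.96) {
  if (mu <= 0 || mu >= 1) stop("`mu` must lie strictly between 0 and 1", call. = FALSE)
  (sigma_x^2 / 2) * stats::qchisq(mu, df = 2 * w^2)
}

#' Complex-domain orthogonal matching pursuit (single patch)
#'
#' Greedy sparse coding: while the squared residual norm exceeds `delta` and
#' fewer than `max_atoms` atoms are active, select the atom with the largest
#' `|d_j^H r|` (ties break to the lowest index), refit all active
#' coefficients by least squares on the active sub-dictionary, and update the
#' residual.
#'
#' @param patch complex vector of length `w^2`.
#' @param dict a `dlpr_dictionary`.
#' @param delta nonnegative squared-residual stopping level.
#' @param max_atoms cap on the support size (default `min(w^2, 30)`).
#' @return list with `support` (1-based atom indices, in selection order),
#'   `coefficients` (complex, aligned with `support`), `residual_norm2`, and
#'   `approximation` (the coded patch `D alpha`).
#' @export
omp <- function(patch, dict, delta, max_atoms = NULL) {
  stopifnot(inherits(dict, "dlpr_dictionary"))
  if (dict$k < 1) stop("empty dictionary", call. = FALSE)
  if (delta < 0) stop("`delta` must be nonnegative", call. = FALSE)
  max_atoms <- as.integer(max_atoms %||% min(dict$w^2, 30L))
  if (max_atoms < 1) stop("`max_atoms` must be >= 1", call. = FALSE)
  p <- as.complex(patch)
  if (length(p) != nrow(dict$atoms)) stop("patch length must equal w^2", call. = FALSE)
  res <- omp_batch(matrix(p, ncol = 1), dict$atoms, delta, max_atoms)
  support <- as.integer(res$idx)
  coefficients <- as.complex(res$coef)
  list(support = support, coefficients = coefficients,
       residual_norm2 = res$rnorm2[1],
       approximation = as.complex(res$recon[, 1]))
}

#' Sparse-code a full patch matrix by OMP
#'
#' Applies [omp()] to every column of a patch matrix and returns the codes
#' together with the reconstruction `D alpha_i` per column.
#'
#' @param patches `w^2 x P` complex matrix (see [extract_patches()]).
#' @param dict a `dlpr_dictionary`.
#' @inheritParams omp
#' @param return_codes set `FALSE` to skip materializing the per-patch code
#'   list (the reconstruction is always returned).
#' @return list with `reconstruction` (`w^2 x P`), `residual_norm2` (length
#'   P), `n_atoms` (length P) and, if requested, `codes` (list of
#'   support/coefficient pairs).
#' @export
code_patches <- function(patches, dict, delta, max_atoms = NULL,
                         return_codes = TRUE) {
  stopifnot(inherits(dict, "dlpr_dictionary"))
  if (dict$k < 1) stop("empty dictionary", call. = FALSE)
  if (delta < 0) stop("`delta` must be nonnegative", call. = FALSE)
  max_atoms <- as.integer(max_atoms %||% min(dict$w^2, 30L))
  if (!is.complex(patches)) patches <- patches + 0i
  res <- omp_batch(patches, dict$atoms, delta, max_atoms)
  out <- list(reconstruction = res$recon,
              residual_norm2 = as.numeric(res$rnorm2),
              n_atoms = as.integer(res$lens))
  if (return_codes) {
    f <- rep.int(seq_along(res$lens), res$lens)
    idx <- split(as.integer(res$idx), factor(f, levels = seq_along(res$lens)))
    cf <- split(as.complex(res$coef), factor(f, levels = seq_along(res$lens)))
    out$codes <- Map(function(i, a) list(support = i, coefficients = a), idx, cf)
    names(out$codes) <- NULL
  }
  out
}
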