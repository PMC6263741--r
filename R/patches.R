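#' Overlapping patch grid
#'
#' Defines the set of `w x w` patches extracted from a `rows x cols` image.
#' Patch positions are the top-left corners, advancing by `stride` pixels in
#' each direction; the final position along each axis is always included so
#' that the grid covers the whole image whenever `stride <= w`. Patches are
#' vectorized column-major within the `w x w` block.
#'
#' @param image_shape integer `(rows, cols)`.
#' @param w patch side length in pixels.
#' @param stride step between patch origins (default 1, fully overlapping).
#' @return an object of class `patch_grid` with the index matrix used by
#'   [extract_patches()] and [aggregate_patches()].
#' @export
patch_grid <- function(image_shape, w, stride = 1L) {
  shape <- check_size(image_shape)
  rows <- shape[1]; cols <- shape[2]
  if (w < 1 || w != round(w)) stop("`w` must be a positive integer", call. = FALSE)
  if (w > rows || w > cols) stop("image smaller than the patch size", call. = FALSE)
  if (stride < 1 || stride != round(stride)) stop("`stride` must be a positive integer", call. = FALSE)
  if (stride > w) stop("`stride` > `w` leaves pixels uncovered", call. = FALSE)
  pos <- function(extent) unique(c(seq(1L, extent - w + 1L, by = stride), extent - w + 1L))
  starts_r <- pos(rows); starts_c <- pos(cols)
  # linear indices of one patch anchored at (1,1), column-major within the block
  base <- as.vector(outer(0:(w - 1L), (0:(w - 1L)) * rows, "+"))
  origins <- as.vector(outer(starts_r, (starts_c - 1L) * rows, "+"))  # linear index of each top-left
  idx <- outer(base, origins, "+")  # w^2 x P
  structure(list(w = as.integer(w), stride = as.integer(stride),
                 image_shape = shape, starts_r = starts_r, starts_c = starts_c,
                 n_patches = length(origins), idx = idx),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d patches of %d x %d, stride %d, image %d x %d\n",
              x$n_patches, x$w, x$w, x$stride, x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Extract overlapping patches
#'
#' Returns the patch matrix whose column `i` is the vectorized `w x w` block
#' at grid position `i`.
#'
#' @param x complex (or numeric) image matrix.
#' @param grid a `patch_grid` matching `dim(x)`.
#' @return `w^2 x n_patches` matrix.
#' @export
extract_patches <- function(x, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  if (!is.matrix(x) || any(dim(x) != grid$image_shape))
    stop("`x` does not match the grid's image shape", call. = FALSE)
  p <- x[grid$idx]
  dim(p) <- dim(grid$idx)
  p
}

#' Aggregate patches back into an image
#'
#' Inverts [extract_patches()]: every pixel receives the sum of the
#' contributions of all patches covering it, divided by its multiplicity
#' (the number of covering patches), so that `aggregate(extract(x)) == x`
#' for any image.
#'
#' @param patches `w^2 x n_patches` matrix.
#' @param grid the `patch_grid` the patches came from.
#' @return image matrix of the grid's shape.
#' @export
aggregate_patches <- function(patches, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  if (!is.matrix(patches) || nrow(patches) != grid$w^2 || ncol(patches) != grid$n_patches)
    stop("`patches` does not match the grid", call. = FALSE)
  n <- prod(grid$image_shape)
  cpatches <- if (is.complex(patches)) patches else patches + 0i
  num <- patch_accumulate(cpatches, grid$idx, n)
  mu <- multiplicity_map(grid)
  if (any(mu == 0)) stop("grid does not cover the image", call. = FALSE)
  out <- num / as.vector(mu)
  dim(out) <- grid$image_shape
  if (all(Im(patches) == 0)) out <- Re(out)
  out
}

# unnormalized patch back-placement sum_i R_i^H p_i (complex image)
patch_backproject <- function(patches, grid) {
  n <- prod(grid$image_shape)
  cpatches <- if (is.complex(patches)) patches else patches + 0i
  num <- patch_accumulate(cpatches, grid$idx, n)
  dim(num) <- grid$image_shape
  num
}

#' Pixel multiplicity map
#'
#' Counts, for every pixel, the number of patches of the grid containing it
#' (the diagonal of the patch-normal operator). Interior pixels of a unit
#' stride grid have multiplicity `w^2`; the corners have multiplicity 1.
#'
#' @param grid a `patch_grid`.
#' @return integer matrix of the grid's image shape.
#' @export
multiplicity_map <- function(grid) {
  stopifnot(inherits(grid, "patch_grid"))
  n <- prod(grid$image_shape)
  mu <- tabulate(grid$idx, nbins = n)
  dim(mu) <- grid$image_shape
  mu
}
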