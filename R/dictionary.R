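#' l1-regularized complex sparse coding of one patch
#'
#' Approximately minimizes `||patch - D alpha||_2^2 + lambda ||alpha||_1`
#' over complex codes by variable splitting with an augmented Lagrangian
#' (ADMM): a quadratic step in the split variable, a complex soft-threshold
#' `max(|v| - kappa, 0) * v / |v|`, and a dual ascent step. Iterations stop
#' when successive codes differ by less than `tol` (relative) or after
#' `inner_iters` steps.
#'
#' @param patch complex vector of length `w^2`.
#' @param dict a `dlpr_dictionary`.
#' @param lambda l1 weight (>= 0).
#' @param inner_iters maximum ADMM iterations (default 100).
#' @param tol relative convergence tolerance on the code (default 1e-5).
#' @param rho ADMM penalty parameter (default 1).
#' @return complex coefficient vector of length `k`, with attribute
#'   `converged` (logical).
#' @export
l1_code <- function(patch, dict, lambda, inner_iters = 100L, tol = 1e-5, rho = 1) {
  stopifnot(inherits(dict, "dlpr_dictionary"))
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  p <- as.complex(patch)
  if (length(p) != nrow(dict$atoms)) stop("patch length must equal w^2", call. = FALSE)
  res <- sparsal_batch(matrix(p, ncol = 1), dict$atoms, lambda,
                       as.integer(inner_iters), tol, rho)
  alpha <- as.complex(res$alpha[, 1])
  conv <- as.logical(res$converged[1])
  if (!conv) warning("l1_code: inner solver did not converge; returning best iterate")
  structure(alpha, converged = conv)
}

# batch version used internally by codl (no warning churn)
l1_code_batch <- function(patches, atoms, lambda, inner_iters = 100L,
                          tol = 1e-5, rho = 1) {
  sparsal_batch(patches, atoms, lambda, as.integer(inner_iters), tol, rho)$alpha
}

#' One projected block-coordinate sweep of the dictionary atoms
#'
#' Updates each atom in turn from the accumulated sufficient statistics
#' `A = sum alpha alpha^H` (k x k) and `B = sum patch alpha^H` (w^2 x k):
#' `d_j <- Proj_ball( d_j + (b_j - D a_j) / A_jj )`, where the projection
#' rescales any atom with norm > 1 onto the unit sphere. Atoms with
#' `A_jj = 0` (never used) are passed through unchanged.
#'
#' @param state a `codl_state` as produced by [codl()] (elements `D`, `A`,
#'   `B` at minimum).
#' @return the state with updated dictionary atoms.
#' @export
update_atoms <- function(state) {
  D <- state$D; A <- state$A; B <- state$B
  k <- ncol(D)
  for (j in seq_len(k)) {
    ajj <- Re(A[j, j])
    if (ajj <= 0) next
    u <- D[, j] + (B[, j] - D %*% A[, j]) / ajj
    nrm <- sqrt(sum(Mod(u)^2))
    if (nrm > 1) u <- u / nrm
    D[, j] <- u
  }
  state$D <- D
  state
}

# Restart atoms that have collapsed onto a near-duplicate of another atom:
# the duplicate is re-seeded on the current batch's worst-represented patch
# and its accumulated statistics are cleared. Without this, a class of
# training patches that no atom covers codes to zero, never enters the
# statistics, and stays uncovered forever while two atoms track one class.
purge_duplicate_atoms <- function(state, Xb, Alpha, coherence = 0.99) {
  D <- state$D
  k <- ncol(D)
  if (k < 2L) return(state)
  resid <- sqrt(colSums(Mod(Xb - D %*% Alpha)^2))
  G <- Mod(Conj(t(D)) %*% D)
  nrm <- sqrt(colSums(Mod(D)^2))
  Gn <- G / (outer(nrm, nrm) + 1e-300)
  for (j in 2:k) {
    if (max(Gn[j, seq_len(j - 1L)]) > coherence && any(resid > 0)) {
      worst <- which.max(resid)
      p <- Xb[, worst]
      pn <- sqrt(sum(Mod(p)^2))
      if (pn == 0) next
      D[, j] <- p / pn
      state$A[j, ] <- 0i; state$A[, j] <- 0i; state$B[, j] <- 0i
      resid[worst] <- 0
      nrm[j] <- 1
      Gn[j, ] <- Mod(Conj(D[, j]) %*% D) / nrm
      Gn[, j] <- Gn[j, ]
    }
  }
  state$D <- D
  state
}

codl_state <- function(D, k) {
  structure(list(D = D, A = matrix(0i, k, k), B = matrix(0i, nrow(D), k), t = 0L),
            class = "codl_state")
}

# default initialization: eta patches (or as many as available) at random,
# normalized to unit norm; random unit-norm complex atoms pad up to k.
codl_init <- function(patches, k, eta) {
  w2 <- nrow(patches); P <- ncol(patches)
  take <- min(k, min(eta, P))
  sel <- sample.int(P, take)
  D <- patches[, sel, drop = FALSE]
  if (k > take) {
    extra <- matrix(stats::rnorm(w2 * (k - take)) + 1i * stats::rnorm(w2 * (k - take)), w2)
    D <- cbind(D, extra)
  }
  nrm <- sqrt(colSums(Mod(D)^2))
  nrm[nrm == 0] <- 1
  sweep(D, 2, nrm, "/")
}

#' Complex-domain online dictionary learning (C-ODL)
#'
#' Learns a `w^2 x k` complex dictionary from a patch matrix by online
#' alternating minimization of
#' `sum_i ||p_i - D alpha_i||_2^2 + lambda ||alpha_i||_1` subject to unit-ball
#' atoms. Each of the `T` online steps draws a mini-batch of `eta` patches
#' (without replacement within an epoch), sparse-codes them with [l1_code()],
#' accumulates the sufficient statistics `A += sum alpha alpha^H`,
#' `B += sum p alpha^H`, and performs one projected block-coordinate sweep of
#' the atoms ([update_atoms()]). Atoms that collapse onto a near-duplicate of
#' another atom are restarted on the batch's worst-represented patch (their
#' statistics cleared), the standard guard against uncovered patch classes.
#'
#' @param patches `w^2 x P` complex matrix of training patches.
#' @param k number of atoms (default 128).
#' @param T_iters number of online steps (default 30).
#' @param eta mini-batch size (default 64).
#' @param lambda l1 weight (default 0.11).
#' @param seed integer seed for batch sampling and initialization.
#' @param D_init optional initial `dlpr_dictionary` (default: random training
#'   patches, unit-normalized).
#' @param state optional `codl_state` carried over from a previous call
#'   (warm start: accumulators and dictionary are reused).
#' @param inner_iters,tol,rho passed to the l1 coder.
#' @param return_state also return the final `codl_state` (for warm starts).
#' @return a `dlpr_dictionary`; if `return_state = TRUE`, a list with
#'   elements `dictionary` and `state`.
#' @export
codl <- function(patches, k = 128L, T_iters = 30L, eta = 64L, lambda = 0.11,
                 seed = 1L, D_init = NULL, state = NULL,
                 inner_iters = 100L, tol = 1e-5, rho = 1,
                 return_state = FALSE) {
  if (!is.complex(patches)) patches <- patches + 0i
  w2 <- nrow(patches); P <- ncol(patches)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (P < 1) stop("no training patches", call. = FALSE)
  w <- as.integer(round(sqrt(w2)))
  eta_eff <- min(eta, P)
  out <- with_seed(seed, {
    st <- state
    if (is.null(st)) {
      D0 <- if (!is.null(D_init)) {
        stopifnot(inherits(D_init, "dlpr_dictionary"))
        if (nrow(D_init$atoms) != w2 || ncol(D_init$atoms) != k)
          stop("`D_init` shape does not match (w^2, k)", call. = FALSE)
        D_init$atoms
      } else codl_init(patches, k, eta_eff)
      st <- codl_state(D0, k)
    }
    if (T_iters > 0) {
      # epoch-wise sampling without replacement
      order_pool <- sample.int(P)
      pos <- 1L
      for (t in seq_len(T_iters)) {
        if (pos + eta_eff - 1L > P) { order_pool <- sample.int(P); pos <- 1L }
        sel <- order_pool[pos:(pos + eta_eff - 1L)]
        pos <- pos + eta_eff
        Xb <- patches[, sel, drop = FALSE]
        Alpha <- l1_code_batch(Xb, st$D, lambda, inner_iters, tol, rho)
        st$A <- st$A + Alpha %*% Conj(t(Alpha))
        st$B <- st$B + Xb %*% Conj(t(Alpha))
        st <- update_atoms(st)
        st <- purge_duplicate_atoms(st, Xb, Alpha)
        st$t <- st$t + 1L
      }
    }
    st
  })
  dict <- new_dictionary(out$D, w)
  if (return_state) list(dictionary = dict, state = out) else dict
}
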