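#' Build the (normalized) structural Laplacian
#'
#' Forms the graph Laplacian L = D - A of a structural connectome, where D is
#' the diagonal matrix of weighted degrees, and normalizes it by its largest
#' eigenvalue, L' = L / lambda_max, so that the spectrum lies in [0, 1]
#' irrespective of network size or density. The eigendecomposition itself is
#' deferred to \code{\link{eigendecompose}}.
#'
#' @param sc a \code{\link{structural_connectome}}.
#' @return An object of class \code{eigenmode_basis} with elements \code{L},
#'   \code{D}, \code{L_norm}, \code{lambda_max_raw}, and (until
#'   \code{eigendecompose} is called) \code{U = NULL}, \code{lambda = NULL}.
#' @export
build_laplacian <- function(sc) {
  stopifnot(inherits(sc, "structural_connectome"))
  A <- sc$A
  d <- rowSums(A)
  L <- diag(d) - A
  # symmetric by construction; eigenvalues real and >= 0
  lambda_max_raw <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (lambda_max_raw <= 0) stop("degenerate Laplacian (no edges?)")
  structure(list(L = L, D = d, L_norm = L / lambda_max_raw,
                 lambda_max_raw = lambda_max_raw,
                 U = NULL, lambda = NULL,
                 region_ids = sc$region_ids),
            class = "eigenmode_basis")
}

#' Eigendecompose the normalized Laplacian
#'
#' Computes the orthonormal eigenmodes u_k and ascending eigenvalues lambda_k
#' of the normalized Laplacian. Eigenmodes with near-zero eigenvalues sustain
#' global, persistent diffusion patterns ("low frequency"); large eigenvalues
#' correspond to spatially complex, transient patterns ("high frequency").
#'
#' A deterministic sign convention is applied: each eigenvector is flipped so
#' its entry of largest absolute value is positive (ties broken by lowest
#' region index). Within numerically degenerate eigenvalue groups, columns
#' are ordered lexicographically by their sign-fixed entries so repeated runs
#' are bit-identical.
#'
#' @param basis an \code{eigenmode_basis} from \code{\link{build_laplacian}}.
#' @return The basis with \code{U} (N x N, orthonormal columns) and
#'   \code{lambda} (ascending, in [0, 1]) populated.
#' @export
eigendecompose <- function(basis) {
  stopifnot(inherits(basis, "eigenmode_basis"))
  eig <- eigen(basis$L_norm, symmetric = TRUE)
  ord <- order(eig$values)           # eigen() returns descending
  lambda <- eig$values[ord]
  U <- fix_eigenvector_signs(eig$vectors[, ord, drop = FALSE])
  # deterministic ordering inside degenerate eigenvalue groups
  grp <- cumsum(c(TRUE, diff(lambda) > 1e-10))
  for (g in unique(grp[duplicated(grp)])) {
    idx <- which(grp == g)
    if (length(idx) > 1L) {
      key <- as.data.frame(t(U[, idx, drop = FALSE]))
      U[, idx] <- U[, idx[do.call(order, key)], drop = FALSE]
    }
  }
  lambda[abs(lambda) < 1e-12] <- 0
  basis$U <- U
  basis$lambda <- lambda
  basis
}

fix_eigenvector_signs <- function(U) {
  for (k in seq_len(ncol(U))) {
    j <- which.max(abs(U[, k]))      # lowest index wins ties
    if (U[j, k] < 0) U[, k] <- -U[, k]
  }
  U
}

#' Select a low- or high-frequency eigenmode band
#'
#' The low-frequency band of order K comprises eigenmodes 2..K (the constant
#' mode u_1 is excluded; it is carried as the regression intercept). The
#' high-frequency band of order K comprises eigenmodes K..N. The defaults
#' used on a 1000-region connectome are K_L = 14 and K_H = 434.
#'
#' @param basis a decomposed \code{eigenmode_basis}.
#' @param kind \code{"low"} or \code{"high"}.
#' @param K band threshold index, 2 <= K <= N.
#' @return An object of class \code{frequency_band} with \code{kind},
#'   \code{K}, and \code{mode_indices}.
#' @export
select_band <- function(basis, kind = c("low", "high"), K) {
  stopifnot(inherits(basis, "eigenmode_basis"), !is.null(basis$lambda))
  kind <- match.arg(kind)
  n <- length(basis$lambda)
  K <- as.integer(K)
  if (K < 2L || K > n)
    stop(sprintf("band threshold K=%d out of range [2, %d]", K, n))
  idx <- if (kind == "low") seq(2L, K) else seq(K, n)
  structure(list(kind = kind, K = K, mode_indices = idx),
            class = "frequency_band")
}

#' Align an eigenmode basis to a reference basis
#'
#' Eigenmodes computed from two similar connectomes (e.g. two subject
#' subsets) can swap order where eigenvalues cross, and carry arbitrary
#' signs. This reorders and sign-flips the columns of \code{basis$U} to
#' maximize |cosine| with the same-index reference mode, by greedy matching
#' restricted to a local index window.
#'
#' @param basis,reference decomposed \code{eigenmode_basis} objects on the
#'   same region set.
#' @param window half-width (in mode indices) of the candidate window for
#'   matching; default 10.
#' @return \code{basis} with columns permuted and sign-flipped; the applied
#'   permutation and signs are stored in attributes \code{"alignment_perm"}
#'   and \code{"alignment_sign"} of the returned object's \code{U}.
#' @export
align_eigenmodes <- function(basis, reference, window = 10L) {
  stopifnot(inherits(basis, "eigenmode_basis"),
            inherits(reference, "eigenmode_basis"),
            !is.null(basis$U), !is.null(reference$U))
  n <- ncol(basis$U)
  if (ncol(reference$U) != n) stop("bases must have the same region count")
  C <- crossprod(reference$U, basis$U)   # C[k, j] = <ref_k, basis_j>
  perm <- integer(n)
  taken <- logical(n)
  # greedy by reference index: mode 1 (constant) first, then ascending
  for (k in seq_len(n)) {
    lo <- max(1L, k - window)
    hi <- min(n, k + window)
    cand <- seq(lo, hi)
    cand <- cand[!taken[cand]]
    if (!length(cand)) cand <- which(!taken)  # window exhausted: fall back
    j <- cand[which.max(abs(C[k, cand]))]
    perm[k] <- j
    taken[j] <- TRUE
  }
  sgn <- sign(C[cbind(seq_len(n), perm)])
  sgn[sgn == 0] <- 1
  U <- sweep(basis$U[, perm, drop = FALSE], 2L, sgn, `*`)
  attr(U, "alignment_perm") <- perm
  attr(U, "alignment_sign") <- sgn
  basis$U <- U
  basis$lambda <- basis$lambda[perm]
  basis
}

#' Pseudo-eigenmode surrogate
#'
#' Draws a unit-norm random vector from the span of the \code{window}
#' eigenmodes whose eigenvalues are nearest lambda_k (a random direction on
#' that subsphere). The surrogate preserves the approximate spatial frequency
#' of mode k by construction, while randomizing its spatial phase, and is
#' orthogonal to the constant mode u_1 (mode 1 is never in the window).
#'
#' @param basis decomposed \code{eigenmode_basis}.
#' @param k target mode index, 2 <= k <= N.
#' @param window number of modes in the spectral window (odd, >= 1); windows
#'   reaching past the ends of the spectrum are truncated (with a message).
#' @param seed optional integer seed.
#' @return Numeric vector of length N, unit norm.
#' @export
pseudo_eigenmode <- function(basis, k, window = 21L, seed = NULL) {
  stopifnot(inherits(basis, "eigenmode_basis"), !is.null(basis$U))
  n <- ncol(basis$U)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("mode index k out of range [2, N]")
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  idx <- pseudo_window_indices(n, k, window)
  with_seed(seed, {
    coef <- stats::rnorm(length(idx))
    v <- drop(basis$U[, idx, drop = FALSE] %*% coef)
    v / sqrt(sum(v^2))
  })
}

# spectral window of `window` modes nearest index k, excluding the constant
# mode; truncated at the spectrum boundary
pseudo_window_indices <- function(n, k, window) {
  half <- window %/% 2L
  lo <- k - half
  hi <- k + half
  if (lo < 2L) { lo <- 2L }
  if (hi > n) { hi <- n }
  idx <- seq(lo, hi)
  if (length(idx) < window)
    message(sprintf("pseudo-eigenmode window truncated to %d modes at the spectrum boundary",
                    length(idx)))
  idx
}

#' Heat-kernel functional connectivity prediction
#'
#' Under the linear network-diffusion model dx/dt = -beta * L' x, activity
#' evolving from a unit impulse at region i reaches, at a critical time
#' t_crit, the configuration exp(-beta L' t_crit) e_i. Collecting all
#' regions' columns yields the predicted whole-brain functional connectivity
#' matrix, evaluated here in spectral form U diag(exp(-beta lambda_k
#' t_crit)) U'.
#'
#' @param basis decomposed \code{eigenmode_basis}.
#' @param beta decay rate (> 0).
#' @param t_crit critical time (>= 0).
#' @return N x N predicted connectivity matrix.
#' @export
heat_kernel_fc <- function(basis, beta, t_crit) {
  stopifnot(inherits(basis, "eigenmode_basis"), !is.null(basis$U))
  if (beta <= 0) stop("beta must be positive")
  if (t_crit < 0) stop("t_crit must be nonnegative")
  w <- exp(-beta * basis$lambda * t_crit)
  basis$U %*% (w * t(basis$U))
}

#' @rdname heat_kernel_fc
#' @param i region index whose diffusion profile (column i of the kernel,
#'   i.e. the configuration evolving from an impulse at region i) is wanted.
#' @export
heat_kernel_profile <- function(basis, beta, t_crit, i) {
  stopifnot(i >= 1L, i <= ncol(basis$U))
  w <- exp(-beta * basis$lambda * t_crit)
  drop(basis$U %*% (w * basis$U[i, ]))
}

#' @export
print.eigenmode_basis <- function(x, ...) {
  cat(sprintf("eigenmode_basis: %d regions, lambda_max(L) = %.4g, %s\n",
              nrow(x$L), x$lambda_max_raw,
              if (is.null(x$U)) "not yet decomposed"
              else sprintf("normalized spectrum [0, %.3g]", max(x$lambda))))
  invisible(x)
}
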