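#' Fit the regional multilinear eigenmode model
#'
#' Regresses region i's empirical functional connectivity profile (column i
#' of the functional matrix, self-connection excluded) on the eigenmodes of
#' a frequency band, with the constant eigenmode u_1 carried as the
#' intercept term. Coefficients are ordinary least squares; the coupling
#' statistic R is the Pearson correlation between predicted and empirical
#' profiles.
#'
#' @param fc a \code{\link{functional_connectome}}.
#' @param basis a decomposed \code{eigenmode_basis}.
#' @param band a \code{frequency_band} from \code{\link{select_band}}.
#' @param i region index.
#' @param exclude_diagonal drop the self-connection from both fitting and R
#'   (default TRUE; the unit diagonal is trivial and would inflate fits).
#' @return An object of class \code{regional_fit}: list with \code{region},
#'   \code{intercept} (coefficient on u_1), \code{coefficients} (one per
#'   band mode), \code{predicted}, \code{observed}, and \code{R}.
#' @export
fit_region <- function(fc, basis, band, i, exclude_diagonal = TRUE) {
  stopifnot(inherits(fc, "functional_connectome"),
            inherits(basis, "eigenmode_basis"), !is.null(basis$U),
            inherits(band, "frequency_band"))
  n <- ncol(basis$U)
  if (nrow(fc$F) != n) stop("functional and structural dimensions disagree")
  i <- as.integer(i)
  stopifnot(i >= 1L, i <= n)
  rows <- if (exclude_diagonal) setdiff(seq_len(n), i) else seq_len(n)
  y <- fc$F[rows, i]
  X <- cbind(basis$U[rows, 1L], basis$U[rows, band$mode_indices, drop = FALSE])
  # the full basis (modes 2..N plus the constant) spans the N-1 retained
  # observations exactly and is permitted; anything larger is rejected
  if (ncol(X) > length(y) + 1L)
    stop(sprintf("rank-deficient design: band of %d predictors (+1 constant) exceeds %d observations",
                 length(band$mode_indices), length(y)))
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  pred <- drop(X %*% beta)
  structure(list(region = i, intercept = beta[[1L]],
                 coefficients = stats::setNames(beta[-1L],
                                                paste0("u", band$mode_indices)),
                 predicted = pred, observed = y,
                 R = stats::cor(pred, y),
                 band = band),
            class = "regional_fit")
}

#' Regional coupling map for a frequency band
#'
#' Applies \code{\link{fit_region}} to every region and collects the
#' coupling values R, the per-region quantification of how well the band's
#' eigenmodes reproduce each region's functional connectivity profile.
#'
#' @inheritParams fit_region
#' @param keep_fits also return the full list of regional fits.
#' @return An object of class \code{coupling_map}: list with \code{R}
#'   (length-N numeric, named by region), \code{band}, and fit metadata.
#' @export
coupling_map <- function(fc, basis, band, exclude_diagonal = TRUE,
                         keep_fits = FALSE) {
  n <- ncol(basis$U)
  fits <- lapply(seq_len(n), function(i)
    fit_region(fc, basis, band, i, exclude_diagonal = exclude_diagonal))
  R <- vapply(fits, `[[`, 0, "R")
  names(R) <- basis$region_ids
  structure(list(R = R, band = band,
                 exclude_diagonal = exclude_diagonal,
                 fits = if (keep_fits) fits else NULL),
            class = "coupling_map")
}

#' @export
print.coupling_map <- function(x, ...) {
  cat(sprintf("coupling_map (%s band, K=%d): N=%d, R in [%.3f, %.3f], mean %.3f\n",
              x$band$kind, x$band$K, length(x$R), min(x$R), max(x$R),
              mean(x$R)))
  invisible(x)
}

#' Whole-brain eigenmode expansion fit
#'
#' Fits the functional matrix as an aggregation of eigenmode outer products
#' F-hat = sum_k c_k u_k u_k', estimating the diagonal coefficients c_k by
#' least squares. By default only off-diagonal entries enter the fit and R;
#' with \code{exclude_diagonal = FALSE} and the full orthonormal basis the
#' solution equals the spectral projection c_k = u_k' F u_k.
#'
#' @param fc a \code{\link{functional_connectome}}.
#' @param basis a decomposed \code{eigenmode_basis}.
#' @param mode_indices eigenmode indices included in the expansion.
#' @param exclude_diagonal fit off-diagonal entries only (default TRUE).
#' @return An object of class \code{whole_brain_fit}: list with \code{c}
#'   (named coefficients), \code{R} (Pearson correlation over the fitted
#'   entries), and \code{predicted} (N x N matrix).
#' @export
whole_brain_fit <- function(fc, basis, mode_indices,
                            exclude_diagonal = TRUE) {
  stopifnot(inherits(fc, "functional_connectome"),
            inherits(basis, "eigenmode_basis"), !is.null(basis$U),
            length(mode_indices) >= 1L)
  U <- basis$U
  n <- ncol(U)
  if (nrow(fc$F) != n) stop("functional and structural dimensions disagree")
  sel <- if (exclude_diagonal) row(fc$F) != col(fc$F) else
    matrix(TRUE, n, n)
  y <- fc$F[sel]
  X <- vapply(mode_indices,
              function(k) tcrossprod(U[, k])[sel],
              numeric(sum(sel)))
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  pred_vec <- drop(X %*% beta)
  pred <- matrix(0, n, n)
  pred[sel] <- pred_vec
  structure(list(c = stats::setNames(beta, paste0("u", mode_indices)),
                 R = stats::cor(pred_vec, y),
                 predicted = pred,
                 mode_indices = mode_indices,
                 exclude_diagonal = exclude_diagonal),
            class = "whole_brain_fit")
}

#' z score of a single eigenmode's whole-brain prediction
#'
#' Fits the whole-brain expansion with mode k alone (plus the constant mode
#' u_1), then repeats the fit with pseudo-eigenmode surrogates of matched
#' spatial frequency and returns (R_obs - mean_null) / sd_null.
#'
#' @param fc a \code{\link{functional_connectome}}.
#' @param basis a decomposed \code{eigenmode_basis}.
#' @param k eigenmode index (>= 2).
#' @param n_null number of pseudo-eigenmode draws (>= 100).
#' @param window spectral window passed to \code{\link{pseudo_eigenmode}}.
#' @param seed optional integer seed.
#' @return Scalar z score, with the observed R and the null ensemble
#'   attached as attributes \code{"observed"} and \code{"null"}.
#' @export
single_mode_z <- function(fc, basis, k, n_null = 1000L, window = 21L,
                          seed = NULL) {
  stopifnot(n_null >= 100L)
  U <- basis$U
  n <- ncol(U)
  sel <- row(fc$F) != col(fc$F)
  y <- fc$F[sel]
  x0 <- tcrossprod(U[, 1L])[sel]
  fit_R <- function(v) {
    X <- cbind(x0, tcrossprod(v)[sel])
    beta <- qr.coef(qr(X), y)
    beta[is.na(beta)] <- 0
    stats::cor(drop(X %*% beta), y)
  }
  R_obs <- fit_R(U[, k])
  idx <- pseudo_window_indices(n, k, window)
  null_R <- with_seed(seed, {
    vapply(seq_len(n_null), function(b) {
      coef <- stats::rnorm(length(idx))
      v <- drop(U[, idx, drop = FALSE] %*% coef)
      fit_R(v / sqrt(sum(v^2)))
    }, 0)
  })
  s <- stats::sd(null_R)
  if (s == 0) stop("pseudo-eigenmode null has zero variance")
  z <- (R_obs - mean(null_R)) / s
  attr(z, "observed") <- R_obs
  attr(z, "null") <- null_R
  z
}
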