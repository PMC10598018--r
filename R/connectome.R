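#' Structural connectome
#'
#' Container for a weighted, undirected structural brain network: a symmetric,
#' nonnegative adjacency matrix with a zero diagonal, optionally annotated
#' with 3-D region coordinates (used by the spin test) and resting-state
#' network labels (used by network-level aggregation).
#'
#' @param A numeric N x N adjacency matrix; symmetric within 1e-10,
#'   nonnegative, zero diagonal, and connected as a graph.
#' @param region_ids character vector of length N; defaults to
#'   \code{"R001"..}.
#' @param coordinates optional N x 3 numeric matrix of region positions.
#' @param labels optional character vector of network labels, one per region.
#' @return An object of class \code{structural_connectome} with elements
#'   \code{A}, \code{region_ids}, \code{coordinates}, \code{labels}.
#' @export
structural_connectome <- function(A, region_ids = NULL, coordinates = NULL,
                                  labels = NULL) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (n < 2L || ncol(A) != n)
    stop("adjacency must be a square matrix with at least 2 regions")
  if (max(abs(A - t(A))) > 1e-10)
    stop("adjacency must be symmetric (tolerance 1e-10)")
  A <- (A + t(A)) / 2
  if (any(A < 0)) stop("adjacency must be nonnegative")
  if (any(diag(A) != 0)) stop("adjacency diagonal must be exactly zero")
  if (!is_connected_adjacency(A))
    stop("structural connectome is disconnected")
  if (is.null(region_ids)) region_ids <- default_region_ids(n)
  if (length(region_ids) != n) stop("region_ids length must equal N")
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    if (nrow(coordinates) != n || ncol(coordinates) != 3L)
      stop("coordinates must be an N x 3 matrix")
    rownames(coordinates) <- region_ids
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("labels length must equal N")
  }
  dimnames(A) <- list(region_ids, region_ids)
  structure(list(A = A, region_ids = region_ids, coordinates = coordinates,
                 labels = labels),
            class = "structural_connectome")
}

#' Functional connectome
#'
#' Container for a symmetric matrix of interregional correlations with unit
#' diagonal. Off-diagonal entries are expected in [-1, 1]; a zeroed
#' (bootstrap-thresholded) entry is permitted.
#'
#' @param F_mat numeric N x N correlation matrix; symmetric within 1e-10.
#' @param region_ids character vector of length N, aligned with the
#'   structural connectome's ordering.
#' @return An object of class \code{functional_connectome} with elements
#'   \code{F} and \code{region_ids}.
#' @export
functional_connectome <- function(F_mat, region_ids = NULL) {
  F_mat <- as.matrix(F_mat)
  n <- nrow(F_mat)
  if (ncol(F_mat) != n) stop("functional matrix must be square")
  if (max(abs(F_mat - t(F_mat))) > 1e-10)
    stop("functional matrix must be symmetric (tolerance 1e-10)")
  F_mat <- (F_mat + t(F_mat)) / 2
  if (max(abs(diag(F_mat) - 1)) > 1e-10)
    stop("functional matrix diagonal must be 1")
  if (max(abs(F_mat)) > 1 + 1e-10)
    stop("functional correlations must lie in [-1, 1]")
  if (is.null(region_ids)) region_ids <- default_region_ids(n)
  if (length(region_ids) != n) stop("region_ids length must equal N")
  dimnames(F_mat) <- list(region_ids, region_ids)
  structure(list(F = F_mat, region_ids = region_ids),
            class = "functional_connectome")
}

#' @export
print.structural_connectome <- function(x, ...) {
  cat(sprintf("structural_connectome: %d regions, %d edges, total weight %.4g\n",
              nrow(x$A), sum(x$A[upper.tri(x$A)] > 0), sum(x$A) / 2))
  if (!is.null(x$coordinates)) cat("  with coordinates\n")
  if (!is.null(x$labels))
    cat(sprintf("  with labels: %s\n",
                paste(sort(unique(x$labels)), collapse = ", ")))
  invisible(x)
}

#' @export
print.functional_connectome <- function(x, ...) {
  off <- x$F[upper.tri(x$F)]
  cat(sprintf("functional_connectome: %d regions, off-diagonal range [%.3f, %.3f]\n",
              nrow(x$F), min(off), max(off)))
  invisible(x)
}

default_region_ids <- function(n) sprintf("R%03d", seq_len(n))

# connectivity check on the binarized adjacency (BFS; no igraph round-trip
# needed for plain matrices)
is_connected_adjacency <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[[1L]]
    queue <- queue[-1L]
    nb <- which(A[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the global
# RNG stream is restored afterwards so seeded calls do not perturb callers.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

offdiag <- function(M) M[row(M) != col(M)]

upper_vec <- function(M) M[upper.tri(M)]
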