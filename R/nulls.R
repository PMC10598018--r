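#' Null ensemble container
#'
#' Holds per-replicate statistic values for one null-model family together
#' with the machinery inputs of the empirical-p / z computations.
#'
#' @param kind one of \code{"label_perm"}, \code{"spin"}, \code{"rewire"},
#'   \code{"degree_spatial"}, \code{"pseudo_mode"}.
#' @param samples numeric vector of replicate statistic values (finite).
#' @param seed optional seed used to generate the ensemble.
#' @return An object of class \code{null_ensemble}.
#' @export
null_ensemble <- function(kind, samples, seed = NULL) {
  kind <- match.arg(kind, c("label_perm", "spin", "rewire",
                            "degree_spatial", "pseudo_mode"))
  samples <- as.numeric(samples)
  if (length(samples) < 1L || !all(is.finite(samples)))
    stop("samples must be a nonempty finite numeric vector")
  structure(list(kind = kind, samples = samples, n = length(samples),
                 seed = seed),
            class = "null_ensemble")
}

#' Empirical p value from a null ensemble
#'
#' Computes p = (1 + #\{null values at least as extreme as observed\}) /
#' (1 + n), the standard permutation p with a +1 small-sample correction
#' that avoids p = 0; the reporting floor is 1/(n+1). The raw proportion of
#' at-least-as-extreme null values (which can be exactly 0, supporting
#' "P < 1e-4"-style statements at n = 10,000) is attached as attribute
#' \code{"raw_proportion"}. Two-sided p doubles the smaller tail, capped
#' at 1.
#'
#' @param observed observed statistic.
#' @param ensemble a \code{null_ensemble} or bare numeric vector of null
#'   statistics.
#' @param side \code{"greater"}, \code{"less"} or \code{"two_sided"}.
#' @return p value with attribute \code{"raw_proportion"}.
#' @export
empirical_p <- function(observed, ensemble,
                        side = c("greater", "less", "two_sided")) {
  side <- match.arg(side)
  s <- if (inherits(ensemble, "null_ensemble")) ensemble$samples else
    as.numeric(ensemble)
  n <- length(s)
  stopifnot(n >= 1L, is.finite(observed))
  k_g <- sum(s >= observed)
  k_l <- sum(s <= observed)
  p <- switch(side,
              greater = (1 + k_g) / (1 + n),
              less = (1 + k_l) / (1 + n),
              two_sided = min(1, 2 * min((1 + k_g) / (1 + n),
                                         (1 + k_l) / (1 + n))))
  attr(p, "raw_proportion") <- switch(side,
                                      greater = k_g / n,
                                      less = k_l / n,
                                      two_sided = min(k_g, k_l) / n)
  p
}

#' z score relative to a null ensemble
#'
#' @inheritParams empirical_p
#' @return (observed - null mean) / null s.d.
#' @export
z_from_null <- function(observed, ensemble) {
  s <- if (inherits(ensemble, "null_ensemble")) ensemble$samples else
    as.numeric(ensemble)
  sdv <- stats::sd(s)
  if (!is.finite(sdv) || sdv == 0) stop("null ensemble has zero variance")
  (observed - mean(s)) / sdv
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment p_(i) * m / i with cumulative-minimum monotonicity
#' enforcement, capped at 1.
#'
#' @param pvals numeric p values in [0, 1].
#' @param q FDR level for the rejection set (default 0.05).
#' @return List with \code{adjusted} (same order as input) and
#'   \code{rejected} (logical).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  p <- as.numeric(pvals)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
  list(adjusted = adj, rejected = adj <= q)
}

#' Network-label permutation test of coupling
#'
#' Tests whether each functional network's mean coupling R differs from the
#' level expected when regions' network assignments are randomly permuted.
#' Per permutation, every network's mean R is recomputed under shuffled
#' labels; empirical p values use the proportion rule (two-sided by
#' doubling the smaller tail, or one-sided on request), and are FDR
#' corrected across networks.
#'
#' @param coupling a \code{coupling_map} or numeric vector of per-region R.
#' @param labels character vector of network names, one per region.
#' @param n number of permutations (default 10000, >= 100).
#' @param side tail convention for the empirical p (default two-sided).
#' @param seed optional integer seed.
#' @return data.frame with one row per network: \code{network},
#'   \code{n_regions}, \code{mean_R}, \code{z}, \code{p}, \code{p_fdr},
#'   plus the full null ensemble list as attribute \code{"ensembles"}.
#' @export
label_permutation_test <- function(coupling, labels, n = 10000L,
                                   side = c("two_sided", "greater", "less"),
                                   seed = NULL) {
  side <- match.arg(side)
  r <- if (inherits(coupling, "coupling_map")) coupling$R else
    as.numeric(coupling)
  if (length(labels) != length(r)) stop("every region must be labeled")
  if (anyNA(labels)) stop("every region must be labeled")
  if (n < 100L) stop("n must be >= 100")
  labels <- as.character(labels)
  nets <- sort(unique(labels))
  sizes <- table(labels)[nets]
  if (any(sizes == 0)) stop("network with zero members")
  obs <- tapply(r, labels, mean)[nets]
  N <- length(r)
  with_seed(seed, {
    null_means <- matrix(NA_real_, n, length(nets),
                         dimnames = list(NULL, nets))
    for (b in seq_len(n)) {
      rp <- r[sample.int(N)]
      null_means[b, ] <- tapply(rp, labels, mean)[nets]
    }
    p <- vapply(nets, function(k)
      as.numeric(empirical_p(obs[[k]], null_means[, k], side = side)), 0)
    z <- vapply(nets, function(k) {
      s <- stats::sd(null_means[, k])
      if (s == 0) {
        # degenerate (e.g. constant coupling): observed equals every
        # permuted value, so the z score is 0 by convention
        if (obs[[k]] == mean(null_means[, k])) 0 else
          sign(obs[[k]] - mean(null_means[, k])) * Inf
      } else z_from_null(obs[[k]], null_means[, k])
    }, 0)
    out <- data.frame(network = nets,
                      n_regions = as.integer(sizes),
                      mean_R = as.numeric(obs),
                      z = z, p = p,
                      p_fdr = fdr_bh(p)$adjusted,
                      row.names = NULL)
    attr(out, "ensembles") <- lapply(nets, function(k)
      null_ensemble("label_perm", null_means[, k], seed = seed))
    names(attr(out, "ensembles")) <- nets
    out
  })
}

#' Spin permutations of spherical region coordinates
#'
#' Spatial-autocorrelation-preserving permutations: per replicate, a uniform
#' random 3-D rotation is applied to the (sphere-projected) coordinates and
#' each original region is reassigned to its nearest rotated region by
#' greedy one-to-one matching. A map m is spun as \code{m[perm]}.
#'
#' @param coordinates N x 3 matrix of region positions (projected to the
#'   unit sphere internally).
#' @param n number of spin replicates.
#' @param seed optional integer seed.
#' @return List of n integer permutations of 1..N.
#' @export
spin_permutation <- function(coordinates, n, seed = NULL) {
  X <- as.matrix(coordinates)
  if (ncol(X) != 3L) stop("coordinates must be N x 3")
  ctr <- scale(X, center = TRUE, scale = FALSE)
  if (qr(ctr)$rank < 2L) stop("degenerate coordinates (collinear)")
  X <- X / sqrt(rowSums(X^2))
  with_seed(seed, {
    lapply(seq_len(n), function(b) {
      R <- random_rotation()
      greedy_nearest_matching(X, X %*% t(R))
    })
  })
}

# uniform random rotation: QR of a Gaussian matrix, sign-fixed, det +1
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

# one-to-one greedy matching by ascending pairwise distance;
# perm[i] = rotated region assigned to original slot i
greedy_nearest_matching <- function(orig, rotated) {
  n <- nrow(orig)
  D <- outer(rowSums(orig^2), rowSums(rotated^2), `+`) -
    2 * tcrossprod(orig, rotated)
  ord <- order(D)
  perm <- integer(n)
  row_free <- rep(TRUE, n)
  col_free <- rep(TRUE, n)
  left <- n
  for (idx in ord) {
    i <- ((idx - 1L) %% n) + 1L
    j <- ((idx - 1L) %/% n) + 1L
    if (row_free[i] && col_free[j]) {
      perm[i] <- j
      row_free[i] <- FALSE
      col_free[j] <- FALSE
      left <- left - 1L
      if (left == 0L) break
    }
  }
  perm
}

#' Degree-preserving weighted rewiring
#'
#' Maslov-Sneppen double-edge swaps that carry edge weights with the edges:
#' repeatedly picks two edges (a,b) and (c,d) with four distinct endpoints
#' and replaces them by (a,d) and (c,b) when neither creates a self-loop or
#' multi-edge. The binary degree sequence, edge count, and weight multiset
#' are preserved exactly; connectivity is re-checked and the whole
#' randomization resampled if broken.
#'
#' @param sc a \code{\link{structural_connectome}}.
#' @param n_swaps attempted swaps; default 10x the edge count.
#' @param seed optional integer seed.
#' @param max_restarts resampling budget when rewiring disconnects the
#'   graph (default 20).
#' @return A rewired \code{\link{structural_connectome}} (coordinates and
#'   labels retained); attribute \code{"n_accepted"} counts accepted swaps.
#' @export
rewire_preserving_degree <- function(sc, n_swaps = NULL, seed = NULL,
                                     max_restarts = 20L) {
  stopifnot(inherits(sc, "structural_connectome"))
  edges <- which(upper.tri(sc$A) & sc$A > 0, arr.ind = TRUE)
  m <- nrow(edges)
  if (m < 2L) stop("need at least 2 edges to rewire")
  if (is.null(n_swaps)) n_swaps <- 10L * m
  with_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      A <- sc$A
      accepted <- 0L
      for (t in seq_len(n_swaps)) {
        e <- sample.int(m, 2L)
        a <- edges[e[1L], 1L]; b <- edges[e[1L], 2L]
        c_ <- edges[e[2L], 1L]; d <- edges[e[2L], 2L]
        if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
        if (length(unique(c(a, b, c_, d))) < 4L) next
        if (A[a, d] > 0 || A[c_, b] > 0) next
        w1 <- A[a, b]; w2 <- A[c_, d]
        A[a, b] <- A[b, a] <- 0
        A[c_, d] <- A[d, c_] <- 0
        A[a, d] <- A[d, a] <- w1
        A[c_, b] <- A[b, c_] <- w2
        edges[e[1L], ] <- c(min(a, d), max(a, d))
        edges[e[2L], ] <- c(min(c_, b), max(c_, b))
        accepted <- accepted + 1L
      }
      if (is_connected_adjacency(A)) {
        if (restart > 1L)
          message(sprintf("rewiring reconnected after %d restart(s)", restart - 1L))
        out <- structural_connectome(A, region_ids = sc$region_ids,
                                     coordinates = sc$coordinates,
                                     labels = sc$labels)
        attr(out, "n_accepted") <- accepted
        return(out)
      }
    }
    stop("swap budget exhausted without a connected result")
  })
}

#' Degree-preserving spatial null connectome
#'
#' Builds a surrogate that keeps no structural information except the
#' binary degree sequence: a new simple connected topology is sampled from
#' the degree sequence, the original weight multiset is randomly reassigned
#' to the new edges, and the original coordinates (and labels) are
#' retained.
#'
#' @param sc a \code{\link{structural_connectome}}.
#' @param seed optional integer seed.
#' @return A surrogate \code{\link{structural_connectome}}.
#' @export
degree_preserving_spatial_null <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "structural_connectome"))
  deg <- as.integer(rowSums(sc$A > 0))
  w <- sc$A[upper.tri(sc$A)]
  w <- w[w > 0]
  with_seed(seed, {
    g <- tryCatch(
      igraph::sample_degseq(deg, method = "vl"),
      error = function(e)
        stop(sprintf("degree sequence not realizable as a connected simple graph: %s",
                     conditionMessage(e))))
    el <- igraph::as_edgelist(g, names = FALSE)
    A <- matrix(0, nrow(sc$A), ncol(sc$A))
    wshuf <- sample(w)
    A[el] <- wshuf
    A <- A + t(A) - diag(diag(A))
    structural_connectome(A, region_ids = sc$region_ids,
                          coordinates = sc$coordinates,
                          labels = sc$labels)
  })
}
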