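#' Aggregate a coupling map by functional networks
#'
#' Descriptive statistics of per-region coupling R within each network
#' label: mean, median, interquartile range, and min-max range (the
#' boxplot summaries), plus member counts.
#'
#' @param coupling a \code{coupling_map} or numeric vector of per-region R.
#' @param labels character network label per region.
#' @return data.frame with one row per network: \code{network}, \code{n},
#'   \code{mean_R}, \code{median_R}, \code{q25}, \code{q75}, \code{min_R},
#'   \code{max_R}.
#' @export
aggregate_by_network <- function(coupling, labels) {
  r <- if (inherits(coupling, "coupling_map")) coupling$R else
    as.numeric(coupling)
  if (length(labels) != length(r) || anyNA(labels))
    stop("every region must be labeled")
  labels <- as.character(labels)
  nets <- sort(unique(labels))
  rows <- lapply(nets, function(k) {
    x <- r[labels == k]
    if (!length(x)) stop(sprintf("empty network '%s'", k))
    data.frame(network = k, n = length(x),
               mean_R = mean(x), median_R = stats::median(x),
               q25 = unname(stats::quantile(x, 0.25)),
               q75 = unname(stats::quantile(x, 0.75)),
               min_R = min(x), max_R = max(x))
  })
  out <- do.call(rbind, rows)
  stopifnot(sum(out$n) == length(r))
  out
}

#' Well-predicted-node distribution versus network size
#'
#' Regions whose coupling R exceeds the grand mean over regions are "well
#' predicted". Returns, per network, the share of well-predicted regions it
#' contains next to its share of all regions; each share vector sums to 1.
#'
#' @inheritParams aggregate_by_network
#' @return data.frame with \code{network}, \code{well_predicted_share},
#'   \code{size_share}, and \code{n_well}; attribute
#'   \code{"threshold"} carries the grand-mean cutoff. A degenerate
#'   (constant) coupling map yields an empty well-predicted set and a
#'   warning.
#' @export
well_predicted_distribution <- function(coupling, labels) {
  r <- if (inherits(coupling, "coupling_map")) coupling$R else
    as.numeric(coupling)
  if (length(labels) != length(r) || anyNA(labels))
    stop("every region must be labeled")
  labels <- as.character(labels)
  nets <- sort(unique(labels))
  thr <- mean(r)
  well <- r > thr
  if (!any(well))
    warning("degenerate coupling map: no region strictly above the mean")
  n_well <- vapply(nets, function(k) sum(well & labels == k), 0L)
  n_all <- vapply(nets, function(k) sum(labels == k), 0L)
  out <- data.frame(network = nets,
                    n_well = n_well,
                    well_predicted_share =
                      if (any(well)) n_well / sum(well) else NA_real_,
                    size_share = n_all / length(r),
                    row.names = NULL)
  attr(out, "threshold") <- thr
  out
}

#' Per-region z map against network permutation nulls
#'
#' Transforms each region's coupling R into a z score relative to the
#' permutation null distribution of its own network's mean R (the ensembles
#' produced by \code{\link{label_permutation_test}}).
#'
#' @inheritParams aggregate_by_network
#' @param ensembles named list of \code{null_ensemble}s, one per network
#'   (attribute \code{"ensembles"} of the label permutation test result).
#' @return Numeric vector of per-region z scores.
#' @export
network_z_map <- function(coupling, labels, ensembles) {
  r <- if (inherits(coupling, "coupling_map")) coupling$R else
    as.numeric(coupling)
  labels <- as.character(labels)
  if (!all(labels %in% names(ensembles)))
    stop("missing permutation ensemble for some network")
  vapply(seq_along(r), function(i)
    z_from_null(r[[i]], ensembles[[labels[[i]]]]), 0)
}

#' Inter-subject variability of regional coupling
#'
#' Per-region standard deviation and coefficient of variation of coupling R
#' across subjects, plus the Pearson correlations of both with the mean
#' coupling map (the floor-effect diagnostics: a high sd-vs-mean
#' correlation that vanishes for CV-vs-mean indicates variability tracking
#' the mean level).
#'
#' @param R_matrix subjects x regions matrix of coupling values.
#' @return List with per-region \code{mean}, \code{sd}, \code{cv} (NA and
#'   flagged where the mean is not positive), \code{cor_sd_mean},
#'   \code{cor_cv_mean}.
#' @export
intersubject_variability <- function(R_matrix) {
  R_matrix <- as.matrix(R_matrix)
  if (nrow(R_matrix) < 2L) stop("need at least 2 subjects")
  m <- colMeans(R_matrix)
  s <- apply(R_matrix, 2L, stats::sd)
  cv <- ifelse(m > 0, s / m, NA_real_)
  if (anyNA(cv))
    warning(sprintf("CV undefined (mean <= 0) for %d region(s)", sum(is.na(cv))))
  safe_cor <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok])
  }
  list(mean = m, sd = s, cv = cv,
       cor_sd_mean = safe_cor(s, m),
       cor_cv_mean = safe_cor(cv, m))
}

#' One-way ANOVA of coupling across regions
#'
#' Region is the factor, subjects are replicates: tests whether mean
#' coupling differs across regions. Degenerate inputs (zero within-region
#' variance with nonzero between-region variance) yield an infinite F with
#' a warning.
#'
#' @param R_matrix subjects x regions matrix of coupling values.
#' @return List with \code{F}, \code{df1} (regions - 1), \code{df2}
#'   (regions x (subjects - 1)), and \code{p}.
#' @export
one_way_anova <- function(R_matrix) {
  R_matrix <- as.matrix(R_matrix)
  S <- nrow(R_matrix)
  n <- ncol(R_matrix)
  if (S < 2L || n < 2L) stop("need >= 2 subjects and >= 2 regions")
  grand <- mean(R_matrix)
  m <- colMeans(R_matrix)
  ss_between <- S * sum((m - grand)^2)
  ss_within <- sum(sweep(R_matrix, 2L, m)^2)
  df1 <- n - 1L
  df2 <- n * (S - 1L)
  if (ss_within == 0 && ss_between == 0)
    return(list(F = 0, df1 = df1, df2 = df2, p = 1))
  if (ss_within == 0) {
    warning("zero within-region variance: F is infinite")
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  }
  Fstat <- (ss_between / df1) / (ss_within / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}
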