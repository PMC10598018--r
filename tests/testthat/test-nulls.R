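test_that("empirical p follows the +1 proportion rule", {
  # 10-value null with 3 values >= observed: p = (1+3)/(1+10)
  nulls <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  p <- empirical_p(7.5, nulls, side = "greater")
  expect_equal(as.numeric(p), 4 / 11)
  expect_equal(attr(p, "raw_proportion"), 0.3)
  # observed at the median: p ~ 0.5 either side
  expect_equal(as.numeric(empirical_p(5.5, nulls, side = "greater")),
               6 / 11)
  # observed beyond all nulls at n = 10000: reported floor 1/(n+1),
  # raw proportion exactly 0 (the "P < 1e-4" convention)
  big <- seq_len(10000) / 10001
  p0 <- empirical_p(2, big, side = "greater")
  expect_equal(as.numeric(p0), 1 / 10001)
  expect_identical(attr(p0, "raw_proportion"), 0)
  # two-sided doubles the smaller tail, capped at 1
  expect_lte(as.numeric(empirical_p(5.5, nulls, side = "two_sided")), 1)
})

test_that("BH adjustment matches the hand computation and p.adjust", {
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.5))
  expect_equal(out$adjusted, c(0.04, 0.04, 0.04, 0.5))
  # all equal p stay equal
  expect_equal(fdr_bh(rep(0.2, 5))$adjusted, rep(0.2, 5))
  # independent oracle on random vectors
  set.seed(1)
  for (rep in 1:5) {
    p <- runif(20)^2
    adj <- fdr_bh(p)$adjusted
    expect_equal(adj, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("z_from_null standardizes against the ensemble", {
  ens <- null_ensemble("label_perm", c(1, 2, 3, 4, 5))
  expect_equal(z_from_null(3, ens), 0)
  expect_equal(z_from_null(3 + 2 * sd(1:5), ens), 2)
  expect_error(z_from_null(1, rep(2, 10)), "variance")
  # calibration: z of a null draw against its peers is ~N(0, 1)
  set.seed(2)
  zs <- replicate(1000, {
    x <- rnorm(200)
    z_from_null(x[[1]], x[-1])
  })
  expect_lt(abs(mean(zs)), 0.1)
  expect_gt(sd(zs), 0.9)
  expect_lt(sd(zs), 1.1)
})

test_that("label permutation test degenerates gracefully and finds effects", {
  labs <- rep(c("a", "b", "c", "d"), each = 25)
  # constant coupling: all z = 0, all p = 1
  out <- label_permutation_test(rep(0.5, 100), labs, n = 100, seed = 1)
  expect_true(all(out$z == 0))
  expect_true(all(out$p == 1))
  # a planted 5-sd elevation in one network hits the resolution floor
  set.seed(3)
  r <- rnorm(100, 0.5, 0.05)
  r[labs == "b"] <- r[labs == "b"] + 5 * 0.05 / sqrt(25) * sqrt(100 / 25)
  out2 <- label_permutation_test(r, labs, n = 999, seed = 2)
  expect_lt(out2$p[out2$network == "b"], 0.01)
  labs_na <- labs
  labs_na[[7]] <- NA
  expect_error(label_permutation_test(r, labs_na, n = 100), "labeled")
})

test_that("spin permutations are bijections built from real rotations", {
  sc <- fixture_sc()
  perms <- spin_permutation(sc$coordinates, n = 20, seed = 4)
  expect_length(perms, 20)
  for (p in perms) expect_setequal(p, 1:100)
  # identity rotation maps every region to itself
  X <- sc$coordinates / sqrt(rowSums(sc$coordinates^2))
  expect_identical(eigencoupling:::greedy_nearest_matching(X, X), 1:100)
  # degenerate (collinear) coordinates are rejected
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(spin_permutation(line, 5, seed = 1), "degenerate|collinear")
})

test_that("spin test preserves autocorrelation-driven type-I error", {
  # two independent smooth maps on the sphere: the spin test's p should be
  # roughly uniform while a naive i.i.d. permutation test over-rejects
  basis <- fixture_basis()
  sc <- fixture_sc()
  spins <- spin_permutation(sc$coordinates, n = 200, seed = 10)
  smooth_map <- function() drop(basis$U[, 2:6] %*% rnorm(5))
  set.seed(11)
  n_rep <- 120
  rej_spin <- 0; rej_naive <- 0
  for (rep in seq_len(n_rep)) {
    x <- smooth_map(); y <- smooth_map()
    obs <- cor(x, y)
    null_spin <- vapply(spins, function(p) cor(x[p], y), 0)
    null_naive <- replicate(200, cor(sample(x), y))
    if (as.numeric(empirical_p(obs, null_spin, "two_sided")) <= 0.05)
      rej_spin <- rej_spin + 1
    if (as.numeric(empirical_p(obs, null_naive, "two_sided")) <= 0.05)
      rej_naive <- rej_naive + 1
  }
  # binomial 95% band around 0.05 for 120 trials: [0.011, 0.089]
  expect_gte(rej_spin / n_rep, 0.011)
  expect_lte(rej_spin / n_rep, 0.089)
  # the naive test over-rejects on autocorrelated maps
  expect_gt(rej_naive / n_rep, 0.15)
})

test_that("rewiring conserves degrees and weights exactly", {
  sc <- generate_structural_connectome(30, density = 0.2, seed = 6)
  for (s in 1:5) {
    rw <- rewire_preserving_degree(sc, seed = s)
    expect_identical(rowSums(rw$A > 0), rowSums(sc$A > 0))
    expect_equal(sort(rw$A[upper.tri(rw$A) & rw$A > 0]),
                 sort(sc$A[upper.tri(sc$A) & sc$A > 0]), tolerance = 1e-15)
    expect_equal(sum(rw$A), sum(sc$A), tolerance = 1e-12)
    expect_true(eigencoupling:::is_connected_adjacency(rw$A))
  }
})

test_that("edge overlap decreases with the swap budget (in expectation)", {
  sc <- generate_structural_connectome(30, density = 0.2, seed = 6)
  m <- sum(sc$A[upper.tri(sc$A)] > 0)
  jacc <- function(B) {
    a <- sc$A > 0; b <- B > 0
    sum(a & b & upper.tri(a)) / sum((a | b) & upper.tri(a))
  }
  j_small <- mean(vapply(1:25, function(s)
    jacc(rewire_preserving_degree(sc, n_swaps = 5, seed = s)$A), 0))
  j_big <- mean(vapply(1:25, function(s)
    jacc(rewire_preserving_degree(sc, n_swaps = 10 * m, seed = s)$A), 0))
  expect_gt(j_small, j_big)
})

test_that("degree-preserving spatial null keeps degrees, weights, coordinates", {
  sc <- generate_structural_connectome(40, density = 0.2, seed = 7)
  null <- degree_preserving_spatial_null(sc, seed = 8)
  expect_identical(rowSums(null$A > 0), rowSums(sc$A > 0))
  expect_equal(sort(null$A[upper.tri(null$A) & null$A > 0]),
               sort(sc$A[upper.tri(sc$A) & sc$A > 0]), tolerance = 1e-15)
  expect_identical(null$coordinates, sc$coordinates)
  # surrogate eigenmodes decorrelate from the originals far more than a
  # 1%-jitter control does
  b0 <- eigendecompose(build_laplacian(sc))
  bn <- align_eigenmodes(eigendecompose(build_laplacian(null)), b0)
  set.seed(9)
  J <- matrix(1, 40, 40)
  J[upper.tri(J)] <- rlnorm(sum(upper.tri(J)), 0, 0.01)
  J[lower.tri(J)] <- t(J)[lower.tri(J)]
  bj <- align_eigenmodes(eigendecompose(build_laplacian(
    structural_connectome(sc$A * J, coordinates = sc$coordinates))), b0)
  cos_null <- mean(abs(colSums(bn$U * b0$U))[-1])
  cos_jitter <- mean(abs(colSums(bj$U * b0$U))[-1])
  expect_lt(cos_null, cos_jitter)
})
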