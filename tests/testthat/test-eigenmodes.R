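test_that("path-graph Laplacian matches the closed form", {
  basis <- build_laplacian(path3_sc())
  expect_equal(basis$L,
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3,
                      dimnames = dimnames(basis$L)))
  expect_equal(basis$lambda_max_raw, 3, tolerance = 1e-12)
  basis <- eigendecompose(basis)
  expect_equal(basis$lambda, c(0, 1 / 3, 1), tolerance = 1e-12)
})

test_that("complete-graph spectrum is {0, n, ..., n} and normalizes to {0, 1, ..., 1}", {
  basis <- eigendecompose(build_laplacian(complete_sc(4)))
  raw <- basis$lambda * basis$lambda_max_raw
  expect_equal(raw, c(0, 4, 4, 4), tolerance = 1e-10)
  expect_equal(basis$lambda, c(0, 1, 1, 1), tolerance = 1e-12)
})

test_that("Laplacian invariants hold on generated connectomes", {
  basis <- fixture_basis()
  n <- nrow(basis$L)
  # zero row sums; constant vector annihilated
  expect_lt(max(abs(rowSums(basis$L))), 1e-10)
  expect_lt(max(abs(basis$L %*% rep(1, n))), 1e-10)
  # normalized spectrum in [0, 1], ascending, lambda_1 = 0
  expect_true(all(diff(basis$lambda) >= 0))
  expect_equal(basis$lambda[[1]], 0, tolerance = 1e-10)
  expect_lte(max(basis$lambda), 1 + 1e-12)
  # orthonormality and constant first mode
  expect_lt(max(abs(crossprod(basis$U) - diag(n))), 1e-8)
  expect_equal(basis$U[, 1], rep(1 / sqrt(n), n), tolerance = 1e-8)
})

test_that("eigenvalues match an independent characteristic-polynomial solve", {
  set.seed(3)
  A <- matrix(0, 5, 5)
  A[upper.tri(A)] <- runif(10, 0.2, 1)
  A <- A + t(A)
  basis <- eigendecompose(build_laplacian(structural_connectome(A)))
  oracle <- charpoly_roots(basis$L_norm)
  expect_equal(basis$lambda, oracle, tolerance = 1e-8)
})

test_that("eigendecomposition is deterministic (sign convention)", {
  b1 <- eigendecompose(build_laplacian(fixture_sc()))
  b2 <- eigendecompose(build_laplacian(fixture_sc()))
  expect_identical(b1$U, b2$U)
  expect_identical(b1$lambda, b2$lambda)
  # sign convention: largest-|entry| element positive
  expect_true(all(apply(b1$U, 2, function(u) u[which.max(abs(u))] > 0)))
})

test_that("invalid structural input is rejected", {
  A <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(structural_connectome(A), "symmetric")
  expect_error(structural_connectome(matrix(c(0, -1, -1, 0), 2, 2)),
               "nonnegative")
  expect_error(structural_connectome(diag(3)), "diagonal")
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 1; A[3, 4] <- A[4, 3] <- 1
  expect_error(structural_connectome(A), "disconnected")
})

test_that("select_band produces the documented index sets", {
  basis <- fixture_basis()
  n <- length(basis$lambda)
  low <- select_band(basis, "low", 14)
  expect_identical(low$mode_indices, 2:14)   # 13 predictors
  high <- select_band(basis, "high", 44)
  expect_identical(high$mode_indices, 44:n)
  expect_error(select_band(basis, "low", 1), "out of range")
  expect_error(select_band(basis, "high", n + 1), "out of range")
})

test_that("full low band gives exact regional fits", {
  basis <- fixture_basis()
  fc <- random_fc(100, seed = 5)
  band <- select_band(basis, "low", 100)   # all non-constant modes
  fit <- fit_region(fc, basis, band, 17)
  expect_equal(fit$R, 1, tolerance = 1e-10)
})

test_that("align_eigenmodes recovers identity, sign flips, and jittered order", {
  basis <- fixture_basis()
  al <- align_eigenmodes(basis, basis)
  expect_identical(attr(al$U, "alignment_perm"), seq_along(basis$lambda))
  expect_true(all(attr(al$U, "alignment_sign") == 1))

  flipped <- basis
  flipped$U[, 5] <- -flipped$U[, 5]
  al <- align_eigenmodes(flipped, basis)
  expect_equal(attr(al$U, "alignment_sign")[[5]], -1)
  expect_equal(al$U[, 5], basis$U[, 5])

  # 1%-jittered connectome: alignment never decreases mean |cosine|
  set.seed(8)
  sc <- fixture_sc()
  J <- matrix(1, 100, 100)
  J[upper.tri(J)] <- rlnorm(sum(upper.tri(J)), 0, 0.01)
  J[lower.tri(J)] <- t(J)[lower.tri(J)]
  jb <- eigendecompose(build_laplacian(
    structural_connectome(sc$A * J, coordinates = sc$coordinates)))
  before <- mean(abs(colSums(jb$U * basis$U)))
  after <- mean(abs(colSums(align_eigenmodes(jb, basis)$U * basis$U)))
  expect_gte(after, before)
})

test_that("greedy alignment is near the exhaustive optimum on N=12", {
  set.seed(12)
  repeat {
    A <- matrix(0, 12, 12)
    A[upper.tri(A)] <- runif(66) * (runif(66) < 0.5)
    A <- A + t(A)
    if (eigencoupling:::is_connected_adjacency(A)) break
  }
  ref <- eigendecompose(build_laplacian(structural_connectome(A)))
  J <- matrix(1, 12, 12)
  J[upper.tri(J)] <- rlnorm(66, 0, 0.05)
  J[lower.tri(J)] <- t(J)[lower.tri(J)]
  other <- eigendecompose(build_laplacian(structural_connectome(A * J)))
  C <- abs(crossprod(ref$U, other$U))
  # exhaustive search over window-2 permutations
  best <- local({
    n <- 12L
    rec <- function(k, used, acc) {
      if (k > n) return(acc)
      cand <- setdiff(max(1, k - 2):min(n, k + 2), used)
      if (!length(cand)) return(-Inf)
      max(vapply(cand, function(j) rec(k + 1L, c(used, j), acc + C[k, j]), 0))
    }
    rec(1L, integer(), 0)
  })
  al <- align_eigenmodes(other, ref, window = 2)
  greedy <- sum(abs(colSums(ref$U * al$U)))
  expect_lte(greedy, best + 1e-8)
  expect_gte(greedy, 0.9 * best)
})

test_that("pseudo-eigenmodes preserve norm, orthogonality to u_1, and spectral band", {
  basis <- fixture_basis()
  # window = 1 returns +/- u_k
  v <- pseudo_eigenmode(basis, 20, window = 1, seed = 1)
  expect_equal(abs(sum(v * basis$U[, 20])), 1, tolerance = 1e-10)
  # draws: unit norm, orthogonal to u_1, energy inside the window
  set.seed(2)
  lam_rng <- range(basis$lambda[eigencoupling:::pseudo_window_indices(100, 50, 21)])
  for (draw in 1:25) {
    v <- pseudo_eigenmode(basis, 50, window = 21)
    expect_equal(sum(v^2), 1, tolerance = 1e-10)
    expect_lt(abs(sum(v * basis$U[, 1])), 1e-10)
    w <- drop(crossprod(basis$U, v))^2
    mean_lambda <- sum(w * basis$lambda)
    expect_gte(mean_lambda, lam_rng[[1]] - 1e-10)
    expect_lte(mean_lambda, lam_rng[[2]] + 1e-10)
  }
  # boundary truncation is logged
  expect_message(pseudo_eigenmode(basis, 99, window = 21, seed = 1),
                 "truncated")
})

test_that("heat kernel matches the matrix exponential and conserves activity", {
  set.seed(4)
  A <- matrix(0, 50, 50)
  A[upper.tri(A)] <- runif(sum(upper.tri(A))) * (runif(sum(upper.tri(A))) < 0.3)
  A <- A + t(A)
  sc <- structural_connectome(A)
  basis <- eigendecompose(build_laplacian(sc))
  hk <- heat_kernel_fc(basis, beta = 1, t_crit = 0.7)
  oracle <- as.matrix(Matrix::expm(-1 * basis$L_norm * 0.7))
  expect_lt(max(abs(hk - oracle)), 1e-8)
  # t = 0 -> identity; t -> Inf -> projector onto the constant mode
  expect_equal(heat_kernel_fc(basis, 1, 0), diag(50), tolerance = 1e-10)
  expect_equal(heat_kernel_fc(basis, 1, 1e8),
               matrix(1 / 50, 50, 50), tolerance = 1e-8)
  # column sums of exp(-beta L t) x conserve sum(x)
  x <- rnorm(50)
  expect_equal(sum(hk %*% x), sum(x), tolerance = 1e-8)
  # profile accessor = column of the kernel
  expect_equal(heat_kernel_profile(basis, 1, 0.7, 3), hk[, 3],
               tolerance = 1e-12)
  expect_error(heat_kernel_fc(basis, -1, 1), "beta")
})
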