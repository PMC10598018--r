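test_that("generated connectomes satisfy the structural invariants", {
  for (cfg in list(c(n = 40, d = 0.2), c(n = 80, d = 0.1), c(n = 60, d = 0.5))) {
    sc <- generate_structural_connectome(cfg[["n"]], density = cfg[["d"]],
                                         seed = 11)
    A <- sc$A
    expect_identical(dim(A), rep(as.integer(cfg[["n"]]), 2))
    expect_lt(max(abs(A - t(A))), 1e-12)
    expect_true(all(A >= 0))
    expect_true(all(diag(A) == 0))
    expect_true(eigencoupling:::is_connected_adjacency(A))
    expect_identical(dim(sc$coordinates), c(as.integer(cfg[["n"]]), 3L))
  }
})

test_that("full density yields a complete weighted graph", {
  sc <- generate_structural_connectome(4, density = 1, seed = 1)
  expect_true(all(sc$A[upper.tri(sc$A)] > 0))
})

test_that("generation is seed-reproducible and weights decay with distance", {
  a <- generate_structural_connectome(100, density = 0.1, seed = 1)
  b <- generate_structural_connectome(100, density = 0.1, seed = 1)
  expect_identical(a$A, b$A)
  expect_identical(a$coordinates, b$coordinates)
  d <- as.matrix(dist(a$coordinates))
  sel <- upper.tri(d) & a$A > 0
  expect_lt(cor(a$A[sel], d[sel], method = "spearman"), 0)
})

test_that("ground truth has one coefficient row per region, one column per mode", {
  basis <- fixture_basis()
  gt <- fixture_world()$gt
  expect_identical(dim(gt$band_weights), dim(basis$U))
  expect_length(gt$planted_gradient, 100)
  expect_true(all(abs(gt$planted_gradient) <= 1))
  # the split partitions the regions
  expect_setequal(c(gt$unimodal, gt$transmodal), 1:100)
})

test_that("planted functional connectomes are valid correlation-like matrices", {
  fc <- fixture_world()$fc
  expect_lt(max(abs(fc$F - t(fc$F))), 1e-12)
  expect_true(all(diag(fc$F) == 1))
  expect_true(all(abs(fc$F) <= 1))
})

test_that("noiseless band-confined weights give exact band fits", {
  basis <- fixture_basis()
  # all-low world: every region's low-band R is 1 to machine precision
  gt_low <- synthetic_ground_truth(basis, planted_gradient = rep(-1, 100),
                                   noise_sigma = 0, seed = 3)
  fc_low <- suppressMessages(plant_functional_connectome(basis, gt_low))
  cm <- coupling_map(fc_low, basis, select_band(basis, "low", gt_low$K_L))
  expect_gt(min(cm$R), 1 - 1e-10)
  # all-high world: exact in the high band, near-zero in the low band
  gt_high <- synthetic_ground_truth(basis, planted_gradient = rep(1, 100),
                                    noise_sigma = 0, seed = 3)
  fc_high <- suppressMessages(plant_functional_connectome(basis, gt_high))
  cm_h <- coupling_map(fc_high, basis, select_band(basis, "high", gt_high$K_H))
  expect_gt(min(cm_h$R), 1 - 1e-10)
  cm_l <- coupling_map(fc_high, basis, select_band(basis, "low", gt_high$K_L))
  expect_lt(mean(cm_l$R), 0.35)
})

test_that("OLS recovers planted coefficients (normal-equations oracle)", {
  basis <- fixture_basis()
  gt <- synthetic_ground_truth(basis, planted_gradient = rep(-1, 100),
                               noise_sigma = 0.05, seed = 9)
  fc <- suppressMessages(plant_functional_connectome(basis, gt))
  band <- select_band(basis, "low", gt$K_L)
  for (i in c(4, 57)) {
    fit <- fit_region(fc, basis, band, i)
    # independent normal-equations solve on the same design
    X <- cbind(basis$U[-i, 1], basis$U[-i, band$mode_indices])
    y <- fc$F[-i, i]
    beta <- solve(crossprod(X), crossprod(X, y))
    expect_equal(unname(c(fit$intercept, fit$coefficients)),
                 drop(beta), tolerance = 1e-8)
    # per-region parameter recovery at noise 0.05
    expect_gte(cor(fit$coefficients, gt$band_weights[i, band$mode_indices]),
               0.99)
  }
})

test_that("time series reproduce the target correlation structure", {
  # identity target: off-diagonal sample correlations vanish
  fc_id <- functional_connectome(diag(20))
  X <- generate_time_series(fc_id, 10000, seed = 1)
  R <- cor(t(X))
  expect_lt(max(abs(R[upper.tri(R)])), 0.05)
  # seeded draws are identical
  expect_identical(X, generate_time_series(fc_id, 10000, seed = 1))
  # one planted r = 0.8 pair recovered within ~3 standard errors of the
  # closed-form sampling s.e. (1 - r^2)/sqrt(T)
  F2 <- diag(20); F2[1, 2] <- F2[2, 1] <- 0.8
  X2 <- generate_time_series(functional_connectome(F2), 5000, seed = 2)
  expect_lt(abs(cor(X2[1, ], X2[2, ]) - 0.8), 0.03)
})

test_that("PSD repair is applied (and reported) for indefinite targets", {
  fc <- fixture_world()$fc   # clipped + noisy: indefinite in general
  if (min(eigen(fc$F, symmetric = TRUE, only.values = TRUE)$values) < 0) {
    expect_message(generate_time_series(fc, 10, seed = 1), "PSD repair")
  }
  S <- eigencoupling:::nearest_psd_correlation(fc$F)
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(diag(S), rep(1, 100), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("group bootstrap keeps real edges and zeroes null edges", {
  n <- 12
  F_true <- diag(n)
  F_true[1, 2] <- F_true[2, 1] <- 0.9
  fc <- functional_connectome(F_true)
  series <- lapply(1:2, function(s)
    generate_time_series(fc, 2000, seed = s))
  out <- suppressMessages(
    group_fc_bootstrap(series, n_boot = 200, sample_len = 276, seed = 3))
  expect_gt(out$F[1, 2], 0.8)            # strong pair retained
  # null pairs (everything not involving the planted pair) mostly zeroed:
  # retention probability is ~alpha = 0.05 per pair
  null_entries <- out$F[upper.tri(out$F)][-1]
  expect_lt(mean(null_entries != 0), 0.20)
  # defaults reproduce the stated bootstrap settings
  expect_identical(formals(group_fc_bootstrap)$n_boot, 1000L)
  expect_identical(formals(group_fc_bootstrap)$sample_len, 276L)
  expect_error(
    suppressMessages(group_fc_bootstrap(series, sample_len = 10000)),
    "exceeds")
})

test_that("subject sets jitter the template reproducibly", {
  sc <- fixture_sc()
  gt <- fixture_world()$gt
  # zero jitter: structural matrices identical to the template
  s0 <- suppressMessages(
    generate_subject_set(sc, gt, n_subjects = 3, subject_noise = 0, seed = 1))
  for (s in s0$subjects) expect_identical(s$sc$A, sc$A)
  # seeded ensembles are reproducible
  s1 <- suppressMessages(
    generate_subject_set(sc, gt, n_subjects = 3, subject_noise = 0.1, seed = 2))
  s2 <- suppressMessages(
    generate_subject_set(sc, gt, n_subjects = 3, subject_noise = 0.1, seed = 2))
  expect_identical(s1$subjects[[3]]$sc$A, s2$subjects[[3]]$sc$A)
  expect_identical(s1$subjects[[3]]$fc$F, s2$subjects[[3]]$fc$F)
})

test_that("mean subject SC converges to the template (law of large numbers)", {
  sc <- fixture_sc()
  gt <- fixture_world()$gt
  set_ <- suppressMessages(
    generate_subject_set(sc, gt, n_subjects = 20, subject_noise = 0.1,
                         seed = 5))
  Abar <- Reduce(`+`, lapply(set_$subjects, function(s) s$sc$A)) / 20
  pos <- sc$A > 0
  rel_err <- abs(Abar[pos] - sc$A[pos]) / sc$A[pos]
  # jitter s.e. of the mean is ~0.1/sqrt(20) = 0.022 per edge
  expect_lt(mean(rel_err), 3 * 0.1 / sqrt(20))
})
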