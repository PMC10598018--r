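# Shared fixtures, built once per test run and memoized.
.fixtures <- new.env(parent = emptyenv())

# medium synthetic connectome + decomposed basis (n = 100, seed 42)
fixture_basis <- function() {
  if (is.null(.fixtures$basis)) {
    sc <- generate_structural_connectome(100, seed = 42)
    .fixtures$sc <- sc
    .fixtures$basis <- eigendecompose(build_laplacian(sc))
  }
  .fixtures$basis
}

fixture_sc <- function() {
  fixture_basis()
  .fixtures$sc
}

# default mixed-band ground truth + planted functional connectome on the
# fixture connectome
fixture_world <- function() {
  if (is.null(.fixtures$world)) {
    basis <- fixture_basis()
    gt <- synthetic_ground_truth(basis, seed = 7)
    fc <- suppressMessages(plant_functional_connectome(basis, gt))
    .fixtures$world <- list(gt = gt, fc = fc)
  }
  .fixtures$world
}

# tiny graphs with known spectra
path3_sc <- function() {
  A <- matrix(c(0, 1, 0,
                1, 0, 1,
                0, 1, 0), 3, 3)
  structural_connectome(A)
}

complete_sc <- function(n) {
  A <- matrix(1, n, n)
  diag(A) <- 0
  structural_connectome(A)
}

random_fc <- function(n, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * (n + 5)), n)
  functional_connectome(stats::cor(t(X)))
}

# characteristic-polynomial coefficients by the Faddeev-LeVerrier
# recursion: an eigenvalue oracle independent of LAPACK
charpoly_roots <- function(M) {
  n <- nrow(M)
  coefs <- numeric(n + 1)  # lambda^n + c1 lambda^(n-1) + ... + cn
  coefs[1] <- 1
  Mk <- diag(n)
  for (k in seq_len(n)) {
    Mk <- M %*% Mk
    ck <- -sum(diag(Mk)) / k
    coefs[k + 1] <- ck
    Mk <- Mk + ck * diag(n)
  }
  sort(Re(polyroot(rev(coefs))))
}
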