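# shared fixtures, built once per test run

# brute-force mass-balance oracle for the free-protomer concentration:
# root of sum_{i=1}^{1e5} i KA^{i-1} c1^i = ctot by bisection
oracle_protomer_conc <- function(ctot, KA) {
  if (KA == 0 || ctot == 0) return(ctot)
  f <- function(c1) {
    i <- 1:1e5
    r <- KA * c1
    c1 * sum(i * r^(i - 1)) - ctot
  }
  upper <- min(ctot, (1 - 1e-12) / KA)
  stats::uniroot(f, c(0, upper), tol = 1e-15)$root
}

.fixture_env <- new.env(parent = emptyenv())

# small noiseless synthetic system: 8 species, 20 conformers, 20 q-points
tiny_sim_noiseless <- function() {
  if (is.null(.fixture_env$tiny0)) {
    .fixture_env$tiny0 <- simulate_series(
      synthetic_spec(), kd_true = 1.6, noise_level = 0,
      n_conformers = 20, nmax = 8, q = seq(0.01, 0.4, length.out = 20),
      seed = 101)
  }
  .fixture_env$tiny0
}

# same system with 1% noise
tiny_sim_noisy <- function() {
  if (is.null(.fixture_env$tiny1)) {
    .fixture_env$tiny1 <- simulate_series(
      synthetic_spec(), kd_true = 1.6, noise_level = 0.01,
      n_conformers = 20, nmax = 8, q = seq(0.01, 0.4, length.out = 20),
      seed = 202)
  }
  .fixture_env$tiny1
}

# an ensemble built directly from given intensity rows (no I(0) check)
raw_ensemble <- function(Imat, q = NULL, size = 2, w0 = NULL) {
  if (is.null(q)) q <- seq(0.01, by = 0.01, length.out = ncol(Imat))
  oligomer_ensemble(size, q, Imat, weights0 = w0, check_i0 = FALSE)
}
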