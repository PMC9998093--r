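test_that("schedule constructors validate their parameters", {
  s <- annealing_schedule()
  expect_equal(s$T_start, 10)
  expect_equal(s$T_end, 0.1)
  expect_equal(s$T_decay, 0.30)
  expect_equal(s$proposal_sigma, 0.1)
  expect_error(annealing_schedule(T_start = 0.01, T_end = 0.1))
  o <- outer_schedule()
  expect_equal(o$n_iterations, 1000)
  expect_equal(o$theta_start, 100)
  expect_equal(o$theta_decay, 0.02)
  expect_equal(o$phi_eff_cutoff, 0.4)
  expect_error(outer_schedule(theta_start = -1))
  # the default ladder runs from T = 10 down to just above 0.1, -30% per step
  ladder <- isodesmix:::.temp_ladder(annealing_schedule())
  expect_equal(ladder[1], 10)
  expect_true(all(ladder >= 0.1))
  expect_equal(ladder[-1] / ladder[-length(ladder)],
               rep(0.7, length(ladder) - 1), tolerance = 1e-12)
})

test_that("a frozen annealing chain leaves KA unchanged", {
  sim <- tiny_sim_noisy()
  res <- fit_ka_annealed(sim$series, sim$ensembles, ka_start = 0.4,
                         schedule = annealing_schedule(T_start = 1, T_end = 1,
                                                       proposal_sigma = 0),
                         seed = 1)
  expect_equal(res$KA, 0.4)
})

test_that("annealing recovers the generative KA on noiseless data", {
  sim <- tiny_sim_noiseless()
  set.seed(2)
  ka <- 1.2
  # repeated sweeps with a shrinking proposal act like a global optimiser
  for (sig in c(0.1, 0.05, 0.02, 0.01, 0.005)) {
    res <- fit_ka_annealed(sim$series, sim$ensembles, ka_start = ka,
                           schedule = annealing_schedule(proposal_sigma = sig))
    ka <- res$KA
  }
  expect_equal(ka, 1 / 1.6, tolerance = 0.05)
})

test_that("annealing sweeps are bit-identical under a fixed seed", {
  sim <- tiny_sim_noisy()
  r1 <- fit_ka_annealed(sim$series, sim$ensembles, ka_start = 0.5, seed = 77)
  r2 <- fit_ka_annealed(sim$series, sim$ensembles, ka_start = 0.5, seed = 77)
  expect_identical(r1$KA, r2$KA)
  expect_identical(r1$chi2r_global, r2$chi2r_global)
})

test_that("refinement with reweighting disabled reduces to a pure isodesmic fit", {
  sim <- tiny_sim_noisy()
  fit <- refine_saxs(sim$series, sim$ensembles,
                     outer = outer_schedule(n_iterations = 5, theta_start = 1e12,
                                            theta_decay = 0),
                     ka_start = 0.8, seed = 31)
  for (l in seq_along(sim$series)) {
    for (i in seq_along(sim$ensembles)) {
      expect_equal(fit$weights[[l]][[i]], sim$ensembles[[i]]$w0, tolerance = 1e-6)
    }
  }
  expect_gt(min(fit$phi_eff), 1 - 1e-6)
})

test_that("a phi_eff cutoff of 1 freezes theta immediately and keeps weights near the prior", {
  sim <- tiny_sim_noisy()
  fit <- refine_saxs(sim$series, sim$ensembles,
                     outer = outer_schedule(n_iterations = 8, phi_eff_cutoff = 1),
                     ka_start = 0.8, seed = 32)
  expect_true(all(fit$frozen))
  expect_equal(fit$theta, rep(100, length(sim$ensembles)))
  for (i in seq_along(sim$ensembles)) {
    expect_lt(max(abs(fit$weights[[1]][[i]] - sim$ensembles[[i]]$w0)), 0.02)
  }
})

test_that("full refinement is deterministic under a fixed seed and reduces chi2", {
  sim <- tiny_sim_noisy()
  outer <- outer_schedule(n_iterations = 25)
  f1 <- refine_saxs(sim$series, sim$ensembles, outer = outer, ka_start = 0.9, seed = 55)
  f2 <- refine_saxs(sim$series, sim$ensembles, outer = outer, ka_start = 0.9, seed = 55)
  expect_identical(f1$KA, f2$KA)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$chi2_history, f2$chi2_history)
  expect_lte(f1$chi2r_global, f1$chi2r_global_initial + 0.05)
  expect_true(all(is.finite(f1$chi2_history$chi2r_global)))
  # weights stay normalised throughout
  for (l in seq_along(sim$series)) {
    sums <- vapply(f1$weights[[l]], sum, numeric(1))
    expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)
  }
  gl <- glance(f1)
  expect_equal(gl$kd, 1 / f1$KA)
  td <- tidy(f1)
  expect_equal(nrow(td), length(sim$series) * length(sim$ensembles) * 20)
})

test_that("weight averaging follows the relative signal contributions", {
  # identical weights across experiments are unchanged
  w <- list(list(c(0.2, 0.8), c(0.5, 0.5)), list(c(0.2, 0.8), c(0.5, 0.5)))
  d1 <- tibble::tibble(i = 1:2, conc = c(1, 0.1))
  d2 <- tibble::tibble(i = 1:2, conc = c(2, 0.8))
  avg <- average_weights(w, list(d1, d2))
  expect_equal(avg$weights[[1]], c(0.2, 0.8))
  expect_equal(rowSums(avg$rho), c(1, 1))
  # hand-set two-experiment case for one species
  wa <- c(1, 0); wb <- c(0, 1)
  w2 <- list(list(wa), list(wb))
  da <- tibble::tibble(i = 1, conc = 2)   # s = 1 in both (single species)
  # rig the signal shares via concentrations: rho proportional to s_l
  avg2 <- average_weights(w2, list(da, da))
  expect_equal(avg2$weights[[1]], c(0.5, 0.5))
  # single experiment: identity
  avg3 <- average_weights(list(list(wa)), list(da))
  expect_equal(avg3$weights[[1]], wa)
  expect_equal(avg3$rho[1, 1], 1)
  expect_error(average_weights(list(list(c(0.5, 0.5)), list(c(1, 0, 0) / 1)),
                               list(da, da)), "inconsistent conformer counts")
})

test_that("weight averaging uses hand-computed rho for unequal signal shares", {
  # two species, two experiments; concentrations chosen so species 2's
  # normalised share is 0.2 in experiment 1 and 0.8 in experiment 2
  d1 <- tibble::tibble(i = 1:2, conc = c(4, 0.25))
  d2 <- tibble::tibble(i = 1:2, conc = c(1, 1))
  s1 <- c(4, 1) / 5; s2 <- c(1, 4) / 5
  rho2 <- c(s1[2], s2[2]) / (s1[2] + s2[2])
  wA <- c(1, 0); wB <- c(0, 1)
  w <- list(list(c(0.5, 0.5), wA), list(c(0.5, 0.5), wB))
  avg <- average_weights(w, list(d1, d2))
  expect_equal(avg$rho[2, ], rho2)
  expect_equal(avg$weights[[2]], rho2[1] * wA + rho2[2] * wB)
})

test_that("KD error scan brackets the truth and handles degenerate grids", {
  sim <- tiny_sim_noisy()
  grid <- 10^seq(log10(0.15), log10(15), length.out = 120)
  sc <- kd_error_scan(sim$series, sim$ensembles, kd_grid = grid)
  expect_gte(sim$kd_true, sc$kd_interval[1])
  expect_lte(sim$kd_true, sc$kd_interval[2])
  # the in-band region is a contiguous bracket for this convex landscape
  runs <- rle(sc$scan$in_interval)
  expect_equal(sum(runs$values), 1)
  # single-point grid degenerates to that point
  expect_warning(one <- kd_error_scan(sim$series, sim$ensembles, kd_grid = 2),
                 "boundary")
  expect_equal(one$kd_interval, c(2, 2))
})

test_that("static single-frame scans are reproducible and exact for single-conformer ensembles", {
  sim <- tiny_sim_noisy()
  # single-conformer ensembles: every draw is identical
  singles <- lapply(sim$ensembles, function(e) {
    oligomer_ensemble(e$size_monomer, e$q, e$intensities[1, , drop = FALSE],
                      check_i0 = FALSE)
  })
  grid <- 10^seq(-1, 1, length.out = 80)
  r <- kd_grid_fit_static(sim$series, singles, kd_grid = grid, n_draws = 3, seed = 5)
  expect_equal(length(unique(r$kd_best)), 1)
  expect_equal(length(unique(r$chi2r_global)), 1)
  ra <- kd_grid_fit_static(sim$series, sim$ensembles, kd_grid = grid, n_draws = 4, seed = 9)
  rb <- kd_grid_fit_static(sim$series, sim$ensembles, kd_grid = grid, n_draws = 4, seed = 9)
  expect_identical(ra, rb)
})

test_that("model comparison endpoints reproduce the pure-dimer fit", {
  sim <- tiny_sim_noisy()
  dimer <- sim$ensembles[[1]]
  octa <- sim$ensembles[[4]]
  # KA -> 0 endpoint of the scan equals a monodisperse dimer fit
  cmp0 <- compare_dimer_oligomer(sim$series, dimer, list(octa), ka_grid = 1e-300)
  Ed <- ensemble_average(dimer)
  chi_dimer <- mean(vapply(sim$series, function(p) {
    sb <- fit_scale_background(p$I, p$sigma, Ed)
    chi2_reduced(sb$scale * Ed + sb$cst, p)
  }, numeric(1)))
  expect_equal(cmp0$chi2r_global[cmp0$model == "dimer-oligomer"], chi_dimer,
               tolerance = 1e-9)
  mono <- cmp0[cmp0$model == "monodisperse", ]
  expect_true(is.finite(mono$chi2r_global))
})

test_that("leave-one-out reports the four-cell comparison with finite values", {
  sim <- tiny_sim_noisy()
  loo <- leave_one_out(sim$series, held_out_label = "15uM", sim$ensembles,
                       outer = outer_schedule(n_iterations = 10),
                       ka_start = 0.8, seed = 91)
  expect_equal(nrow(loo$cells), 4)
  expect_true(all(is.finite(loo$cells$chi2r)))
  expect_setequal(loo$cells$weights, c("prior", "fitted"))
  expect_setequal(loo$cells$kd, c("initial", "fitted"))
  expect_error(leave_one_out(sim$series, "nope", sim$ensembles), "not found")
})

test_that("a duplicated held-out profile validates at its training chi2", {
  sim <- tiny_sim_noisy()
  dup <- sim$series[[3]]
  attr(dup, "label") <- "dup"
  series <- c(sim$series, list(dup))
  loo <- leave_one_out(series, held_out_label = "dup", sim$ensembles,
                       outer = outer_schedule(n_iterations = 5),
                       ka_start = 0.8, seed = 92)
  fit <- loo$fit
  # training chi2 of the 15 uM profile, recomputed the same way
  E <- vapply(seq_along(sim$ensembles), function(i) {
    ensemble_average(sim$ensembles[[i]], fit$avg_weights[[i]])
  }, numeric(length(sim$ensembles[[1]]$q)))
  d <- isodesmic_distribution(monomer_to_protomer(15), KA = fit$KA,
                              nmax = length(sim$ensembles))
  I_mix <- as.numeric(E %*% d$phi)
  sb <- fit_scale_background(dup$I, dup$sigma, I_mix)
  chi_train <- chi2_reduced(sb$scale * I_mix + sb$cst, dup)
  expect_equal(loo$cells$chi2r[loo$cells$weights == "fitted" &
                                 loo$cells$kd == "fitted"],
               chi_train, tolerance = 1e-10)
})
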