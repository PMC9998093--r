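#' Simulated-annealing schedule for the association-constant fit
#'
#' Metropolis Monte Carlo with simulated annealing: proposals are Gaussian
#' in KA-space, the temperature starts at `T_start` and is decreased by
#' `T_decay` (fractional) every Monte Carlo step until it falls below
#' `T_end`; non-positive KA proposals are redrawn.
#'
#' @param T_start,T_end annealing temperatures (defaults 10 and 0.1).
#' @param T_decay fractional temperature decrease per step (default 0.30).
#' @param proposal_sigma standard deviation of the Gaussian KA proposal
#'   (µM^-1, default 0.1).
#' @return an `annealing_schedule` list.
#' @export
annealing_schedule <- function(T_start = 10, T_end = 0.1, T_decay = 0.30,
                               proposal_sigma = 0.1) {
  stopifnot(T_start >= T_end, T_end > 0, proposal_sigma >= 0,
            T_decay >= 0, T_decay < 1)
  structure(list(T_start = T_start, T_end = T_end, T_decay = T_decay,
                 proposal_sigma = proposal_sigma), class = "annealing_schedule")
}

#' Outer-loop schedule of the self-consistent optimisation
#'
#' @param n_iterations outer iterations (default 1000).
#' @param theta_start initial BME confidence parameter (default 100).
#' @param theta_decay fractional decrease of theta per iteration
#'   (default 0.02).
#' @param phi_eff_cutoff once a species' fraction of effective frames
#'   drops below this, its theta is no longer decreased (default 0.4).
#' @return an `outer_schedule` list.
#' @export
outer_schedule <- function(n_iterations = 1000, theta_start = 100,
                           theta_decay = 0.02, phi_eff_cutoff = 0.4) {
  stopifnot(n_iterations >= 1, theta_start > 0, theta_decay >= 0,
            theta_decay < 1, phi_eff_cutoff >= 0, phi_eff_cutoff <= 1)
  structure(list(n_iterations = n_iterations, theta_start = theta_start,
                 theta_decay = theta_decay, phi_eff_cutoff = phi_eff_cutoff),
            class = "outer_schedule")
}

# temperature ladder: T_start * (1-decay)^k for k = 0..floor(log(T_end/T_start)/log(1-decay))
.temp_ladder <- function(sched) {
  if (sched$T_decay == 0 || sched$T_start == sched$T_end) return(sched$T_start)
  kmax <- floor(log(sched$T_end / sched$T_start) / log(1 - sched$T_decay) + 1e-12)
  sched$T_start * (1 - sched$T_decay)^(0:max(kmax, 0))
}

# global chi2_r of a KA value given cached per-experiment ensemble-average
# matrices E (m x N) and scale-corrected data
.chi2_of_ka <- function(KA, ctots, E_list, I_list, sig_list, nmax) {
  chis <- vapply(seq_along(E_list), function(l) {
    I_mix <- as.numeric(E_list[[l]] %*% .iso_phi(ctots[l], KA, nmax))
    sum((I_mix - I_list[[l]])^2 / sig_list[[l]]^2) / length(I_mix)
  }, numeric(1))
  mean(chis)
}

# one annealing sweep; returns list(KA, chi2)
.anneal_sweep <- function(ka, sched, ctots, E_list, I_list, sig_list, nmax) {
  chi_old <- .chi2_of_ka(ka, ctots, E_list, I_list, sig_list, nmax)
  for (Temp in .temp_ladder(sched)) {
    repeat {
      ka_new <- stats::rnorm(1, ka, sched$proposal_sigma)
      if (ka_new > 0 || sched$proposal_sigma == 0) break
    }
    if (ka_new <= 0) ka_new <- ka  # sigma == 0 degenerate case
    chi_new <- .chi2_of_ka(ka_new, ctots, E_list, I_list, sig_list, nmax)
    alpha <- exp(-(chi_new - chi_old) / Temp)
    if (alpha > 1 || stats::runif(1) < alpha) {
      ka <- ka_new; chi_old <- chi_new
    }
  }
  list(KA = ka, chi2 = chi_old)
}

#' One simulated-annealing sweep of the global association constant
#'
#' Fits the isodesmic KA globally to a concentration series by Metropolis
#' Monte Carlo with simulated annealing, holding the per-experiment scale
#' and background and the ensemble weights fixed. Each candidate KA is
#' evaluated by recomputing the species distribution, the mixture curve
#' and the global reduced chi-square; acceptance uses
#' \eqn{\alpha = \exp(-(\chi^2_{new} - \chi^2_{old})/T)}.
#'
#' @param series list of [saxs_profile()] with monomer concentrations.
#' @param ensembles list of [oligomer_ensemble()] (protomer index 1..N).
#' @param ka_start starting KA (µM^-1).
#' @param schedule an [annealing_schedule()].
#' @param weights optional list of per-species weight vectors (defaults
#'   to each ensemble's current `w`).
#' @param scale_background optional list of per-experiment `(scale, cst)`;
#'   fitted at `ka_start` when omitted.
#' @param seed optional RNG seed (sweep is deterministic given the seed).
#' @return list with `KA`, `KD`, `chi2r_global`.
#' @export
fit_ka_annealed <- function(series, ensembles, ka_start, schedule = annealing_schedule(),
                            weights = NULL, scale_background = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nmax <- length(ensembles)
  q <- ensembles[[1]]$q
  E <- vapply(seq_len(nmax), function(i) {
    ensemble_average(ensembles[[i]], if (is.null(weights)) NULL else weights[[i]])
  }, numeric(length(q)))
  ctots <- vapply(series, function(p) monomer_to_protomer(attr(p, "conc_monomer")), numeric(1))
  I_list <- list(); sig_list <- list(); E_list <- list()
  for (l in seq_along(series)) {
    d <- isodesmic_distribution(ctots[l], KA = ka_start, nmax = nmax)
    I_mix <- as.numeric(E %*% d$phi)
    sb <- scale_background[[l]] %||% fit_scale_background(series[[l]]$I, series[[l]]$sigma, I_mix)
    pf <- apply_inverse_scale(series[[l]], sb)
    I_list[[l]] <- pf$I; sig_list[[l]] <- pf$sigma; E_list[[l]] <- E
  }
  res <- .anneal_sweep(ka_start, schedule, ctots, E_list, I_list, sig_list, nmax)
  list(KA = res$KA, KD = 1 / res$KA, chi2r_global = res$chi2)
}

#' Self-consistent refinement of oligomer distribution and ensemble weights
#'
#' The three-step iterative optimiser: each outer iteration (1) fits the
#' scale and constant background of every experiment against the current
#' mixture curve, (2) fits the isodesmic KA globally by Metropolis
#' simulated annealing, and (3) for every experiment and every populated
#' species, deconvolutes the species' SAXS profile from the mixture and
#' reweights its conformational ensemble by BME. The BME confidence
#' parameter theta starts high (weights barely move) and decays each
#' iteration; once a species' fraction of effective frames falls below
#' `phi_eff_cutoff` (in any experiment), its theta is frozen.
#'
#' @param series list of [saxs_profile()] (a concentration series); each
#'   must carry its monomer concentration.
#' @param ensembles list of [oligomer_ensemble()] on the experimental
#'   q-grid, protomer index 1..N.
#' @param outer an [outer_schedule()].
#' @param annealing an [annealing_schedule()].
#' @param ka_start initial KA (µM^-1, default 1).
#' @param seed RNG seed; a fixed seed makes the full run deterministic.
#' @param phi_floor species with volume fraction below this in an
#'   experiment are excluded from reweighting for that experiment (they
#'   still contribute to the mixture curve).
#' @param verbose print progress every 100 iterations.
#'
#' @details Because the annealing step re-randomises KA from `T_start`
#' every outer iteration, the iterate sequence is a Markov chain that
#' fluctuates around the self-consistent solution rather than settling
#' pointwise. The returned state (KA, weights, scale/background, theta,
#' phi_eff) is therefore the iterate with the lowest global reduced
#' chi-square; `chi2_history` records the full trajectory and
#' `best_iteration` which iterate was reported.
#'
#' @return a `saxs_refinement` object: list with `KA`, `KD`,
#'   `scale_background` (per experiment), `weights` (per experiment, per
#'   species), `avg_weights` (signal-share-averaged across experiments),
#'   `theta`, `phi_eff` (species x experiment matrix), `frozen`,
#'   `chi2_history` (tibble), `chi2r_global`, `distributions`, `series`,
#'   `ensembles`, `seed`, schedule settings.
#' @export
refine_saxs <- function(series, ensembles, outer = outer_schedule(),
                        annealing = annealing_schedule(), ka_start = 1,
                        seed = NULL, phi_floor = 1e-12, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(series); N <- length(ensembles)
  q <- ensembles[[1]]$q; m <- length(q)
  ctots <- vapply(series, function(p) monomer_to_protomer(attr(p, "conc_monomer")), numeric(1))
  if (any(is.na(ctots))) stop("every profile needs a `conc_monomer`", call. = FALSE)
  for (e in ensembles) {
    if (length(e$q) != m || any(abs(e$q - q) > 1e-12)) {
      stop("all ensembles must be on the experimental q-grid", call. = FALSE)
    }
  }
  sigma_blocks <- lapply(ensembles, block_error)
  Imats <- lapply(ensembles, function(e) e$intensities)
  w0s <- lapply(ensembles, function(e) e$w0)
  # per-experiment state
  W <- replicate(L, lapply(ensembles, function(e) e$w0), simplify = FALSE)
  E0 <- vapply(ensembles, function(e) ensemble_average(e, e$w0), numeric(m))
  E <- replicate(L, E0, simplify = FALSE)
  lambda <- replicate(L, replicate(N, numeric(m), simplify = FALSE), simplify = FALSE)
  theta <- rep(outer$theta_start, N)
  frozen <- rep(FALSE, N)
  phi_eff_mat <- matrix(1, N, L)
  KA <- ka_start
  sb <- vector("list", L)
  best <- list(chi2 = Inf)
  hist_iter <- numeric(outer$n_iterations)
  ka_hist <- numeric(outer$n_iterations)
  phi_eff_min_hist <- numeric(outer$n_iterations)
  chi2_init <- NA_real_

  for (t in seq_len(outer$n_iterations)) {
    # Step 1: scale and background per experiment
    I_list <- vector("list", L); sig_list <- vector("list", L)
    dists <- vector("list", L)
    for (l in seq_len(L)) {
      d <- isodesmic_distribution(ctots[l], KA = KA, nmax = N)
      dists[[l]] <- d
      I_mix <- as.numeric(E[[l]] %*% d$phi)
      sb[[l]] <- fit_scale_background(series[[l]]$I, series[[l]]$sigma, I_mix)
      I_list[[l]] <- (series[[l]]$I - sb[[l]]$cst) / sb[[l]]$scale
      sig_list[[l]] <- series[[l]]$sigma / abs(sb[[l]]$scale)
    }
    if (t == 1) chi2_init <- .chi2_of_ka(KA, ctots, E, I_list, sig_list, N)
    # Step 2: global KA by simulated annealing (warm start from current KA)
    sw <- .anneal_sweep(KA, annealing, ctots, E, I_list, sig_list, N)
    KA <- sw$KA
    # Step 3: deconvolute and reweight, species by species (Gauss-Seidel)
    for (l in seq_len(L)) {
      d <- isodesmic_distribution(ctots[l], KA = KA, nmax = N)
      dists[[l]] <- d
      phi <- d$phi
      I_mix <- as.numeric(E[[l]] %*% phi)
      Vtot <- rowSums(vapply(seq_len(N), function(r) (sigma_blocks[[r]] * phi[r])^2,
                             numeric(m)))
      for (i in seq_len(N)) {
        if (phi[i] < phi_floor) next
        I_extr <- (I_list[[l]] - (I_mix - phi[i] * E[[l]][, i])) / phi[i]
        var_rest <- pmax(Vtot - (sigma_blocks[[i]] * phi[i])^2, 0)
        sigma_extr <- sqrt(sig_list[[l]]^2 + var_rest) / phi[i]
        res <- bme_dual_solve(Imats[[i]], w0s[[i]], I_extr, sigma_extr,
                              theta[i], lambda[[l]][[i]])
        lambda[[l]][[i]] <- as.numeric(res$lambda)
        w_new <- as.numeric(res$w)
        W[[l]][[i]] <- w_new
        Enew <- as.numeric(crossprod(Imats[[i]], w_new))
        I_mix <- I_mix + phi[i] * (Enew - E[[l]][, i])
        E[[l]][, i] <- Enew
        phi_eff_mat[i, l] <- exp(res$S_rel)
      }
    }
    # theta decay with per-species freeze
    frozen <- frozen | (apply(phi_eff_mat, 1, min) < outer$phi_eff_cutoff)
    theta[!frozen] <- theta[!frozen] * (1 - outer$theta_decay)
    hist_iter[t] <- .chi2_of_ka(KA, ctots, E, I_list, sig_list, N)
    ka_hist[t] <- KA
    phi_eff_min_hist[t] <- min(phi_eff_mat)
    # converged-state snapshot: the Monte Carlo chain never settles
    # pointwise (the annealing re-randomises KA from T_start each
    # iteration), so the self-consistent solution reported to the user is
    # the best-fit iterate, not whatever transient the final sweep ends on
    if (hist_iter[t] <= best$chi2) {
      best <- list(chi2 = hist_iter[t], iteration = t, KA = KA, W = W,
                   sb = sb, theta = theta, frozen = frozen,
                   phi_eff = phi_eff_mat, dists = dists)
    }
    if (verbose && t %% 100 == 0) {
      message(sprintf("iter %d: KA = %.4g, chi2r_global = %.4g", t, KA, hist_iter[t]))
    }
    if (!is.finite(hist_iter[t])) {
      stop(sprintf("chi2 diverged at iteration %d (KA = %g)", t, KA), call. = FALSE)
    }
  }
  avg <- average_weights(best$W, best$dists)
  structure(
    list(KA = best$KA, KD = 1 / best$KA, scale_background = best$sb,
         weights = best$W,
         avg_weights = avg$weights, rho = avg$rho,
         theta = best$theta, frozen = best$frozen, phi_eff = best$phi_eff,
         chi2_history = tibble::tibble(iteration = seq_len(outer$n_iterations),
                                       chi2r_global = hist_iter,
                                       ka = ka_hist,
                                       min_phi_eff = phi_eff_min_hist),
         chi2r_global = best$chi2,
         chi2r_global_initial = chi2_init,
         best_iteration = best$iteration,
         distributions = best$dists, series = series, ensembles = ensembles,
         outer = outer, annealing = annealing, ka_start = ka_start,
         seed = seed),
    class = "saxs_refinement")
}

#' @export
print.saxs_refinement <- function(x, ...) {
  cat("Self-consistent SAXS refinement\n")
  cat(sprintf("  %d experiments, %d species, %d iterations\n",
              length(x$series), length(x$ensembles), nrow(x$chi2_history)))
  cat(sprintf("  KD = %.4g uM (KA = %.4g uM^-1)\n", x$KD, x$KA))
  cat(sprintf("  chi2r_global: %.4g -> %.4g\n", x$chi2r_global_initial, x$chi2r_global))
  cat(sprintf("  species with frozen theta: %d / %d\n", sum(x$frozen), length(x$frozen)))
  invisible(x)
}

#' Signal-share-weighted averaging of per-experiment conformational weights
#'
#' Each SAXS experiment informs each species in proportion to that
#' species' share of the experiment's scattering signal,
#' \eqn{s_{i,l} = i^2 c_{i,l} / \sum_i i^2 c_{i,l}}. The averaged weight of
#' conformer k of species i is \eqn{\langle w \rangle_{k,i} =
#' \sum_l \rho_{i,l} w_{k,i,l}} with \eqn{\rho_{i,l} = s_{i,l} / \sum_l s_{i,l}}.
#'
#' @param per_experiment_weights list over experiments of lists over
#'   species of weight vectors (equal conformer counts per species).
#' @param per_experiment_distributions list over experiments of
#'   [isodesmic_distribution()] tibbles.
#' @return list with `weights` (list over species of averaged, normalised
#'   weight vectors) and `rho` (species x experiment matrix).
#' @export
average_weights <- function(per_experiment_weights, per_experiment_distributions) {
  L <- length(per_experiment_weights)
  stopifnot(L == length(per_experiment_distributions), L >= 1)
  N <- length(per_experiment_weights[[1]])
  s <- matrix(vapply(per_experiment_distributions, function(d) {
    x <- d$i^2 * d$conc
    x / sum(x)
  }, numeric(N)), nrow = N)           # N x L
  rho <- s / rowSums(s)
  weights <- lapply(seq_len(N), function(i) {
    ns <- unique(vapply(per_experiment_weights, function(Wl) length(Wl[[i]]), numeric(1)))
    if (length(ns) != 1) stop("inconsistent conformer counts across experiments", call. = FALSE)
    w <- Reduce(`+`, lapply(seq_len(L), function(l) {
      rho[i, l] * per_experiment_weights[[l]][[i]]
    }))
    w / sum(w)
  })
  list(weights = weights, rho = rho)
}

# vectorised scale/background fit + chi2 for a matrix of model curves:
# returns chi2 (in raw experimental space) per column of M
.sbfit_chi2_cols <- function(y, sigma, M) {
  w <- 1 / sigma^2
  sw <- sum(w); sy <- sum(w * y); syy <- sum(w * y^2)
  sx <- colSums(w * M); sxx <- colSums(w * M^2); sxy <- colSums(w * y * M)
  det <- sw * sxx - sx^2
  scale <- (sw * sxy - sx * sy) / det
  cst <- (sxx * sy - sx * sxy) / det
  chi2 <- syy - 2 * scale * sxy - 2 * cst * sy + scale^2 * sxx +
    2 * scale * cst * sx + cst^2 * sw
  pmax(chi2, 0) / length(y)
}

#' Error scan of the fitted isodesmic dissociation constant
#'
#' Recomputes the global reduced chi-square on a KD grid, holding the
#' ensemble weights fixed and refitting only scale and background at each
#' KD. The reported uncertainty interval contains every KD whose global
#' chi-square lies within 10% of the minimum.
#'
#' @param series list of [saxs_profile()].
#' @param ensembles list of [oligomer_ensemble()].
#' @param weights list over species of fixed weight vectors (e.g. the
#'   averaged weights of a refinement), or `NULL` for the priors.
#' @param kd_grid KD values to scan (µM).
#' @param chi2_tol fractional chi-square band defining the interval
#'   (default 0.10).
#' @return list with `kd_best`, `kd_interval` (length 2), `chi2_min`, and
#'   `scan` (tibble `kd`, `chi2r_global`, `in_interval`).
#' @export
kd_error_scan <- function(series, ensembles, weights = NULL, kd_grid,
                          chi2_tol = 0.10) {
  N <- length(ensembles); q <- ensembles[[1]]$q
  E <- vapply(seq_len(N), function(i) {
    ensemble_average(ensembles[[i]], if (is.null(weights)) NULL else weights[[i]])
  }, numeric(length(q)))
  ctots <- vapply(series, function(p) monomer_to_protomer(attr(p, "conc_monomer")), numeric(1))
  chi2 <- rowMeans(matrix(vapply(seq_along(series), function(l) {
    PHI <- .iso_phi_grid(ctots[l], 1 / kd_grid, N)
    M <- E %*% PHI
    .sbfit_chi2_cols(series[[l]]$I, series[[l]]$sigma, M)
  }, numeric(length(kd_grid))), nrow = length(kd_grid)))
  best <- which.min(chi2)
  inside <- chi2 <= (1 + chi2_tol) * chi2[best]
  interval <- range(kd_grid[inside])
  if (inside[1] || inside[length(inside)]) {
    warning("KD uncertainty interval touches the grid boundary; widen the grid")
  }
  list(kd_best = kd_grid[best], kd_interval = interval, chi2_min = chi2[best],
       scan = tibble::tibble(kd = kd_grid, chi2r_global = chi2, in_interval = inside))
}

#' Static single-conformer fit of the dissociation constant
#'
#' Repeatedly draws one conformer per species, scans a log-spaced KD grid
#' (fitting scale and background at every KD) and records the best KD and
#' chi-square per draw. Measures how well static structures alone can fit
#' the concentration series.
#'
#' @param series list of [saxs_profile()].
#' @param ensembles list of [oligomer_ensemble()].
#' @param kd_grid KD grid (µM); default 10,000 log-spaced values in
#'   `[0.01, 100]`.
#' @param n_draws number of random single-frame draws.
#' @param seed RNG seed.
#' @return tibble with one row per draw: `draw`, `kd_best`,
#'   `chi2r_global`.
#' @export
kd_grid_fit_static <- function(series, ensembles, kd_grid = NULL, n_draws = 100,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(kd_grid)) kd_grid <- 10^seq(log10(0.01), log10(100), length.out = 10000)
  N <- length(ensembles); q <- ensembles[[1]]$q
  ctots <- vapply(series, function(p) monomer_to_protomer(attr(p, "conc_monomer")), numeric(1))
  PHIs <- lapply(seq_along(series), function(l) .iso_phi_grid(ctots[l], 1 / kd_grid, N))
  purrr::map_dfr(seq_len(n_draws), function(dr) {
    picks <- vapply(ensembles, function(e) sample.int(nrow(e$intensities), 1), integer(1))
    E <- vapply(seq_len(N), function(i) ensembles[[i]]$intensities[picks[i], ],
                numeric(length(q)))
    chi2 <- rowMeans(matrix(vapply(seq_along(series), function(l) {
      .sbfit_chi2_cols(series[[l]]$I, series[[l]]$sigma, E %*% PHIs[[l]])
    }, numeric(length(kd_grid))), nrow = length(kd_grid)))
    best <- which.min(chi2)
    tibble::tibble(draw = dr, kd_best = kd_grid[best], chi2r_global = chi2[best])
  })
}

#' Compare the isodesmic model with dimer--n-mer alternatives
#'
#' For each candidate oligomer size, scans the dimer--n-mer association
#' constant over a wide log grid (scale and background refitted at every
#' value) and reports the best-fit KA and global chi-square; monodisperse
#' single-oligomer fits (volume fraction 1) are included for reference.
#'
#' @param series list of [saxs_profile()].
#' @param dimer_ens [oligomer_ensemble()] of the free protomer (dimer).
#' @param oligomer_ens_by_size named list of [oligomer_ensemble()] for
#'   the candidate sizes (names/sizes in monomer subunits, even, >= 8).
#' @param ka_grid KA values to scan (µM^-1); default 25 decades,
#'   10 points per decade.
#' @return tibble with `model` ("dimer-oligomer" / "monodisperse"),
#'   `size_monomer`, `ka_best`, `chi2r_global`.
#' @export
compare_dimer_oligomer <- function(series, dimer_ens, oligomer_ens_by_size,
                                   ka_grid = 10^seq(-12, 12, length.out = 241)) {
  ctots <- vapply(series, function(p) monomer_to_protomer(attr(p, "conc_monomer")), numeric(1))
  Ed <- ensemble_average(dimer_ens)
  purrr::map_dfr(oligomer_ens_by_size, function(ens) {
    i <- ens$size_monomer
    Ei <- ensemble_average(ens)
    chi2 <- rowMeans(matrix(vapply(seq_along(series), function(l) {
      PHI <- matrix(vapply(ka_grid, function(ka) {
        mod <- solve_dimer_oligomer(ctots[l], ka, i)
        c(mod$phi_dimer, mod$phi_i)
      }, numeric(2)), nrow = 2)
      M <- cbind(Ed, Ei) %*% PHI
      .sbfit_chi2_cols(series[[l]]$I, series[[l]]$sigma, M)
    }, numeric(length(ka_grid))), nrow = length(ka_grid)))
    best <- which.min(chi2)
    mono <- mean(vapply(seq_along(series), function(l) {
      .sbfit_chi2_cols(series[[l]]$I, series[[l]]$sigma, cbind(Ei))
    }, numeric(1)))
    tibble::tibble(model = c("dimer-oligomer", "monodisperse"),
                   size_monomer = i,
                   ka_best = c(ka_grid[best], NA_real_),
                   chi2r_global = c(chi2[best], mono))
  })
}

#' Leave-one-out validation of the refinement
#'
#' Removes one experiment from the series, refines on the remainder, and
#' evaluates the held-out profile (fitting only scale and background)
#' under the four combinations of prior/fitted weights and initial/fitted
#' KD — the comparison used to select the reweighting cut-off without
#' overfitting.
#'
#' @param series list of [saxs_profile()].
#' @param held_out_label label of the profile to hold out.
#' @param ensembles list of [oligomer_ensemble()].
#' @param outer,annealing schedules, as in [refine_saxs()].
#' @param ka_start initial KA (µM^-1); defines the "initial KD" cell.
#' @param seed RNG seed.
#' @param ... passed to [refine_saxs()].
#' @return list with `cells` (tibble: `weights`, `kd`, `chi2r`), `fit`
#'   (the training refinement) and `held_out_label`.
#' @export
leave_one_out <- function(series, held_out_label, ensembles,
                          outer = outer_schedule(), annealing = annealing_schedule(),
                          ka_start = 1, seed = NULL, ...) {
  labels <- vapply(series, function(p) attr(p, "label"), character(1))
  idx <- which(labels == held_out_label)
  if (length(idx) != 1) stop("held-out label not found (or not unique) in series", call. = FALSE)
  train <- series[-idx]; held <- series[[idx]]
  fit <- refine_saxs(train, ensembles, outer = outer, annealing = annealing,
                     ka_start = ka_start, seed = seed, ...)
  N <- length(ensembles)
  ctot <- monomer_to_protomer(attr(held, "conc_monomer"))
  eval_cell <- function(weights, ka) {
    E <- vapply(seq_len(N), function(i) {
      ensemble_average(ensembles[[i]], if (is.null(weights)) NULL else weights[[i]])
    }, numeric(length(held$q)))
    d <- isodesmic_distribution(ctot, KA = ka, nmax = N)
    I_mix <- as.numeric(E %*% d$phi)
    sb <- fit_scale_background(held$I, held$sigma, I_mix)
    chi2_reduced(sb$scale * I_mix + sb$cst, held)
  }
  w0 <- lapply(ensembles, function(e) e$w0)
  wf <- fit$avg_weights
  cells <- tibble::tibble(
    weights = c("prior", "fitted", "prior", "fitted"),
    kd = c("initial", "fitted", "fitted", "initial"),
    chi2r = c(eval_cell(w0, ka_start), eval_cell(wf, fit$KA),
              eval_cell(w0, fit$KA), eval_cell(wf, ka_start)))
  list(cells = cells, fit = fit, held_out_label = held_out_label)
}
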