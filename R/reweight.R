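#' Deconvolute the SAXS contribution of one species from a mixture
#'
#' Subtracts the modelled contribution of all other species from the
#' (scale-corrected) experimental profile and rescales by the species'
#' volume fraction:
#' \deqn{\langle I \rangle_{i,extr} = (I_{exp} - \langle I \rangle_{mix,rest}) / \phi_i,}
#' with uncertainties propagated from both the experimental errors and the
#' block-error estimates of the other species' ensemble averages:
#' \deqn{\sigma_{i,extr} = \sqrt{\sigma_{exp}^2 +
#'   \sum_{r \ne i} (\sigma_{r,block} \phi_r)^2} / \phi_i.}
#' Negative extracted intensities are legitimate deconvolution artefacts
#' and are retained.
#'
#' @param profile_fit experimental profile already transformed onto the
#'   model scale (see [apply_inverse_scale()]).
#' @param ensembles list of [oligomer_ensemble()] matching the rows of
#'   `distribution`.
#' @param distribution tibble from [isodesmic_distribution()].
#' @param species_i protomer index of the species to extract (row of
#'   `distribution`).
#' @param sigma_blocks optional list of per-species block-error vectors
#'   (computed with [block_error()] on the prior ensembles); computed on
#'   the fly when omitted.
#' @param phi_floor volume fractions below this are considered numerically
#'   meaningless; the function returns `NULL` (skip-species signal) rather
#'   than an unusable extraction.
#' @return list with `I_extr`, `sigma_extr`, `species_i`, or `NULL` when
#'   `phi_i < phi_floor`.
#' @export
extract_profile <- function(profile_fit, ensembles, distribution, species_i,
                            sigma_blocks = NULL, phi_floor = 1e-12) {
  row <- match(species_i, distribution$i)
  if (is.na(row)) stop("species not in distribution", call. = FALSE)
  phi <- distribution$phi
  if (phi[row] < phi_floor) return(NULL)
  if (is.null(sigma_blocks)) sigma_blocks <- lapply(ensembles, block_error)
  E <- vapply(ensembles, ensemble_average, numeric(length(profile_fit$q)))
  I_rest <- as.numeric(E %*% phi) - phi[row] * E[, row]
  I_extr <- (profile_fit$I - I_rest) / phi[row]
  var_rest <- rowSums(vapply(seq_along(ensembles)[-row], function(r) {
    (sigma_blocks[[r]] * phi[r])^2
  }, numeric(length(profile_fit$q))))
  sigma_extr <- sqrt(profile_fit$sigma^2 + var_rest) / phi[row]
  list(I_extr = I_extr, sigma_extr = sigma_extr, species_i = species_i)
}

#' Bayesian/maximum-entropy reweighting of one ensemble
#'
#' Minimises \eqn{L(w) = (m/2)\chi^2_r(w) - \theta S_{rel}(w)} over the
#' probability simplex, where \eqn{\chi^2_r} measures agreement between the
#' weighted ensemble average and the target (extracted) profile and
#' \eqn{S_{rel} = -\sum_k w_k \log(w_k / w^0_k)} penalises departure from
#' the prior weights. The convex problem is solved in the dual (one
#' Lagrange multiplier per observable), which enforces positivity and
#' normalisation by construction; the solution is deterministic.
#'
#' @param ensemble an [oligomer_ensemble()]; its `w0` is the prior.
#' @param extracted list with `I_extr` and `sigma_extr` (from
#'   [extract_profile()]), or a [saxs_profile()].
#' @param theta confidence parameter (> 0); large values keep `w = w0`.
#' @param lambda0 optional warm-start multipliers (length m).
#' @param gtol,maxit optimiser tolerances (gradient norm, iteration cap).
#' @return a `bme_result` list: `w`, `theta`, `chi2r_before`,
#'   `chi2r_after`, `S_rel` (<= 0), `phi_eff` = exp(S_rel), `lambda`,
#'   `converged`, `iterations`.
#' @export
bme_reweight <- function(ensemble, extracted, theta, lambda0 = NULL,
                         gtol = 1e-10, maxit = 10000) {
  stopifnot(theta > 0)
  Imat <- ensemble$intensities
  if (nrow(Imat) < 2) stop("reweighting needs >= 2 conformers", call. = FALSE)
  if (is.data.frame(extracted)) {
    Iexp <- extracted$I; sig <- extracted$sigma
  } else {
    Iexp <- extracted$I_extr; sig <- extracted$sigma_extr
  }
  stopifnot(length(Iexp) == ncol(Imat))
  if (is.null(lambda0)) lambda0 <- numeric(ncol(Imat))
  res <- bme_dual_solve(Imat, ensemble$w0, Iexp, sig, theta, lambda0,
                        gtol = gtol, maxit = maxit)
  if (!res$converged && res$iterations >= maxit) {
    stop("BME optimiser failed to converge within `maxit` iterations", call. = FALSE)
  }
  before <- chi2_reduced(as.numeric(crossprod(Imat, ensemble$w0)), Iexp, sigma = sig)
  structure(
    list(w = as.numeric(res$w), theta = theta,
         chi2r_before = before, chi2r_after = res$chi2r,
         S_rel = res$S_rel, phi_eff = exp(res$S_rel),
         lambda = as.numeric(res$lambda),
         converged = res$converged, iterations = res$iterations),
    class = "bme_result")
}

#' @export
print.bme_result <- function(x, ...) {
  cat(sprintf("BME reweighting: theta = %.4g, chi2r %.4g -> %.4g, phi_eff = %.3f\n",
              x$theta, x$chi2r_before, x$chi2r_after, x$phi_eff))
  invisible(x)
}

#' Fraction of effective frames
#'
#' \eqn{\phi_{eff} = \exp(S_{rel}) = \exp(-\sum_k w_k \log(w_k/w^0_k))},
#' a measure in (0, 1] of how much of the prior ensemble is retained;
#' equals 1 iff `w == w0`.
#'
#' @param w posterior weights.
#' @param w0 prior weights.
#' @return scalar in (0, 1].
#' @export
phi_eff <- function(w, w0) {
  stopifnot(length(w) == length(w0))
  if (any(w < 0) || any(w0 < 0)) stop("weights must be non-negative", call. = FALSE)
  w <- w / sum(w); w0 <- w0 / sum(w0)
  if (any(w > 0 & w0 == 0)) {
    stop("`w` has support where `w0` is zero; relative entropy undefined", call. = FALSE)
  }
  nz <- w > 0
  exp(-sum(w[nz] * log(w[nz] / w0[nz])))
}
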