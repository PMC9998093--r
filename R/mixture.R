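#' Construct an oligomer conformational ensemble
#'
#' Holds per-conformer SAXS curves of one oligomeric species on a common
#' q-grid, with statistical weights and optional bead coordinates. The
#' forward scattering of each conformer is required to equal the number of
#' subunits in the oligomer (the convention that makes each species' signal
#' share proportional to size^2 * concentration). Conformers deviating by
#' more than 1% are renormalised with a warning. When an analytic forward
#' scattering `I0` is supplied (e.g. from [debye_intensity()]) it is used
#' for the check; otherwise the intensity at the smallest measured q is
#' used, which is only meaningful when the grid reaches the Guinier regime.
#'
#' @param size_monomer subunit count of the species, in monomers.
#' @param q q-grid (Å^-1), length m.
#' @param intensities n x m matrix of per-conformer curves.
#' @param weights statistical weights `w` (default uniform); normalised.
#' @param weights0 reference/prior weights `w0` (default uniform).
#' @param coords optional n x n_beads x 3 array of bead coordinates (nm).
#' @param beads optional bead table (tibble: `bead`, `subunit`, `domain`,
#'   `binding_site`, `mass`) describing the architecture shared by all
#'   conformers.
#' @param I0 optional length-n analytic forward scattering per conformer.
#' @param check_i0 check/enforce the I(0) = size convention (default TRUE).
#' @return an `oligomer_ensemble` object.
#' @export
oligomer_ensemble <- function(size_monomer, q, intensities, weights = NULL,
                              weights0 = NULL, coords = NULL, beads = NULL,
                              I0 = NULL, check_i0 = TRUE) {
  intensities <- as.matrix(intensities)
  n <- nrow(intensities)
  if (ncol(intensities) != length(q)) stop("intensity columns must match q-grid", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (is.null(weights0)) weights0 <- rep(1 / n, n)
  stopifnot(all(weights >= 0), all(weights0 >= 0))
  weights <- weights / sum(weights)
  weights0 <- weights0 / sum(weights0)
  if (check_i0) {
    fwd <- if (!is.null(I0)) I0 else intensities[, 1]
    off <- abs(fwd / size_monomer - 1) > 0.01
    if (any(off)) {
      warning(sprintf("%d conformer(s) violate I(0) = subunit count by >1%%; renormalised", sum(off)))
      intensities[off, ] <- intensities[off, , drop = FALSE] * (size_monomer / fwd[off])
      if (!is.null(I0)) I0[off] <- size_monomer
    }
  }
  structure(
    list(size_monomer = as.integer(size_monomer), q = as.numeric(q),
         intensities = intensities, w = weights, w0 = weights0,
         coords = coords, beads = beads, I0 = I0),
    class = "oligomer_ensemble")
}

#' @export
print.oligomer_ensemble <- function(x, ...) {
  cat(sprintf("Oligomer ensemble: %d-mer, %d conformers, %d q-points%s\n",
              x$size_monomer, nrow(x$intensities), length(x$q),
              if (is.null(x$coords)) "" else sprintf(", coordinates (%d beads)", dim(x$coords)[2])))
  invisible(x)
}

#' Weighted ensemble-average SAXS curve
#'
#' @param ensemble an [oligomer_ensemble()].
#' @param weights weights to use (default the ensemble's current `w`).
#' @return length-m average intensity.
#' @export
ensemble_average <- function(ensemble, weights = NULL) {
  w <- weights %||% ensemble$w
  stopifnot(length(w) == nrow(ensemble$intensities))
  as.numeric(crossprod(ensemble$intensities, w / sum(w)))
}

#' Compositional average over a polydisperse mixture
#'
#' \eqn{\langle I \rangle_{mix} = \sum_i \phi_i \langle I \rangle_{i,ens}},
#' the volume-fraction-weighted average of per-species ensemble-average
#' curves. With the I(0) = subunit-count convention, the fraction of total
#' signal carried by species i is proportional to \eqn{i^2 c_i}.
#'
#' @param ensembles list of [oligomer_ensemble()], one per species in
#'   `distribution` (matched by position to rows of `distribution`).
#' @param distribution tibble from [isodesmic_distribution()] (columns
#'   `i`, `conc`, `phi`).
#' @return list with `I_mix` (length-m curve) and `contributions` (tibble
#'   `i`, `phi`, `signal_share` with the i^2 c_i-normalised share).
#' @export
mix_intensity <- function(ensembles, distribution) {
  if (length(ensembles) != nrow(distribution)) {
    stop("need one ensemble per species in the distribution", call. = FALSE)
  }
  q0 <- ensembles[[1]]$q
  for (e in ensembles) {
    if (length(e$q) != length(q0) || any(e$q != q0)) {
      stop("all ensembles must share one q-grid", call. = FALSE)
    }
  }
  E <- vapply(ensembles, ensemble_average, numeric(length(q0)))  # m x N
  I_mix <- as.numeric(E %*% distribution$phi)
  s <- distribution$i^2 * distribution$conc
  contributions <- tibble::tibble(
    i = distribution$i, phi = distribution$phi,
    signal_share = if (sum(s) > 0) s / sum(s) else s)
  list(I_mix = I_mix, contributions = contributions)
}

#' Two-species mixture curve of a dimer--n-mer model
#'
#' \eqn{\langle I\rangle_{mix} = \phi_{dimer}\langle I\rangle_{dimer} +
#' \phi_i \langle I\rangle_i}.
#'
#' @param dimer_ens,oligomer_ens [oligomer_ensemble()] objects sharing a
#'   q-grid.
#' @param model list from [solve_dimer_oligomer()].
#' @return list with `I_mix` and `contributions`.
#' @export
mix_dimer_oligomer <- function(dimer_ens, oligomer_ens, model) {
  if (length(dimer_ens$q) != length(oligomer_ens$q) ||
      any(dimer_ens$q != oligomer_ens$q)) {
    stop("ensembles must share one q-grid", call. = FALSE)
  }
  I_mix <- model$phi_dimer * ensemble_average(dimer_ens) +
    model$phi_i * ensemble_average(oligomer_ens)
  p <- oligomer_ens$size_monomer / 2
  s <- c(1 * model$c_dimer, p^2 * model$c_i)
  list(I_mix = I_mix,
       contributions = tibble::tibble(
         i = c(1, p), phi = c(model$phi_dimer, model$phi_i),
         signal_share = if (sum(s) > 0) s / sum(s) else s))
}

#' Block-error estimate of the ensemble-average uncertainty
#'
#' Standard error of the unweighted (prior) ensemble mean at each q-point,
#' estimated by block averaging: conformers are grouped into blocks of
#' growing size (powers of two, in their original order), and the error
#' estimate is read off at the smallest block size whose estimate changes
#' by less than 5% upon doubling (plateau); failing that, the largest block
#' size with at least two blocks is used. For exchangeable conformers this
#' reduces to sd/sqrt(n); for serially correlated conformers it is larger.
#'
#' @param ensemble an [oligomer_ensemble()] with >= 8 conformers, in
#'   production order.
#' @param plateau_tol relative change defining the plateau (default 0.05).
#' @return length-m vector of standard errors.
#' @export
block_error <- function(ensemble, plateau_tol = 0.05) {
  X <- ensemble$intensities
  n <- nrow(X)
  if (n < 8) stop("block error analysis needs >= 8 conformers", call. = FALSE)
  bsizes <- 2^(0:floor(log2(n / 4)))  # at least 4 blocks
  se <- matrix(NA_real_, length(bsizes), ncol(X))
  for (bi in seq_along(bsizes)) {
    b <- bsizes[bi]
    nb <- floor(n / b)
    idx <- rep(seq_len(nb), each = b)
    means <- rowsum(X[seq_len(nb * b), , drop = FALSE], idx) / b
    se[bi, ] <- apply(means, 2, stats::sd) / sqrt(nb)
  }
  out <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    pick <- length(bsizes)
    for (bi in seq_len(length(bsizes) - 1)) {
      if (se[bi, j] == 0 || se[bi + 1, j] <= se[bi, j] ||
          abs(se[bi + 1, j] - se[bi, j]) < plateau_tol * se[bi, j]) {
        pick <- bi
        break
      }
    }
    out[j] <- se[pick, j]
  }
  out
}
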