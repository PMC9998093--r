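#' Free protomer concentration under the isodesmic model
#'
#' Solves the isodesmic mass balance for the concentration of the free
#' association unit (the protomer; for SPOP-like systems the BTB-mediated
#' dimer). With total protomer concentration `ctot` and a single
#' size-independent association constant `KA`, the infinite-series mass
#' balance \eqn{\sum_i i K_A^{i-1} c_1^i = c_{tot}} has the closed-form root
#' \deqn{c_1 = \frac{2 c_{tot} K_A + 1 - \sqrt{4 c_{tot} K_A + 1}}{2 c_{tot} K_A^2}.}
#'
#' The closed form suffers catastrophic cancellation when
#' \eqn{K_A c_{tot} \ll 1}; below `ctot*KA < 1e-3` a fifth-order series
#' expansion `ctot*(1 - 2u + 5u^2 - 14u^3 + ...)` in `u = ctot*KA`
#' (Catalan-number coefficients) is used instead.
#'
#' @param ctot total protomer concentration (µM), >= 0. Note this counts
#'   protomers: for a system whose protomer is a dimer it is half of the
#'   reported monomer concentration (see [monomer_to_protomer()]).
#' @param KA isodesmic association constant (µM^-1), >= 0.
#' @return free protomer concentration c1 (µM), in `[0, ctot]`.
#' @seealso [isodesmic_distribution()]
#' @export
#' @examples
#' isodesmic_protomer_conc(20, 0)      # no association: all free
#' isodesmic_protomer_conc(20, 0.625)  # KD = 1.6 uM
isodesmic_protomer_conc <- function(ctot, KA) {
  if (any(ctot < 0) || any(KA < 0)) {
    stop("`ctot` and `KA` must be non-negative", call. = FALSE)
  }
  u <- ctot * KA
  out <- numeric(length(u))
  # the closed form cancels catastrophically for u << 1 (numerator ~ 2u^2);
  # below u = 1e-3 use the Catalan-number series, accurate to machine
  # precision there
  small <- (u < 1e-3) | ctot == 0
  out[small] <- (ctot * (1 - 2 * u + 5 * u^2 - 14 * u^3 + 42 * u^4 - 132 * u^5))[small]
  if (any(!small)) {
    out[!small] <- ((2 * u + 1 - sqrt(4 * u + 1)) / (2 * ctot * KA^2))[!small]
  }
  pmin(pmax(out, 0), ctot + 0 * out)
}

#' Convert a reported monomer concentration to protomer units
#'
#' For systems whose association unit is an always-formed dimer, the
#' protomer concentration entering the isodesmic model is half of the total
#' monomer concentration reported for the scattering experiment.
#'
#' @param conc_monomer total monomer concentration (µM).
#' @return total protomer concentration (µM).
#' @export
monomer_to_protomer <- function(conc_monomer) conc_monomer / 2

#' Species distribution of an isodesmic self-association model
#'
#' Computes the equilibrium concentration of every oligomer with
#' `i = 1..nmax` protomers, \eqn{c_i = c_1 (K_A c_1)^{i-1}}, and the volume
#' fraction \eqn{\phi_i = i c_i / \sum_i i c_i}.
#'
#' @param ctot total protomer concentration (µM).
#' @param KA isodesmic association constant (µM^-1). Supply either `KA` or
#'   `KD`.
#' @param nmax largest oligomer considered, in protomers (default 30, i.e.
#'   a 60-mer of monomers).
#' @param KD isodesmic dissociation constant (µM); `KA = 1/KD`.
#' @return a tibble with columns `i` (protomers), `n_monomer` (= 2i),
#'   `conc` (µM of oligomer), `phi` (volume fraction). The truncation
#'   residual `1 - sum(i*c_i)/ctot` is attached as attribute
#'   `mass_residual`.
#' @export
#' @examples
#' d <- isodesmic_distribution(10, KD = 1.6)
#' attr(d, "mass_residual")
isodesmic_distribution <- function(ctot, KA = NULL, nmax = 30, KD = NULL) {
  if (is.null(KA)) {
    if (is.null(KD)) stop("supply `KA` or `KD`", call. = FALSE)
    stopifnot(KD > 0)
    KA <- 1 / KD
  }
  if (nmax < 1) stop("`nmax` must be >= 1", call. = FALSE)
  if (ctot < 0 || KA < 0) stop("`ctot` and `KA` must be non-negative", call. = FALSE)
  i <- seq_len(nmax)
  c1 <- isodesmic_protomer_conc(ctot, KA)
  r <- KA * c1                      # geometric ratio c_{i+1}/c_i, < 1
  conc <- c1 * r^(i - 1)
  mass <- sum(i * conc)
  phi <- if (mass > 0) i * conc / mass else c(1, rep(0, nmax - 1))
  out <- tibble::tibble(i = i, n_monomer = 2L * i, conc = conc, phi = phi)
  attr(out, "mass_residual") <- if (ctot > 0) 1 - mass / ctot else 0
  attr(out, "KA") <- KA
  attr(out, "ctot") <- ctot
  class(out) <- c("isodesmic_distribution", class(out))
  out
}

# lean internals for hot loops: volume fractions / concentrations without
# tibble construction
.iso_conc <- function(ctot, KA, nmax) {
  c1 <- isodesmic_protomer_conc(ctot, KA)
  c1 * (KA * c1)^(0:(nmax - 1))
}
.iso_phi <- function(ctot, KA, nmax) {
  conc <- .iso_conc(ctot, KA, nmax)
  i <- seq_len(nmax)
  mass <- sum(i * conc)
  if (mass > 0) i * conc / mass else c(1, rep(0, nmax - 1))
}
# volume-fraction matrix (nmax x K) over a vector of KA values
.iso_phi_grid <- function(ctot, KA_vec, nmax) {
  vapply(KA_vec, function(ka) .iso_phi(ctot, ka, nmax), numeric(nmax))
}

#' Dimer--n-mer two-state equilibrium
#'
#' Solves the mass balance of a two-state association model in which free
#' protomers (dimers of the monomer) coexist only with a single i-mer:
#' \eqn{K_A = c_i / c_{dimer}^{i/2}} and
#' \eqn{c_i = (c_{tot,dimer} - c_{dimer}) / (i/2)}, with `i` the oligomer
#' size in monomer subunits.
#'
#' @param ctot_dimer total protomer (dimer-subunit) concentration (µM).
#' @param KA_do association constant of the i-mer (µM^(1 - i/2)).
#' @param i oligomer size in monomer subunits; even, >= 4.
#' @return a list with `c_dimer`, `c_i` (µM) and volume fractions
#'   `phi_dimer`, `phi_i`.
#' @export
solve_dimer_oligomer <- function(ctot_dimer, KA_do, i) {
  if (i %% 2 != 0 || i < 4) stop("`i` must be even and >= 4", call. = FALSE)
  if (ctot_dimer < 0 || KA_do < 0) stop("concentrations and KA must be >= 0", call. = FALSE)
  p <- i / 2  # protomers per oligomer
  if (ctot_dimer == 0 || KA_do == 0) {
    cd <- ctot_dimer
  } else {
    f <- function(cd) KA_do * cd^p - (ctot_dimer - cd) / p
    # f(0) < 0, f(ctot) >= 0, strictly increasing: bracket guaranteed
    cd <- stats::uniroot(f, c(0, ctot_dimer), tol = 1e-14 * max(ctot_dimer, 1))$root
  }
  ci <- (ctot_dimer - cd) / p
  mass <- cd + p * ci
  list(
    c_dimer = cd, c_i = ci,
    phi_dimer = if (mass > 0) cd / mass else 1,
    phi_i = if (mass > 0) p * ci / mass else 0
  )
}

#' Weight-average molecular weight of an isodesmic mixture
#'
#' The observable measured by composition-gradient multi-angle light
#' scattering: \deqn{\langle MW \rangle_w =
#' \frac{\sum_i c_i (i\,MW_{protomer})^2}{\sum_i c_i\, i\,MW_{protomer}}.}
#'
#' @param distribution a tibble from [isodesmic_distribution()] (columns
#'   `i`, `conc`).
#' @param mw_protomer molar mass of the association unit (kDa).
#' @return weight-average molecular weight (kDa).
#' @export
average_mw <- function(distribution, mw_protomer) {
  ci <- distribution$conc
  i <- distribution$i
  denom <- sum(ci * i * mw_protomer)
  if (denom <= 0) stop("all species concentrations are zero; average undefined", call. = FALSE)
  sum(ci * (i * mw_protomer)^2) / denom
}

#' Fit the isodesmic model to CG-MALS data
#'
#' Fits a single global isodesmic dissociation constant KD across one or
#' more composition-gradient MALS data sets, with a separate protomer
#' molecular weight per data set (absorbing concentration-determination
#' uncertainty between merged sets). Loss is error-weighted least squares
#' when a `sigma_mw` column is present, unweighted otherwise. The quoted
#' KD uncertainty is two standard errors of the fit.
#'
#' @param data a data frame with columns `conc_monomer` (µM monomer),
#'   `mw` (kDa), optional `sigma_mw`, and optional `dataset` id (single
#'   data set assumed when absent).
#' @param nmax largest oligomer in protomers (default 30).
#' @param kd_start,mw_start optional starting values.
#' @return an object of class `cgmals_fit`: list with `kd` (µM),
#'   `kd_error` (2 SE), `mw_protomer` (named per dataset, kDa), `fit`
#'   (the underlying `nls` object) and `data`.
#' @export
fit_cgmals <- function(data, nmax = 30, kd_start = NULL, mw_start = NULL) {
  stopifnot(all(c("conc_monomer", "mw") %in% names(data)))
  if (is.null(data$dataset)) data$dataset <- "1"
  data$dataset <- factor(data$dataset)
  sets <- levels(data$dataset)
  if (any(table(data$dataset) < 3)) stop("each dataset needs >= 3 points", call. = FALSE)
  if (is.null(mw_start)) {
    mw_start <- vapply(sets, function(s) min(data$mw[data$dataset == s]), numeric(1))
  }
  if (is.null(kd_start)) kd_start <- 1
  w <- if (!is.null(data$sigma_mw)) 1 / data$sigma_mw^2 else rep(1, nrow(data))

  pred <- function(log_kd, mws) {
    kd <- exp(log_kd)
    vapply(seq_len(nrow(data)), function(r) {
      d <- isodesmic_distribution(monomer_to_protomer(data$conc_monomer[r]),
                                  KA = 1 / kd, nmax = nmax)
      average_mw(d, mws[[as.integer(data$dataset[r])]])
    }, numeric(1))
  }
  start <- c(list(log_kd = log(kd_start)), as.list(stats::setNames(mw_start, paste0("mw", seq_along(sets)))))
  fml <- stats::as.formula(paste(
    "mw ~ pred(log_kd, c(", paste0("mw", seq_along(sets), collapse = ", "), "))"))
  fit <- minpack.lm::nlsLM(fml, data = data, start = start, weights = w,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  kd <- exp(est[["log_kd"]])
  kd_error <- 2 * kd * se[["log_kd"]]  # delta method on log scale, 2 SD
  mws <- stats::setNames(est[paste0("mw", seq_along(sets))], sets)
  structure(
    list(kd = kd, kd_error = unname(kd_error), mw_protomer = mws,
         fit = fit, data = tibble::as_tibble(data), nmax = nmax),
    class = "cgmals_fit")
}

#' @export
print.cgmals_fit <- function(x, ...) {
  cat("Isodesmic fit to CG-MALS data\n")
  cat(sprintf("  KD = %.3g +/- %.2g uM (2 SE)\n", x$kd, x$kd_error))
  for (s in names(x$mw_protomer)) {
    cat(sprintf("  MW_protomer[%s] = %.4g kDa\n", s, x$mw_protomer[[s]]))
  }
  invisible(x)
}

#' Read a CG-MALS table
#'
#' Delimited text with columns `conc_monomer` (µM monomer), `mw` (kDa),
#' optional `sigma_mw` and `dataset`.
#'
#' @param path file path.
#' @return tibble.
#' @export
read_cgmals <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, comment.char = "#"))
}

#' Export a species distribution
#'
#' Writes the per-species table `(i, n_monomer, conc, phi)` as delimited
#' text and, alongside it, a JSON summary `{KD, ctot, nmax, mass_residual}`.
#'
#' @param distribution from [isodesmic_distribution()].
#' @param path output path for the table; the JSON summary goes to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(distribution, path) {
  utils::write.table(as.data.frame(distribution), path,
                     row.names = FALSE, quote = FALSE, sep = "\t")
  ka <- attr(distribution, "KA")
  summ <- list(KD = if (ka > 0) 1 / ka else Inf,
               ctot = attr(distribution, "ctot"),
               nmax = max(distribution$i),
               mass_residual = attr(distribution, "mass_residual"))
  jsonlite::write_json(summ, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
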