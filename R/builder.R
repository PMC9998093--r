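#' Specification of the synthetic rigid-helical-oligomer generator
#'
#' Describes a linear, helical filament whose repeating subunit carries a
#' rigid core (the self-association domains) centred on the filament axis
#' and a mobile substrate-binding domain that samples three states: two
#' "docked" states close to the core and one "extended" state further out,
#' mimicking a substrate-binding domain on a flexible linker.
#'
#' @param rise axial rise per subunit (nm, default 3.1).
#' @param subunits_per_turn helical repeat (default 16).
#' @param state_pops populations of the (docked-A, docked-B, extended)
#'   states of the mobile domain; must sum to 1.
#' @param state_dist core-to-mobile-domain centre-of-mass distance of each
#'   state (nm); defaults straddle the 4.4 / 5.2 nm docked/extended
#'   classification thresholds.
#' @param jitter Gaussian positional noise per bead coordinate (nm).
#' @param noise_level relative Gaussian noise of simulated experiments.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(rise = 3.1, subunits_per_turn = 16,
                           state_pops = c(docked_a = 0.45, docked_b = 0.35, extended = 0.20),
                           state_dist = c(docked_a = 3.6, docked_b = 4.2, extended = 5.8),
                           jitter = 0.1, noise_level = 0.01) {
  stopifnot(rise > 0, subunits_per_turn > 0, length(state_pops) == 3,
            length(state_dist) == 3, jitter >= 0, noise_level >= 0)
  if (abs(sum(state_pops) - 1) > 1e-9) stop("`state_pops` must sum to 1", call. = FALSE)
  structure(list(rise = rise, subunits_per_turn = subunits_per_turn,
                 state_pops = state_pops, state_dist = state_dist,
                 jitter = jitter, noise_level = noise_level),
            class = "synthetic_spec")
}

# zero-mean local bead templates (nm): rigid core and mobile domain shapes
.core_template <- matrix(c(
   1.0,  0.0,  0.4,
  -1.0,  0.0, -0.4,
   0.0,  0.9, -0.4,
   0.0, -0.9,  0.4), ncol = 3, byrow = TRUE)
.math_template <- matrix(c(
   0.8,  0.0,  0.0,
  -0.4,  0.6,  0.0,
  -0.4, -0.6,  0.0), ncol = 3, byrow = TRUE)

.rot_z <- function(a) {
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Bead architecture table of a generated oligomer
#'
#' @param size subunit count.
#' @return tibble with `bead`, `subunit`, `domain` ("core"/"math"),
#'   `binding_site`, `mass`.
#' @export
subunit_architecture <- function(size) {
  nc <- nrow(.core_template); nm <- nrow(.math_template)
  per <- nc + nm
  tibble::tibble(
    bead = seq_len(size * per),
    subunit = rep(seq_len(size), each = per),
    domain = rep(c(rep("core", nc), rep("math", nm)), size),
    binding_site = rep(c(rep(FALSE, nc), TRUE, rep(FALSE, nm - 1)), size),
    mass = 1)
}

#' Generate a synthetic helical-oligomer ensemble
#'
#' Places subunit cores on an ideal helix axis (rise and twist from the
#' spec; each core's centre of mass lies exactly on the axis so that the
#' jitter-free end-to-end distance is `rise * (size - 1)`), attaches the
#' mobile domain radially at a distance drawn from the three-state model,
#' and adds Gaussian jitter to every bead coordinate. Per-conformer SAXS
#' curves come from the Debye formula with forward scattering normalised
#' to the subunit count.
#'
#' @param spec a [synthetic_spec()].
#' @param size oligomer size in subunits (monomers).
#' @param n_conformers number of conformers.
#' @param q optional q-grid (Å^-1); when supplied, intensities are
#'   computed (binned Debye, see `bin_width`).
#' @param seed optional RNG seed; when `NULL`, the current RNG state is
#'   used.
#' @param bin_width pair-distance bin width (nm) for the Debye evaluation.
#' @return an [oligomer_ensemble()] with coordinates (and intensities when
#'   `q` is given).
#' @export
generate_oligomer <- function(spec, size, n_conformers, q = NULL, seed = NULL,
                              bin_width = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  arch <- subunit_architecture(size)
  nb <- nrow(arch)
  twist <- 2 * pi / spec$subunits_per_turn
  # rigid scaffold, identical for all conformers
  base <- matrix(0, nb, 3)
  for (s in seq_len(size)) {
    R <- .rot_z((s - 1) * twist)
    z <- c(0, 0, (s - 1) * spec$rise)
    rows_c <- which(arch$subunit == s & arch$domain == "core")
    rows_m <- which(arch$subunit == s & arch$domain == "math")
    base[rows_c, ] <- .core_template %*% t(R) + rep(z, each = length(rows_c))
    base[rows_m, ] <- .math_template %*% t(R) + rep(z, each = length(rows_m))
  }
  radial <- cbind(cos((arch$subunit - 1) * twist), sin((arch$subunit - 1) * twist), 0)
  coords <- array(0, c(n_conformers, nb, 3))
  states <- matrix(0L, n_conformers, size)
  for (k in seq_len(n_conformers)) {
    st <- sample.int(3, size, replace = TRUE, prob = spec$state_pops)
    states[k, ] <- st
    x <- base
    m_rows <- arch$domain == "math"
    d <- spec$state_dist[st[arch$subunit[m_rows]]]
    x[m_rows, ] <- x[m_rows, ] + radial[m_rows, , drop = FALSE] * d
    if (spec$jitter > 0) x <- x + matrix(stats::rnorm(nb * 3, sd = spec$jitter), nb, 3)
    coords[k, , ] <- x
  }
  intens <- NULL; I0 <- NULL
  if (!is.null(q)) {
    intens <- debye_batch(coords, rep(1, nb), q, size, bin_width = bin_width)
    I0 <- rep(size, n_conformers)
  }
  ens <- oligomer_ensemble(size, q = q %||% numeric(0),
                           intensities = intens %||% matrix(numeric(0), n_conformers, 0),
                           coords = coords, beads = arch, I0 = I0,
                           check_i0 = !is.null(q))
  attr(ens, "states") <- states
  ens
}

#' Debye-formula SAXS curve of a bead model
#'
#' \deqn{I(q) = \sum_{j,k} f_j f_k \frac{\sin(q r_{jk})}{q r_{jk}},}
#' with the q -> 0 limit handled analytically (`sinc -> 1`, so
#' `I(0) = (sum f)^2`), then normalised so that the forward scattering
#' equals `size` (the subunit count), which scales species intensities
#' proportionally to particle volume. Coordinates are in nm, q in Å^-1;
#' the conversion is internal.
#'
#' @param coords n_beads x 3 matrix (nm).
#' @param form_factors per-bead scattering factors (recycled).
#' @param q q-grid (Å^-1).
#' @param size subunit count used for the I(0) normalisation.
#' @param bin_width optional pair-distance bin width (nm) for an
#'   approximate fast evaluation; `NULL` (default) computes the exact
#'   double sum.
#' @return length-m intensity curve with `I(q=0) = size` by construction.
#' @export
debye_intensity <- function(coords, form_factors = 1, q, size, bin_width = NULL) {
  coords <- as.matrix(coords)
  nb <- nrow(coords)
  if (nb < 1) stop("need at least one bead", call. = FALSE)
  f <- rep_len(form_factors, nb)
  qa <- q * 10  # A^-1 -> nm^-1 so q*r uses r in nm
  I0_raw <- sum(f)^2
  if (nb == 1) return(rep(size, length(q)))
  if (is.null(bin_width)) {
    d <- as.matrix(stats::dist(coords))
    ff <- tcrossprod(f)
    I_raw <- vapply(qa, function(qq) {
      s <- qq * d
      sc <- ifelse(s == 0, 1, sin(s) / ifelse(s == 0, 1, s))
      sum(ff * sc)
    }, numeric(1))
  } else {
    arr <- array(coords, c(1, nb, 3))
    return(as.numeric(debye_batch(arr, f, q, size, bin_width = bin_width)))
  }
  I_raw * (size / I0_raw)
}

# binned Debye for a stack of conformers sharing one bead architecture;
# exact self-terms, pair distances histogrammed at `bin_width` resolution
debye_batch <- function(coords_array, f, q, size, bin_width = 0.05) {
  nconf <- dim(coords_array)[1]
  nb <- dim(coords_array)[2]
  qa <- q * 10
  # conservative maximum extent across conformers
  dmax <- 0
  for (k in seq_len(nconf)) {
    x <- coords_array[k, , , drop = TRUE]
    dim(x) <- c(nb, 3)
    rng <- apply(x, 2, range)
    dmax <- max(dmax, sqrt(sum((rng[2, ] - rng[1, ])^2)))
  }
  nbins <- max(1L, ceiling(dmax / bin_width) + 1L)
  centers <- (seq_len(nbins) - 0.5) * bin_width
  S <- outer(centers, qa, function(r, qq) {
    s <- qq * r
    ifelse(s == 0, 1, sin(s) / ifelse(s == 0, 1, s))
  })  # nbins x m
  stopifnot(length(unique(f)) == 1)  # uniform form factors in batch mode
  f2 <- f[1]^2
  I0_raw <- (sum(f))^2
  out <- matrix(0, nconf, length(q))
  for (k in seq_len(nconf)) {
    x <- coords_array[k, , , drop = TRUE]
    dim(x) <- c(nb, 3)
    d <- stats::dist(x)
    counts <- tabulate(pmin(ceiling(d / bin_width), nbins), nbins)
    I_raw <- 2 * f2 * as.numeric(counts %*% S) + nb * f2
    out[k, ] <- I_raw * (size / I0_raw)
  }
  out
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Proper rotation only (no reflection), mass-unweighted.
#'
#' @param moving,fixed n x 3 coordinate matrices in correspondence.
#' @return list with rotation `R` (3 x 3), translation `t` (applied as
#'   `x %*% t(R) + t`), and `rmsd` of the fit.
#' @export
kabsch <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm); Q <- sweep(fixed, 2, cf)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cf - as.numeric(R %*% cm)
  fitted <- moving %*% t(R) + rep(t_vec, each = nrow(moving))
  list(R = R, t = t_vec,
       rmsd = sqrt(mean(rowSums((fitted - fixed)^2))))
}

.subunit_count <- function(ens) max(ens$beads$subunit)

#' Splice two oligomer ensembles into a longer oligomer
#'
#' Implements filament elongation by joining conformers: the last subunit
#' of input A and the first subunit of input B are removed (so that the
#' newly joined subunits were internal in their source ensembles), extra
#' subunits are trimmed from the front of B to reach the target size, the
#' core domains of the last two subunits of A are superposed onto the core
#' domains of the first two subunits of (trimmed) B, the duplicated pair is
#' deleted, and the joint is rejected if any two beads of the newly joined
#' subunits come closer than the clash cutoff. The output size is
#' `nA + nB - 4 - extra` subunits; terminal subunits of the product always
#' originate from terminal subunits of the inputs.
#'
#' @param ensA,ensB [oligomer_ensemble()] objects with coordinates and
#'   bead tables from the same architecture.
#' @param target_size output size in subunits.
#' @param n_out number of conformers to build.
#' @param clash_cutoff minimum allowed inter-bead distance (nm) between
#'   the joined subunits; default 0.04 nm (0.4 Å).
#' @param seed optional RNG seed.
#' @param max_attempts attempts before declaring the rejection rate
#'   pathological.
#' @param q optional q-grid to compute Debye intensities for the product.
#' @param bin_width Debye bin width (nm).
#' @return an [oligomer_ensemble()] with coordinates; attribute `origin`
#'   is an `n_out x target_size` character matrix of subunit provenance
#'   tags `"<input>:<subunit>:<terminal|internal>"`.
#' @export
join_oligomers <- function(ensA, ensB, target_size, n_out,
                           clash_cutoff = 0.04, seed = NULL,
                           max_attempts = 1e4, q = NULL, bin_width = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ensA$coords) || is.null(ensB$coords)) {
    stop("both ensembles must carry coordinates", call. = FALSE)
  }
  nA <- .subunit_count(ensA); nB <- .subunit_count(ensB)
  extra <- nA + nB - 4 - target_size
  if (extra < 0 || nB - 1 - extra < 3) {
    stop(sprintf("target size %d not achievable from inputs of %d and %d subunits",
                 target_size, nA, nB), call. = FALSE)
  }
  archA <- ensA$beads; archB <- ensB$beads
  keepA <- archA$subunit <= nA - 1
  # B: drop first subunit and `extra` more from the front
  first_kept <- 2 + extra
  keepB <- archB$subunit >= first_kept
  subB <- archB$subunit[keepB] - (first_kept - 1)  # renumber 1..(nB-1-extra)
  nBkept <- nB - first_kept + 1
  coreA_align <- which(archA$subunit[keepA] %in% c(nA - 2, nA - 1) &
                         archA$domain[keepA] == "core")
  coreB_align <- which(subB %in% c(1, 2) & archB$domain[keepB] == "core")
  joinA_rows <- which(archA$subunit[keepA] == nA - 1)
  appendB <- subB >= 3
  joinB_rows <- which(subB[appendB] == 3)

  nbA <- sum(keepA); nbApp <- sum(appendB)
  out <- array(0, c(n_out, nbA + nbApp, 3))
  origin <- matrix(NA_character_, n_out, target_size)
  attempts <- 0; built <- 0
  nconfA <- dim(ensA$coords)[1]; nconfB <- dim(ensB$coords)[1]
  while (built < n_out) {
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      stop(sprintf("splice rejection rate %.1f%% over %d attempts; inputs incompatible",
                   100 * (1 - built / attempts), attempts), call. = FALSE)
    }
    a <- sample.int(nconfA, 1); b <- sample.int(nconfB, 1)
    XA <- ensA$coords[a, , , drop = TRUE]; dim(XA) <- c(dim(ensA$coords)[2], 3)
    XB <- ensB$coords[b, , , drop = TRUE]; dim(XB) <- c(dim(ensB$coords)[2], 3)
    XA <- XA[keepA, , drop = FALSE]
    XB <- XB[keepB, , drop = FALSE]
    fit <- kabsch(XB[coreB_align, , drop = FALSE], XA[coreA_align, , drop = FALSE])
    XBt <- XB %*% t(fit$R) + rep(fit$t, each = nrow(XB))
    XBapp <- XBt[appendB, , drop = FALSE]
    # clash check between the two newly joined subunits only
    dmin <- min(proxy_crossdist(XA[joinA_rows, , drop = FALSE],
                                XBapp[joinB_rows, , drop = FALSE]))
    if (dmin < clash_cutoff) next
    built <- built + 1
    out[built, , ] <- rbind(XA, XBapp)
    srcA <- seq_len(nA - 1)
    srcB <- seq(first_kept + 2, nB)
    origin[built, ] <- c(
      sprintf("A:%d:%s", srcA, ifelse(srcA %in% c(1, nA), "terminal", "internal")),
      sprintf("B:%d:%s", srcB, ifelse(srcB %in% c(1, nB), "terminal", "internal")))
  }
  arch_out <- subunit_architecture(target_size)
  intens <- NULL; I0 <- NULL
  if (!is.null(q)) {
    intens <- debye_batch(out, rep(1, nbA + nbApp), q, target_size, bin_width = bin_width)
    I0 <- rep(target_size, n_out)
  }
  ens <- oligomer_ensemble(target_size, q = q %||% numeric(0),
                           intensities = intens %||% matrix(numeric(0), n_out, 0),
                           coords = out, beads = arch_out, I0 = I0,
                           check_i0 = !is.null(q))
  attr(ens, "origin") <- origin
  attr(ens, "acceptance_rate") <- built / attempts
  ens
}

# minimal cross-distance matrix between two coordinate sets
proxy_crossdist <- function(X, Y) {
  xx <- rowSums(X^2); yy <- rowSums(Y^2)
  d2 <- outer(xx, yy, "+") - 2 * tcrossprod(X, Y)
  sqrt(pmax(d2, 0))
}

#' Simulate a SAXS concentration series from the synthetic model
#'
#' Generates conformational ensembles for every even-sized oligomer up to
#' `2 * nmax` subunits, computes mixture curves under the isodesmic model
#' at the given true dissociation constant, and adds relative Gaussian
#' noise. The generative ground truth is returned for recovery tests.
#'
#' @param spec a [synthetic_spec()].
#' @param kd_true isodesmic dissociation constant (µM, protomer units).
#' @param concentrations monomer concentrations of the series (µM);
#'   default the 5-40 µM series.
#' @param noise_level relative noise (sigma = noise_level * I); `NULL`
#'   uses `spec$noise_level`. At 0, profiles are noiseless but carry a
#'   small positive sigma column (1e-6 relative) so chi-square is defined.
#' @param n_conformers conformers per species.
#' @param nmax largest species in protomers (default 30).
#' @param q q-grid (Å^-1).
#' @param seed RNG seed.
#' @param bin_width Debye bin width (nm).
#' @return list with `series` (list of [saxs_profile()]), `ensembles`
#'   (list of [oligomer_ensemble()], protomer index 1..nmax),
#'   `distributions` (per experiment), `kd_true`, `spec`.
#' @export
simulate_series <- function(spec, kd_true = 1.6,
                            concentrations = c(5, 10, 15, 20, 30, 40),
                            noise_level = NULL, n_conformers = 100,
                            nmax = 30, q = seq(0.01, 0.4, length.out = 40),
                            seed = NULL, bin_width = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_level)) noise_level <- spec$noise_level
  ensembles <- lapply(seq_len(nmax), function(p) {
    generate_oligomer(spec, size = 2L * p, n_conformers = n_conformers,
                      q = q, bin_width = bin_width)
  })
  distributions <- lapply(concentrations, function(cc) {
    isodesmic_distribution(monomer_to_protomer(cc), KD = kd_true, nmax = nmax)
  })
  series <- purrr::map2(concentrations, distributions, function(cc, d) {
    I_mix <- mix_intensity(ensembles, d)$I_mix
    sig <- pmax(noise_level, 1e-6) * abs(I_mix)
    I_exp <- I_mix + noise_level * abs(I_mix) * stats::rnorm(length(I_mix))
    saxs_profile(q, I_exp, sig, conc_monomer = cc, label = sprintf("%guM", cc))
  })
  list(series = series, ensembles = ensembles, distributions = distributions,
       kd_true = kd_true, spec = spec)
}
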