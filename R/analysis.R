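.com <- function(X, mass) colSums(X * mass) / sum(mass)

#' Geometry summary of a conformational ensemble
#'
#' Per-conformer radius of gyration (mass-weighted over all beads),
#' end-to-end distance (between the centres of mass of the core domains of
#' the two terminal subunits), per-subunit distance between the mobile
#' (substrate-binding) domain and the core of the same subunit, and
#' centre-of-mass distances between binding sites in neighbouring
#' subunits. Weighted means are reported under both the prior (`w0`) and
#' current (`w`) weights.
#'
#' @param ensemble an [oligomer_ensemble()] with coordinates and a bead
#'   table.
#' @param weights optional weights overriding the ensemble's `w`.
#' @return a `geometry_summary` list: `per_conformer` (tibble: `conformer`,
#'   `rg`, `ree`, `mean_math_dist`), `math_dist` (tibble pooled over
#'   subunits: `conformer`, `subunit`, `dist`), `site_dist` (tibble:
#'   `conformer`, `pair`, `dist`), and `means` (tibble of w0- and
#'   w-weighted means of each observable). All distances in nm.
#' @export
geometry_summary <- function(ensemble, weights = NULL) {
  if (is.null(ensemble$coords) || is.null(ensemble$beads)) {
    stop("ensemble must carry coordinates and a bead table", call. = FALSE)
  }
  arch <- ensemble$beads
  if (nrow(arch) != dim(ensemble$coords)[2]) {
    stop("bead table does not match coordinate dimensions", call. = FALSE)
  }
  w <- weights %||% ensemble$w
  w <- w / sum(w)
  w0 <- ensemble$w0 / sum(ensemble$w0)
  n <- dim(ensemble$coords)[1]
  size <- max(arch$subunit)
  core1 <- arch$subunit == 1 & arch$domain == "core"
  coreN <- arch$subunit == size & arch$domain == "core"
  per_sub_core <- lapply(seq_len(size), function(s) arch$subunit == s & arch$domain == "core")
  per_sub_math <- lapply(seq_len(size), function(s) arch$subunit == s & arch$domain == "math")
  per_sub_site <- lapply(seq_len(size), function(s) arch$subunit == s & arch$binding_site)

  rg <- numeric(n); ree <- numeric(n)
  md <- matrix(0, n, size)
  sd_pairs <- if (size > 1) matrix(0, n, size - 1) else matrix(0, n, 0)
  for (k in seq_len(n)) {
    X <- ensemble$coords[k, , , drop = TRUE]; dim(X) <- c(nrow(arch), 3)
    com_all <- .com(X, arch$mass)
    rg[k] <- sqrt(sum(arch$mass * rowSums(sweep(X, 2, com_all)^2)) / sum(arch$mass))
    ree[k] <- sqrt(sum((.com(X[core1, , drop = FALSE], arch$mass[core1]) -
                          .com(X[coreN, , drop = FALSE], arch$mass[coreN]))^2))
    site_com <- matrix(NA_real_, size, 3)
    for (s in seq_len(size)) {
      cc <- .com(X[per_sub_core[[s]], , drop = FALSE], arch$mass[per_sub_core[[s]]])
      cm <- .com(X[per_sub_math[[s]], , drop = FALSE], arch$mass[per_sub_math[[s]]])
      md[k, s] <- sqrt(sum((cm - cc)^2))
      if (any(per_sub_site[[s]])) {
        site_com[s, ] <- .com(X[per_sub_site[[s]], , drop = FALSE],
                              arch$mass[per_sub_site[[s]]])
      }
    }
    if (size > 1) {
      sd_pairs[k, ] <- sqrt(rowSums((site_com[-1, , drop = FALSE] -
                                       site_com[-size, , drop = FALSE])^2))
    }
  }
  per_conf <- tibble::tibble(conformer = seq_len(n), rg = rg, ree = ree,
                             mean_math_dist = rowMeans(md))
  math_dist <- tibble::tibble(
    conformer = rep(seq_len(n), times = size),
    subunit = rep(seq_len(size), each = n),
    dist = as.numeric(md))
  site_dist <- tibble::tibble(
    conformer = rep(seq_len(n), times = max(size - 1, 0)),
    pair = rep(seq_len(max(size - 1, 0)), each = n),
    dist = as.numeric(sd_pairs))
  wmean <- function(x, ww) sum(x * ww)
  means <- tibble::tibble(
    observable = c("rg", "ree", "math_dist", "site_dist"),
    mean_w0 = c(wmean(rg, w0), wmean(ree, w0), wmean(rowMeans(md), w0),
                if (size > 1) wmean(rowMeans(sd_pairs), w0) else NA_real_),
    mean_w = c(wmean(rg, w), wmean(ree, w), wmean(rowMeans(md), w),
               if (size > 1) wmean(rowMeans(sd_pairs), w) else NA_real_))
  structure(list(per_conformer = per_conf, math_dist = math_dist,
                 site_dist = site_dist, means = means,
                 size = size),
            class = "geometry_summary")
}

#' Power-law fit R = R0 * N^nu
#'
#' Nonlinear least squares of a scaling law; used for the end-to-end
#' distance versus oligomer size (rigid linear filaments give nu near 1)
#' and for motif spacing versus residue separation.
#'
#' @param sizes predictor N (subunit counts or residue separations).
#' @param mean_R response (nm); must be positive.
#' @return a `power_law_fit` list: `R0`, `nu`, `cov` (2 x 2 covariance),
#'   `fit` (nls object).
#' @export
fit_power_law <- function(sizes, mean_R) {
  stopifnot(length(sizes) == length(mean_R))
  if (length(sizes) < 3) stop("need >= 3 sizes", call. = FALSE)
  if (any(mean_R <= 0) || any(sizes <= 0)) stop("sizes and R must be positive", call. = FALSE)
  lmfit <- stats::lm(log(mean_R) ~ log(sizes))
  start <- list(R0 = exp(stats::coef(lmfit)[[1]]), nu = stats::coef(lmfit)[[2]])
  df <- data.frame(N = sizes, R = mean_R)
  fit <- minpack.lm::nlsLM(R ~ R0 * N^nu, data = df, start = start)
  cv <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  structure(list(R0 = stats::coef(fit)[["R0"]], nu = stats::coef(fit)[["nu"]],
                 cov = cv, fit = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power law R = R0 * N^nu: R0 = %.4g nm, nu = %.4g\n", x$R0, x$nu))
  invisible(x)
}

#' Subsample an ensemble by geometric criteria
#'
#' Selects conformers by end-to-end distance or by the mean distance of
#' the mobile domain from the core, with thresholds defined from the
#' ensemble itself: `extended_ee` keeps frames with
#' `ree > max(ree) - (max(ree) - mean(ree))/2`; `compact_ee` keeps
#' `ree < min(ree) + (mean(ree) - min(ree))/2`; `math_compact` keeps
#' frames whose subunit-averaged mobile-domain distance is `< 4.4` nm and
#' `math_extended` `> 5.2` nm (`threshold` overrides these defaults).
#'
#' @param ensemble an [oligomer_ensemble()] with coordinates.
#' @param criterion one of `"extended_ee"`, `"compact_ee"`,
#'   `"math_compact"`, `"math_extended"`.
#' @param threshold optional custom threshold (nm) for the math criteria.
#' @param geometry optional precomputed [geometry_summary()].
#' @return the sub-ensemble (an [oligomer_ensemble()]), with attribute
#'   `selected` (conformer indices) and `threshold`.
#' @export
subsample_ensemble <- function(ensemble,
                               criterion = c("extended_ee", "compact_ee",
                                             "math_compact", "math_extended"),
                               threshold = NULL, geometry = NULL) {
  criterion <- match.arg(criterion)
  g <- geometry %||% geometry_summary(ensemble)
  pc <- g$per_conformer
  thr <- switch(criterion,
    extended_ee = max(pc$ree) - (max(pc$ree) - mean(pc$ree)) / 2,
    compact_ee = min(pc$ree) + (mean(pc$ree) - min(pc$ree)) / 2,
    math_compact = threshold %||% 4.4,
    math_extended = threshold %||% 5.2)
  keep <- switch(criterion,
    extended_ee = pc$ree > thr,
    compact_ee = pc$ree < thr,
    math_compact = pc$mean_math_dist < thr,
    math_extended = pc$mean_math_dist > thr)
  if (!any(keep)) {
    stop(sprintf("empty selection for '%s' (threshold %.4g nm)", criterion, thr),
         call. = FALSE)
  }
  idx <- which(keep)
  sub <- oligomer_ensemble(
    ensemble$size_monomer, ensemble$q,
    ensemble$intensities[idx, , drop = FALSE],
    weights = ensemble$w[idx], weights0 = ensemble$w0[idx],
    coords = ensemble$coords[idx, , , drop = FALSE],
    beads = ensemble$beads,
    I0 = ensemble$I0[idx], check_i0 = FALSE)
  attr(sub, "selected") <- idx
  attr(sub, "threshold") <- thr
  sub
}

# allowed-residue sets of the two degenerate binding-motif patterns
.motif_patterns <- list(
  P1 = c("GAVLIMWFPC", "STCYNQDEHR", "ST", "STCYNQDEHR", "ST"),
  P2 = c("GAVLIMWFPC", "STCYNQDEHR", "ST", "ST", "STCYNQDEHR"))

#' Find degenerate binding motifs in a protein sequence
#'
#' Scans for five-residue windows matching either of two position-specific
#' allowed-residue patterns (P1: hydrophobic, polar, S/T, polar, S/T;
#' P2: hydrophobic, polar, S/T, S/T, polar). All windows are reported,
#' including overlaps; a window matching both patterns appears once per
#' pattern id.
#'
#' @param sequence uppercase amino-acid string (standard 20-letter
#'   alphabet).
#' @return tibble with `start`, `end`, `pattern` ("P1"/"P2"), ordered by
#'   `start`.
#' @export
find_motifs <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  if (!all(aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])) {
    stop("sequence contains non-standard amino-acid characters", call. = FALSE)
  }
  n <- length(aa)
  out <- list()
  for (pid in names(.motif_patterns)) {
    sets <- strsplit(.motif_patterns[[pid]], "")
    if (n >= 5) {
      ok <- rep(TRUE, n - 4)
      for (p in 1:5) ok <- ok & aa[p:(n - 5 + p)] %in% sets[[p]]
      if (any(ok)) {
        out[[pid]] <- tibble::tibble(start = which(ok), end = which(ok) + 4L,
                                     pattern = pid)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(start = integer(), end = integer(), pattern = character()))
  }
  dplyr::arrange(res, .data$start, .data$pattern)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta_sequences <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  stats::setNames(toupper(unlist(seqs)), names(seqs))
}

#' Spacing between neighbouring motifs over a coordinate trajectory
#'
#' Given one-bead-per-residue conformations of a disordered region and a
#' motif table, computes for every frame the distance between the middle
#' residues of consecutive motifs (consecutive by start position, each
#' match used once).
#'
#' @param trajectory n_frames x n_residues x 3 array (nm).
#' @param motifs tibble from [find_motifs()] (>= 2 motifs).
#' @return list with `distances` (tibble: `frame`, `pair`, `sep_residues`,
#'   `dist`) and `pair_means` (tibble: `pair`, `sep_residues`,
#'   `mean_dist`).
#' @export
motif_spacing <- function(trajectory, motifs) {
  if (nrow(motifs) < 2) stop("need >= 2 motifs", call. = FALSE)
  motifs <- dplyr::arrange(motifs, .data$start)
  mid <- motifs$start + 2L
  nf <- dim(trajectory)[1]
  pairs <- seq_len(nrow(motifs) - 1)
  res <- purrr::map_dfr(seq_len(nf), function(fr) {
    X <- trajectory[fr, , , drop = TRUE]; dim(X) <- c(dim(trajectory)[2], 3)
    d <- sqrt(rowSums((X[mid[-1], , drop = FALSE] -
                         X[mid[-length(mid)], , drop = FALSE])^2))
    tibble::tibble(frame = fr, pair = pairs,
                   sep_residues = diff(mid), dist = d)
  })
  pair_means <- res |>
    dplyr::group_by(.data$pair, .data$sep_residues) |>
    dplyr::summarise(mean_dist = mean(.data$dist), .groups = "drop")
  list(distances = res, pair_means = pair_means)
}

#' Three-component Gaussian decomposition of a distance histogram
#'
#' Optional helper for picking representative conformers: fits a
#' 3-component Gaussian mixture to the pooled mobile-domain distance
#' distribution and returns, per component, the conformer/subunit pairs
#' whose distance lies within `0.1 * sigma` of the component mean.
#'
#' @param math_dist tibble from [geometry_summary()] (`$math_dist`).
#' @param k number of components (default 3).
#' @param pick_width half-width of the selection window in units of the
#'   component standard deviation (default 0.1).
#' @return list with `components` (tibble: `component`, `mean`, `sd`,
#'   `weight`) and `representatives` (tibble: `component`, `conformer`,
#'   `subunit`, `dist`).
#' @export
decompose_math_states <- function(math_dist, k = 3, pick_width = 0.1) {
  x <- math_dist$dist
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  gm <- mclust::Mclust(x, G = k, modelNames = "V", verbose = FALSE)
  ord <- order(gm$parameters$mean)
  comp <- tibble::tibble(
    component = seq_len(k),
    mean = as.numeric(gm$parameters$mean[ord]),
    sd = sqrt(as.numeric(gm$parameters$variance$sigmasq[ord])),
    weight = as.numeric(gm$parameters$pro[ord]))
  reps <- purrr::map_dfr(seq_len(k), function(ci) {
    sel <- abs(x - comp$mean[ci]) <= pick_width * comp$sd[ci]
    dplyr::mutate(math_dist[sel, ], component = ci)
  })
  list(components = comp, representatives = reps)
}
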