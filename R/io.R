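#' Read / write a per-species intensity matrix
#'
#' Delimited-text container for per-conformer SAXS curves of one species:
#' the first non-comment row is the q-grid (Å^-1), each subsequent row one
#' conformer's intensities on that grid. A `# size_monomer=<n>` header
#' records the subunit count.
#'
#' @param path file path.
#' @param size_monomer subunit count; read from the header when omitted.
#' @param ... passed to [oligomer_ensemble()] (e.g. `check_i0 = FALSE`).
#' @return an [oligomer_ensemble()].
#' @export
read_intensity_matrix <- function(path, size_monomer = NULL, ...) {
  lines <- readLines(path)
  meta <- grep("^\\s*#", lines, value = TRUE)
  if (is.null(size_monomer)) {
    hit <- grep("size_monomer\\s*=", meta, value = TRUE)
    if (length(hit) == 0) stop("no `size_monomer` header and none supplied", call. = FALSE)
    size_monomer <- as.integer(sub(".*size_monomer\\s*=\\s*", "", hit[1]))
  }
  body <- lines[!grepl("^\\s*#", lines)]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  if (length(unique(lengths(rows))) != 1) {
    stop("ragged intensity matrix: all rows must share the q-grid length", call. = FALSE)
  }
  q <- rows[[1]]
  if (length(rows) < 2) stop("no conformer rows after the q-grid row", call. = FALSE)
  intens <- do.call(rbind, rows[-1])
  oligomer_ensemble(size_monomer, q, intens, ...)
}

#' @rdname read_intensity_matrix
#' @param ensemble an [oligomer_ensemble()] with intensities.
#' @export
write_intensity_matrix <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# size_monomer=%d", ensemble$size_monomer), con)
  writeLines(paste(format(ensemble$q, digits = 17), collapse = " "), con)
  apply(ensemble$intensities, 1, function(row) {
    writeLines(paste(format(row, digits = 17), collapse = " "), con)
  })
  invisible(path)
}

#' Read a concentration series from a manifest
#'
#' The manifest is a YAML list of experiments, each with `path` (a
#' 3-column SAXS file, resolved relative to the manifest), `conc_monomer_uM`
#' and `label`.
#'
#' @param path manifest path.
#' @param q_unit passed to [read_saxs_profile()].
#' @return list of [saxs_profile()].
#' @export
read_saxs_series <- function(path, q_unit = "A^-1") {
  manifest <- yaml::read_yaml(path)
  base <- dirname(path)
  lapply(manifest, function(entry) {
    stopifnot(!is.null(entry$path), !is.null(entry$conc_monomer_uM))
    fp <- entry$path
    if (!file.exists(fp)) fp <- file.path(base, entry$path)
    read_saxs_profile(fp, conc_monomer = entry$conc_monomer_uM,
                      label = entry$label %||% basename(entry$path),
                      q_unit = q_unit)
  })
}

#' Write the outputs of a refinement to a directory
#'
#' Writes, per the package's plain-text conventions: `state.json` (fitted
#' KD/KA, global chi-square before/after, per-experiment scale and
#' background, per-species theta, phi_eff and freeze flags, seed),
#' `chi2_history.csv`, one `weights_<experiment>_<species>.tsv` table per
#' experiment per species (columns conformer, w0, w), one
#' `weights_avg_<species>.tsv` per species, and per-experiment refined
#' (scale-corrected) profiles `refined_<experiment>.dat`.
#'
#' @param fit a `saxs_refinement`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_refinement <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- vapply(fit$series, function(p) attr(p, "label"), character(1))
  labels[is.na(labels)] <- paste0("exp", seq_along(labels))[is.na(labels)]
  state <- list(
    KD = fit$KD, KA = fit$KA,
    chi2r_global_initial = fit$chi2r_global_initial,
    chi2r_global = fit$chi2r_global,
    best_iteration = fit$best_iteration,
    scale_background = stats::setNames(fit$scale_background, labels),
    theta = fit$theta, frozen = fit$frozen,
    phi_eff = as.data.frame(stats::setNames(as.data.frame(fit$phi_eff), labels)),
    phi_eff_cutoff = fit$outer$phi_eff_cutoff,
    n_iterations = fit$outer$n_iterations,
    seed = fit$seed)
  jsonlite::write_json(state, file.path(dir, "state.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(fit$chi2_history, file.path(dir, "chi2_history.csv"),
                   row.names = FALSE)
  for (l in seq_along(fit$series)) {
    for (i in seq_along(fit$ensembles)) {
      tab <- data.frame(conformer = seq_along(fit$weights[[l]][[i]]),
                        w0 = fit$ensembles[[i]]$w0, w = fit$weights[[l]][[i]])
      utils::write.table(tab,
                         file.path(dir, sprintf("weights_%s_%02d.tsv", labels[l], i)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    pf <- apply_inverse_scale(fit$series[[l]], fit$scale_background[[l]])
    write_saxs_profile(pf, file.path(dir, sprintf("refined_%s.dat", labels[l])))
  }
  for (i in seq_along(fit$ensembles)) {
    tab <- data.frame(conformer = seq_along(fit$avg_weights[[i]]),
                      w0 = fit$ensembles[[i]]$w0, w = fit$avg_weights[[i]])
    utils::write.table(tab, file.path(dir, sprintf("weights_avg_%02d.tsv", i)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
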