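#' Construct a SAXS profile
#'
#' A SAXS profile is a tibble with columns `q` (momentum transfer, Å^-1,
#' strictly increasing and positive), `I` (intensity, arbitrary units) and
#' `sigma` (per-point uncertainty, > 0), carrying the total monomer
#' concentration of the experiment and a label as attributes.
#'
#' @param q momentum transfer grid (Å^-1).
#' @param I intensities.
#' @param sigma per-point uncertainties (> 0).
#' @param conc_monomer total monomer concentration of the experiment (µM).
#' @param label experiment identifier.
#' @return a `saxs_profile` tibble.
#' @export
saxs_profile <- function(q, I, sigma, conc_monomer = NA_real_, label = NA_character_) {
  if (length(q) != length(I) || length(q) != length(sigma)) {
    stop("`q`, `I`, `sigma` must have equal length", call. = FALSE)
  }
  if (any(diff(q) <= 0) || any(q <= 0)) {
    stop("`q` must be strictly increasing and positive", call. = FALSE)
  }
  if (any(sigma <= 0)) stop("`sigma` must be positive everywhere", call. = FALSE)
  out <- tibble::tibble(q = as.numeric(q), I = as.numeric(I), sigma = as.numeric(sigma))
  attr(out, "conc_monomer") <- conc_monomer
  attr(out, "label") <- label
  class(out) <- c("saxs_profile", class(out))
  out
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("SAXS profile '%s': %d points, q in [%.4g, %.4g] A^-1, conc = %s uM monomer\n",
              attr(x, "label"), nrow(x), min(x$q), max(x$q),
              format(attr(x, "conc_monomer"))))
  NextMethod()
}

#' Read / write a SAXS profile
#'
#' Three-column whitespace- or comma-delimited text `(q, I, sigma)` with
#' `#` comment lines. Header metadata lines `# conc_uM=<x>` and
#' `# label=<x>` are parsed into the profile attributes. Uncertainties are
#' required. Files in nm^-1 must be flagged explicitly; they are never
#' auto-detected.
#'
#' @param path file path.
#' @param conc_monomer,label override/provide metadata.
#' @param q_unit `"A^-1"` (default) or `"nm^-1"` (converted on read).
#' @return a [saxs_profile()].
#' @export
read_saxs_profile <- function(path, conc_monomer = NULL, label = NULL,
                              q_unit = c("A^-1", "nm^-1")) {
  q_unit <- match.arg(q_unit)
  lines <- readLines(path)
  meta <- grep("^\\s*#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0(key, "\\s*="), meta, value = TRUE)
    if (length(hit) == 0) return(NULL)
    as.vector(sub(paste0(".*", key, "\\s*=\\s*"), "", hit[1]))
  }
  body <- sub("#.*$", "", lines)
  body <- body[nzchar(trimws(body))]
  body <- gsub(",", " ", body)
  fields <- strsplit(trimws(body), "\\s+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1 || ncol < 3) {
    stop("expected 3 columns (q, I, sigma); uncertainties are required", call. = FALSE)
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = ncol[1], byrow = TRUE)
  q <- m[, 1]
  if (q_unit == "nm^-1") q <- q / 10
  cm <- conc_monomer %||% as.numeric(get_meta("conc_uM") %||% NA)
  lb <- label %||% get_meta("label") %||% NA_character_
  saxs_profile(q, m[, 2], m[, 3], conc_monomer = cm, label = lb)
}

#' @rdname read_saxs_profile
#' @param profile a [saxs_profile()].
#' @export
write_saxs_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cm <- attr(profile, "conc_monomer")
  lb <- attr(profile, "label")
  if (!is.na(cm)) writeLines(sprintf("# conc_uM=%s", format(cm, digits = 17)), con)
  if (!is.na(lb)) writeLines(sprintf("# label=%s", lb), con)
  utils::write.table(
    data.frame(q = format(profile$q, digits = 17),
               I = format(profile$I, digits = 17),
               sigma = format(profile$sigma, digits = 17)),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Truncate a profile to low q
#'
#' Retains exactly the points with `q < qmax` (strict), the usable range
#' for analysis.
#'
#' @param profile a [saxs_profile()].
#' @param qmax upper bound (Å^-1), exclusive.
#' @return a [saxs_profile()].
#' @export
truncate_q <- function(profile, qmax = 0.4) {
  keep <- profile$q < qmax
  if (!any(keep)) stop("no points with q < qmax remain", call. = FALSE)
  saxs_profile(profile$q[keep], profile$I[keep], profile$sigma[keep],
               conc_monomer = attr(profile, "conc_monomer"),
               label = attr(profile, "label"))
}

#' Error-weighted scale and constant background fit
#'
#' Finds `(scale, cst)` minimising
#' \eqn{\sum_j (I_{exp,j} - scale\, I_{model,j} - cst)^2 / \sigma_j^2}
#' by the weighted normal equations.
#'
#' @param I_exp experimental intensities.
#' @param sigma_exp experimental uncertainties.
#' @param I_model model intensities on the same grid.
#' @return list with `scale` and `cst`.
#' @export
fit_scale_background <- function(I_exp, sigma_exp, I_model) {
  stopifnot(length(I_exp) == length(I_model), length(I_exp) == length(sigma_exp))
  if (length(I_exp) < 2) stop("need >= 2 points", call. = FALSE)
  w <- 1 / sigma_exp^2
  sw <- sum(w); sx <- sum(w * I_model); sxx <- sum(w * I_model^2)
  sy <- sum(w * I_exp); sxy <- sum(w * I_model * I_exp)
  det <- sw * sxx - sx^2
  if (abs(det) <= 1e-14 * sw * max(sxx, 1)) {
    stop("singular design: `I_model` is constant", call. = FALSE)
  }
  scale <- (sw * sxy - sx * sy) / det
  cst <- (sxx * sy - sx * sxy) / det
  list(scale = scale, cst = cst)
}

#' Apply the inverse of a scale/background transform to a profile
#'
#' Rather than rescaling every model conformer, the experimental profile is
#' transformed onto the model scale: `I_fit = (I - cst)/scale`,
#' `sigma_fit = sigma/|scale|`.
#'
#' @param profile a [saxs_profile()].
#' @param sb list with `scale` (non-zero) and `cst`.
#' @return transformed [saxs_profile()].
#' @export
apply_inverse_scale <- function(profile, sb) {
  if (sb$scale == 0) stop("`scale` must be non-zero", call. = FALSE)
  saxs_profile(profile$q, (profile$I - sb$cst) / sb$scale,
               profile$sigma / abs(sb$scale),
               conc_monomer = attr(profile, "conc_monomer"),
               label = attr(profile, "label"))
}

#' Reduced chi-square between a model curve and a profile
#'
#' \eqn{\chi^2_r = \frac{1}{m} \sum_j (I_{model,j} - I_{exp,j})^2 / \sigma_j^2}.
#'
#' @param I_model model intensities.
#' @param profile a [saxs_profile()], or a numeric vector `I_exp` (then
#'   supply `sigma`).
#' @param sigma uncertainties when `profile` is a bare vector.
#' @return scalar reduced chi-square.
#' @export
chi2_reduced <- function(I_model, profile, sigma = NULL) {
  if (is.data.frame(profile)) {
    I_exp <- profile$I; sigma <- profile$sigma
  } else {
    I_exp <- profile
    if (is.null(sigma)) stop("supply `sigma`", call. = FALSE)
  }
  m <- length(I_exp)
  if (m == 0) stop("empty profile", call. = FALSE)
  stopifnot(length(I_model) == m)
  sum((I_model - I_exp)^2 / sigma^2) / m
}

#' Global reduced chi-square across a concentration series
#'
#' The unweighted mean of per-experiment reduced chi-squares, valid when
#' every profile has the same number of points; otherwise a points-weighted
#' mean is used and a message is emitted.
#'
#' @param chi2_list numeric vector/list of per-experiment reduced
#'   chi-squares.
#' @param m_points optional vector of per-experiment point counts; needed
#'   to verify equal sizes (assumed equal when omitted).
#' @return scalar global reduced chi-square.
#' @export
chi2_global <- function(chi2_list, m_points = NULL) {
  x <- unlist(chi2_list)
  if (length(x) == 0) stop("no experiments", call. = FALSE)
  if (!is.null(m_points) && length(unique(m_points)) > 1) {
    message("profiles have unequal point counts; using points-weighted mean")
    return(sum(x * m_points) / sum(m_points))
  }
  mean(x)
}
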