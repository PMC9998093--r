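#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a refinement: per-conformer weights
#'
#' @param x a `saxs_refinement`.
#' @param ... unused.
#' @return tibble with `experiment`, `i` (protomers), `n_monomer`,
#'   `conformer`, `w0`, `w`, plus the experiment-averaged weight `w_avg`.
#' @export
tidy.saxs_refinement <- function(x, ...) {
  labels <- vapply(x$series, function(p) attr(p, "label"), character(1))
  purrr::map_dfr(seq_along(x$series), function(l) {
    purrr::map_dfr(seq_along(x$ensembles), function(sp) {
      w0 <- x$ensembles[[sp]]$w0
      wl <- x$weights[[l]][[sp]]
      wa <- x$avg_weights[[sp]]
      tibble::tibble(
        experiment = labels[[l]], i = sp, n_monomer = 2L * sp,
        conformer = seq_along(wl), w0 = w0, w = wl, w_avg = wa)
    })
  })
}

#' One-row summary of a refinement
#'
#' @param x a `saxs_refinement`.
#' @param ... unused.
#' @return tibble with `kd`, `ka`, `chi2r_global_initial`,
#'   `chi2r_global`, `n_experiments`, `n_species`, `n_iterations`,
#'   `n_frozen`, `min_phi_eff`.
#' @export
glance.saxs_refinement <- function(x, ...) {
  tibble::tibble(
    kd = x$KD, ka = x$KA,
    chi2r_global_initial = x$chi2r_global_initial,
    chi2r_global = x$chi2r_global,
    n_experiments = length(x$series),
    n_species = length(x$ensembles),
    n_iterations = nrow(x$chi2_history),
    n_frozen = sum(x$frozen),
    min_phi_eff = min(x$phi_eff))
}

#' @export
tidy.cgmals_fit <- function(x, ...) {
  tibble::tibble(term = c("kd", paste0("mw_protomer_", names(x$mw_protomer))),
                 estimate = c(x$kd, unname(x$mw_protomer)),
                 std.error = c(x$kd_error / 2, rep(NA_real_, length(x$mw_protomer))))
}

#' @export
glance.cgmals_fit <- function(x, ...) {
  tibble::tibble(kd = x$kd, kd_error = x$kd_error,
                 n_datasets = length(x$mw_protomer), n_obs = nrow(x$data))
}

#' @export
tidy.power_law_fit <- function(x, ...) {
  se <- sqrt(diag(x$cov))
  tibble::tibble(term = c("R0", "nu"), estimate = c(x$R0, x$nu),
                 std.error = as.numeric(se))
}

#' Plot the chi-square trajectory of a refinement
#'
#' @param object a `saxs_refinement`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.saxs_refinement <- function(object, ...) {
  ggplot2::ggplot(object$chi2_history,
                  ggplot2::aes(x = .data$iteration, y = .data$chi2r_global)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "outer iteration",
                  y = expression(chi[r * ",global"]^2),
                  title = "Self-consistent refinement trajectory") +
    ggplot2::theme_minimal()
}

#' Plot a species distribution
#'
#' @param object an `isodesmic_distribution` tibble.
#' @param ... unused.
#' @return a ggplot of species concentrations and volume fractions.
#' @export
autoplot.isodesmic_distribution <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("conc", "phi"),
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_monomer, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "oligomer size (monomer subunits)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a SAXS profile with an optional model curve
#'
#' @param object a [saxs_profile()].
#' @param I_model optional model intensities on the same grid.
#' @param ... unused.
#' @return a ggplot (log intensity vs q).
#' @export
autoplot.saxs_profile <- function(object, I_model = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(x = .data$q, y = .data$I)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$I - .data$sigma,
                                          ymax = .data$I + .data$sigma),
                             size = 0.1, colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q)") +
    ggplot2::theme_minimal()
  if (!is.null(I_model)) {
    p <- p + ggplot2::geom_line(data = tibble::tibble(q = object$q, I = I_model),
                                colour = "firebrick")
  }
  p
}
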