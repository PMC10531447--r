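#' Plot cumulative permeation counts
#'
#' @param counts Tibble from [cumulative_counts()].
#' @return A ggplot: one step curve per monomer, time in ns.
#' @export
plot_cumulative_counts <- function(counts) {
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$time_ps / 1000, y = .data$cumulative,
                               colour = .data$monomer)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (ns)", y = "cumulative water crossings",
                  colour = "monomer") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_cumulative_counts Distance series (raw and, when
#'   present, smoothed).
#' @param ds A `distance_series` or `salt_bridge_series`.
#' @export
plot_distance_series <- function(ds) {
  p <- ggplot2::ggplot(ds, ggplot2::aes(x = .data$time_ps / 1000,
                                        y = .data$distance)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "time (ns)", y = "minimal distance (Å)") +
    ggplot2::theme_minimal()
  if ("smoothed" %in% names(ds))
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), linewidth = 1)
  cutoff <- attr(ds, "cutoff")
  if (!is.null(cutoff))
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  p
}

#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z_mid, y = .data$density)) +
    ggplot2::geom_col(width = attr(object, "slice_width"), fill = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "bulk_density"),
                        linetype = "dashed") +
    ggplot2::labs(x = "z (Å)", y = "water density (Å^-3)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.free_energy_profile <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !.data$masked),
                  ggplot2::aes(x = .data$z_mid, y = .data$G)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "z (Å)", y = "G(z) (kJ/mol)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dn_fit <- function(object, ...) {
  ggplot2::ggplot(object$msd, ggplot2::aes(x = .data$tau_ps, y = .data$msd)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept, slope = 2 * object$D_n,
                         colour = "firebrick") +
    ggplot2::labs(x = "lag (ps)", y = "MSD of n(t)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rmsf_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$resid, y = .data$rmsf,
                                       colour = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.condition_test <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$condition, y = .data$value,
                               fill = .data$condition)) +
    ggplot2::geom_boxplot(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = object$metric %||% "value",
                  subtitle = sprintf("%s, min p = %.3g", object$test,
                                     min(object$p_values$p))) +
    ggplot2::theme_minimal()
}
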