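#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a phase-maximization fit
#'
#' @param x A [maximize_phases()] result.
#' @param ... Unused.
#' @return One row per channel: `channel`, `amplitude`, `phase`.
#' @export
tidy.trigmax_fit <- function(x, ...) {
  tibble::tibble(channel = seq_along(x$phases),
                 amplitude = x$amplitudes,
                 phase = x$phases)
}

#' @rdname tidy.trigmax_fit
#' @return `glance()`: one row with `max_sar`, `iterations`, `converged`,
#'   `perturbed`.
#' @export
glance.trigmax_fit <- function(x, ...) {
  tibble::tibble(max_sar = x$max_sar, iterations = x$iterations,
                 converged = x$converged, perturbed = x$perturbed)
}

#' Tidy a worst-case peak result
#'
#' @param x A [worst_case_psar()] result.
#' @param ... Unused.
#' @return The per-matrix tibble (without the phase list-column).
#' @export
tidy.worst_case_result <- function(x, ...) {
  dplyr::select(x$results, -dplyr::any_of("phases"))
}

#' @rdname tidy.worst_case_result
#' @export
glance.worst_case_result <- function(x, ...) {
  tibble::tibble(peak_sar = x$peak_sar, peak_index = x$peak_index,
                 n_matrices = nrow(x$results))
}

#' Tidy a method-comparison report
#'
#' @param x A [compare_methods()] result.
#' @param ... Unused.
#' @return Long tibble: `drive`, `actual`, `method`, `estimate`,
#'   `overestimation_pct`.
#' @export
tidy.bounds_report <- function(x, ...) {
  est_cols <- setdiff(names(x$drives), c("drive", "actual"))
  tidyr::pivot_longer(x$drives, dplyr::all_of(est_cols),
                      names_to = "method", values_to = "estimate") |>
    dplyr::mutate(overestimation_pct = 100 * (.data$estimate / .data$actual - 1))
}

#' @rdname tidy.bounds_report
#' @export
glance.bounds_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    dplyr::select(x$summary, "method", "mean_overestimation_pct"),
    names_from = "method", values_from = "mean_overestimation_pct",
    names_prefix = "mean_over_")
  dplyr::mutate(wide, n_drives = nrow(x$drives), n_matrices = x$n_matrices)
}

method_palette <- c(tm = "#1b9e77", rp = "#377eb8", tp = "#e41a1c",
                    lb = "#984ea3", ub = "#ff7f00")

#' Scatter of estimated versus actual peak SAR
#'
#' One point per drive and method: the exact worst-case (TM) values line up on
#' a curve bounding the actual values from above, the total-power bound is a
#' horizontal line at fixed total power, and the reference-phases estimates
#' scatter between them.
#'
#' @param object A [compare_methods()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bounds_report <- function(object, ...) {
  long <- tidy.bounds_report(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$actual, y = .data$estimate,
                                     colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_colour_manual(values = method_palette) +
    ggplot2::labs(x = "actual peak SAR (W/kg)",
                  y = "estimated worst-case peak SAR (W/kg)",
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' Histogram of actual-peak-SAR overestimation by method
#'
#' @param report A [compare_methods()] result.
#' @param binwidth Bin width in percent.
#' @return A ggplot.
#' @export
plot_overestimation <- function(report, binwidth = 5) {
  long <- tidy.bounds_report(report)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$overestimation_pct,
                                     fill = .data$method)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.55, boundary = 0) +
    ggplot2::scale_fill_manual(values = method_palette) +
    ggplot2::labs(x = "overestimation of actual peak SAR (%)", y = "drives",
                  fill = "method") +
    ggplot2::theme_minimal()
}

#' Convergence trace of the fixed-point iteration
#'
#' Plots the SAR after each sweep and (right axis of interest) the residual to
#' the converged value on a log scale, making the exponential convergence of
#' the update visible.
#'
#' @param fit A [maximize_phases()] result.
#' @return A ggplot.
#' @export
plot_convergence <- function(fit) {
  stopifnot(inherits(fit, "trigmax_fit"))
  h <- fit$sar_history
  d <- tibble::tibble(iteration = seq_along(h) - 1, sar = h,
                      residual = abs(fit$max_sar - h))
  d$residual[d$residual == 0] <- NA_real_
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$residual)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sweep", y = "|SAR - converged SAR| (W/kg)") +
    ggplot2::theme_minimal()
}
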