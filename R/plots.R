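#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a delta-G time series
#'
#' Line with a +/- 2 sigma ribbon, the convergence diagnostic of the
#' free energy estimate.
#'
#' @param object A [delta_g_time_series()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.delta_g_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$iteration, y = .data$delta_g)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$delta_g - 2 * .data$sigma,
        ymax = .data$delta_g + 2 * .data$sigma
      ),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "recorded iteration (prefix length)",
      y = "delta G (kT)",
      title = "Free energy difference vs simulation time"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the replica-to-state trace of an archive
#'
#' Each replica's random walk through the alchemical states; flat lines
#' reveal mixing bottlenecks.
#'
#' @param object A `simulation_archive`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.simulation_archive <- function(object, ...) {
  st <- object$state_trace
  df <- tibble::tibble(
    iteration = rep(seq_len(nrow(st)), ncol(st)),
    replica = factor(rep(seq_len(ncol(st)), each = nrow(st))),
    state = as.vector(st)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$iteration, y = .data$state, colour = .data$replica
  )) +
    ggplot2::geom_step(alpha = 0.7) +
    ggplot2::labs(
      x = "iteration", y = "alchemical state",
      title = "Replica state trace"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a diagnostics category table
#'
#' Max |PCC| per degree-of-freedom category with 95% CIs, the bar-chart
#' analogue of the slow-DOF heat map row for one archive.
#'
#' @param object A `diagnostics_report`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.diagnostics_report <- function(object, ...) {
  ct <- object$category_table
  ggplot2::ggplot(ct, ggplot2::aes(
    x = stats::reorder(.data$category, abs(.data$pcc)),
    y = abs(.data$pcc)
  )) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = abs(.data$ci_lo), ymax = abs(.data$ci_hi)),
      width = 0.2
    ) +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = NULL, y = "max |PCC| with dU/dlambda",
      title = "Slow degree-of-freedom scan"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an empirical state-transition matrix
#'
#' @param mixing A [mixing_statistics()] result.
#' @return A ggplot heat map of the row-stochastic transition matrix.
#' @export
plot_mixing_matrix <- function(mixing) {
  TM <- mixing$transition_matrix
  df <- tibble::tibble(
    from = rep(seq_len(nrow(TM)), ncol(TM)),
    to = rep(seq_len(ncol(TM)), each = nrow(TM)),
    p = as.vector(TM)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$to, .data$from, fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(
      low = "white", high = "steelblue4", limits = c(0, 1)
    ) +
    ggplot2::labs(
      x = "state (to)", y = "state (from)", fill = "P",
      title = "Empirical state-transition matrix"
    ) +
    ggplot2::theme_minimal()
}
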