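#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a replicator trajectory
#'
#' Strain frequencies against slow time, one line per strain.
#'
#' @param object A `replicator_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.replicator_trajectory <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$z,
                                   colour = factor(.data$strain))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(tau ~ "(slow time)"), y = "strain frequency",
                  colour = "strain") +
    ggplot2::theme_minimal()
}

#' Plot aggregated prevalences of a full-system trajectory
#'
#' Shows S, total single colonization I, co-colonization D and total
#' carriage T over time.
#'
#' @param object A `full_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.full_trajectory <- function(object, ...) {
  agg <- trajectory_aggregates(object)
  df <- tidyr::pivot_longer(agg[, c("time", "S", "I", "D", "T")],
                            -"time", names_to = "aggregate", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$aggregate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "host fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot mean fitness paths of a canonical ensemble
#'
#' Thin lines: Q(tau) per replicate; thick line: ensemble mean.
#'
#' @param object A `canonical_ensemble`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.canonical_ensemble <- function(object, ...) {
  mean_df <- dplyr::summarise(dplyr::group_by(object$summary, .data$tau),
                              Q = mean(.data$Q), .groups = "drop")
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$tau, y = .data$Q,
                               group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.3, linewidth = 0.3) +
    ggplot2::geom_line(data = mean_df, ggplot2::aes(group = NULL),
                       colour = "red", linewidth = 1) +
    ggplot2::labs(x = expression(tau), y = "mean fitness Q",
                  title = paste("Canonical class:", object$class)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
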