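# ggplot2 visualisations for the main result types.

#' Plot a belief trajectory
#'
#' Shows the one-step-ahead predicted probability of the state-1
#' outcome over trials, with the observed binaries as points, in the
#' style of the usual belief-update figures for reversal tasks.
#'
#' @param object A `belief_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.belief_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$u), shape = 3,
                        alpha = 0.4, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$muhat_1),
                       colour = "#2166AC", linewidth = 0.7) +
    ggplot2::labs(x = "trial", y = "p(state 1)",
                  title = paste0("Belief trajectory (",
                                 attr(object, "model"), ")")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot Bayesian model selection results
#'
#' Bars of expected model frequencies and protected exceedance
#' probabilities.
#'
#' @param object A `bms_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bms_result <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("expected_freq", "pxp"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_col(fill = "#2166AC") +
    ggplot2::facet_wrap(~quantity) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Random-effects model selection") +
    ggplot2::theme_minimal()
}

#' Plot parameter-recovery scatter
#'
#' True versus recovered parameter values, one facet per parameter,
#' with the identity line and per-parameter correlation.
#'
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_report <- function(object, ...) {
  lab <- object$correlations |>
    dplyr::mutate(label = sprintf("r = %.2f", .data$r))
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = .data$true, y = .data$recovered)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, colour = "#2166AC") +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "generating value", y = "recovered value",
                  title = sprintf("Parameter recovery (%s, mean r = %.2f)",
                                  object$model, object$mean_r)) +
    ggplot2::theme_minimal()
}

#' Plot a model-recovery confusion matrix
#'
#' @param object A `confusion_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_report <- function(object, ...) {
  df <- object$confusion |>
    dplyr::group_by(.data$true_family) |>
    dplyr::mutate(frac = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$selected_family,
                                   y = .data$true_family,
                                   fill = .data$frac)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.0f%%)", .data$n,
                                                    100 * .data$frac))) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166AC",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "selected family", y = "generating family",
                  fill = "fraction",
                  title = sprintf("Model recovery (overall %.1f%%)",
                                  100 * object$overall)) +
    ggplot2::theme_minimal()
}

#' Side-by-side continuous versus state-switching belief simulation
#'
#' Runs the context and no-context networks forward on the same
#' reversal sequence and overlays the readout-node beliefs, making the
#' abrupt-switch versus gradual-update contrast visible.
#'
#' @param seq A `trial_design` (or the protocol from
#'   [reversal_protocol()]).
#' @param ... Parameters passed to [build_network()] for the context
#'   build (e.g. `lambda_2`, `omega_4`).
#' @return A ggplot object.
#' @export
plot_switching_demo <- function(seq, ...) {
  ctx <- run_forward(build_network("context", ...), seq)
  noc <- run_forward(build_network("nocontext"), seq)
  df <- dplyr::bind_rows(
    tibble::tibble(trial = ctx$trial, muhat = ctx$muhat_1,
                   model = "context (state switching)"),
    tibble::tibble(trial = noc$trial, muhat = noc$muhat_1,
                   model = "no context (continuous)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$muhat,
                                   colour = .data$model)) +
    ggplot2::geom_point(data = tibble::tibble(trial = seq$trial,
                                              muhat = seq$u),
                        colour = "grey40", shape = 3, alpha = 0.4) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "trial", y = "p(state 1)", colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
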