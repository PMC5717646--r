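# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an enumerated steady-state table
#'
#' @param x a `kpr_steady_states` tibble.
#' @param ... unused.
#' @return A long tibble with one row per state and coordinate: `state`
#'   (index by ascending `S`), `coordinate`, `value`.
#' @exportS3Method generics::tidy
tidy.kpr_steady_states <- function(x, ...) {
  coords <- c("S", grep("^[CD][0-9]+$", names(x), value = TRUE))
  out <- tibble::as_tibble(x[coords])
  out$state <- seq_len(nrow(out))
  tidyr::pivot_longer(out, -"state", names_to = "coordinate",
                      values_to = "value")
}

#' One-row summary of a steady-state enumeration
#'
#' @param x a `kpr_steady_states` tibble.
#' @param ... unused.
#' @return A one-row tibble: `n_states`, `n_stable` (`NA` if stability has
#'   not been classified), `max_residual`, `S_min`, `S_max`.
#' @exportS3Method generics::glance
glance.kpr_steady_states <- function(x, ...) {
  tibble::tibble(
    n_states = nrow(x),
    n_stable = if ("stability" %in% names(x))
      sum(grepl("^stable", x$stability)) else NA_integer_,
    max_residual = max(x$residual),
    S_min = min(x$S), S_max = max(x$S))
}

#' Tidy a stability report
#'
#' @param x a `kpr_stability` object from [classify()].
#' @param ... unused.
#' @return A tibble with one row per eigenvalue: `eigenvalue` (complex),
#'   `re`, `im`.
#' @exportS3Method generics::tidy
tidy.kpr_stability <- function(x, ...) {
  tibble::tibble(eigenvalue = x$eigenvalues, re = Re(x$eigenvalues),
                 im = Im(x$eigenvalues))
}

#' @rdname tidy.kpr_stability
#' @return For `glance()`: a one-row tibble with `class`, `unstable_dim`,
#'   `oscillatory`, `max_re`.
#' @exportS3Method generics::glance
glance.kpr_stability <- function(x, ...) {
  tibble::tibble(class = x$class, unstable_dim = x$unstable_dim,
                 oscillatory = x$oscillatory,
                 max_re = max(Re(x$eigenvalues)))
}

#' Plot a dose-response curve
#'
#' Log-log plot of the activation readout `CN` against the agonist
#' concentration `L1` (one panel per `nu1` if several), with stable
#' branches drawn solid and unstable branches dashed.
#'
#' @param object a `kpr_response` tibble from [response_function()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.kpr_response <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$logL1, y = .data$logCN,
                                    group = .data$branch,
                                    colour = .data$stable,
                                    linetype = .data$stable)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2e7d32",
                                            `FALSE` = "#c62828"),
                                 labels = c(`TRUE` = "stable",
                                            `FALSE` = "unstable"),
                                 name = NULL) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = expression(log[10] ~ L[1]),
                  y = expression(log[10] ~ C[N])) +
    ggplot2::theme_minimal()
  if (length(unique(object$nu1)) > 1L)
    p <- p + ggplot2::facet_wrap(~nu1, labeller = ggplot2::label_both)
  p
}

#' Plot a one-parameter steady-state scan
#'
#' Branch diagram of `CN` against the swept parameter on log-log axes,
#' stable branches in green and unstable in red, with fold intervals marked.
#'
#' @param object a `kpr_scan` from [scan_parameter()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.kpr_scan <- function(object, ...) {
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(x = .data$value, y = .data$CN,
                                    group = .data$branch,
                                    colour = .data$stable)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2e7d32",
                                            `FALSE` = "#c62828"),
                                 labels = c(`TRUE` = "stable",
                                            `FALSE` = "unstable"),
                                 name = NULL) +
    ggplot2::labs(x = object$parameter, y = expression(C[N])) +
    ggplot2::theme_minimal()
  if (nrow(object$folds))
    p <- p + ggplot2::geom_vline(xintercept = sqrt(object$folds$lower *
                                                     object$folds$upper),
                                 linetype = "dotted", colour = "grey40")
  p
}

#' Plot a trajectory
#'
#' Time courses of all state variables on a log time axis.
#'
#' @param object a `kpr_trajectory` from [integrate_model()].
#' @param variables columns to draw (default: all state variables).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.kpr_trajectory <- function(object, variables = NULL, ...) {
  vars <- variables %||% setdiff(names(object), "t")
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[c("t", vars)], -"t",
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "concentration", colour = NULL) +
    ggplot2::theme_minimal()
}
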