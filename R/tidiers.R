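#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy methods for fitted objects
#'
#' `tidy()` returns one row per term/point; `glance()` returns a one-row
#' model summary, in the broom convention.
#'
#' @param x A fitted methpanel object.
#' @param ... Unused.
#' @return A tibble.
#' @name methpanel-tidiers
NULL

#' @rdname methpanel-tidiers
#' @export
tidy.mp_penalized <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef)) |>
    dplyr::filter(.data$estimate != 0 | .data$term == "(Intercept)")
}

#' @rdname methpanel-tidiers
#' @export
glance.mp_penalized <- function(x, ...) {
  tibble::tibble(penalty = x$penalty, mixing = x$mixing, lambda = x$lambda,
                 n_selected = length(x$selected))
}

#' @rdname methpanel-tidiers
#' @export
tidy.mp_panel_model <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @rdname methpanel-tidiers
#' @export
glance.mp_panel_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$panel), separated = x$separated,
                 transform = x$transform)
}

#' @rdname methpanel-tidiers
#' @export
tidy.mp_roc <- function(x, ...) x$points

#' @rdname methpanel-tidiers
#' @export
glance.mp_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_conf_low = x$auc_ci[1L],
                 auc_conf_high = x$auc_ci[2L],
                 youden_threshold = x$youden$threshold,
                 youden_j = x$youden$j)
}

#' @rdname methpanel-tidiers
#' @export
glance.mp_dmps <- function(x, ...) attr(x, "summary")

#' Plot methods
#'
#' `autoplot()` draws the natural ggplot2 display of each result type: a
#' volcano plot for DMP fits (delta-beta against -log10 p, colored by
#' call), the ROC curve with its Youden operating point, and the CV curve
#' of a penalized fit.
#'
#' @param object A methpanel result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name methpanel-autoplot
NULL

#' @rdname methpanel-autoplot
#' @importFrom ggplot2 autoplot
#' @export
autoplot.mp_roc <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(data = object$youden,
                        ggplot2::aes(x = 1 - .data$specificity,
                                     y = .data$sensitivity),
                        colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                                  object$auc, object$auc_ci[1L],
                                  object$auc_ci[2L]))
}

#' @rdname methpanel-autoplot
#' @param fdr FDR threshold drawn on the volcano plot.
#' @export
plot_volcano <- function(object, fdr = 0.10) {
  df <- tibble::as_tibble(object)
  df$called <- df$q_value <= fdr
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_beta,
                                   y = -log10(.data$p_value),
                                   colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey70"),
                                 guide = "none") +
    ggplot2::labs(x = expression(Delta * beta~"(AN - NN)"),
                  y = expression(-log[10]~italic(p)))
}

#' @rdname methpanel-autoplot
#' @export
autoplot.mp_penalized <- function(object, ...) {
  ggplot2::ggplot(object$cv_curve,
                  ggplot2::aes(x = log(.data$lambda),
                               y = .data$mean_cv_error)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_cv_error - .data$se,
                                        ymax = .data$mean_cv_error + .data$se),
                           width = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = log(object$lambda), linetype = "dashed") +
    ggplot2::labs(x = expression(log(lambda)), y = "Mean CV error")
}
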