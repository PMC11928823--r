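# ggplot2 panels for each result type: stress-strain with the modulus window,
# relaxation trace with the Maxwell fit and its chi2 path, friction force vs
# load with the COF line, and the Hertz fit.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_abline
#'   geom_vline annotate labs theme_minimal scale_x_log10
NULL

#' @export
ggplot2::autoplot

#' Plot a stress-strain curve
#'
#' @param object A [stress_strain()] curve.
#' @param summary Optional `tensile_summary` (from [youngs_modulus()]); when
#'   given, the fit window and failure point are annotated.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stress_strain <- function(object, summary = NULL, ...) {
  p <- ggplot(object, aes(x = .data$strain, y = .data$stress / 1e6)) +
    geom_line(colour = "grey30") +
    labs(x = sprintf("%s strain (-)", convention(object)),
         y = sprintf("%s stress (MPa)", convention(object))) +
    theme_minimal()
  if (!is.null(summary)) {
    p <- p +
      geom_vline(xintercept = c(summary$fit_window_lo, summary$fit_window_hi),
                 linetype = "dashed", colour = "steelblue") +
      annotate("point", x = summary$failure_strain,
               y = summary$failure_stress / 1e6, colour = "firebrick", size = 2) +
      labs(subtitle = sprintf("E = %.3g MPa (R2 = %.4f)",
                              summary$youngs_modulus / 1e6, summary$fit_r2))
  }
  p
}

#' Plot a relaxation trace and its Maxwell fit
#'
#' Hold-segment stress (points) with the fitted Prony series (line).
#'
#' @param object A `maxwell_fit` from [fit_maxwell()] or [select_order()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.maxwell_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$time)) +
    geom_point(aes(y = .data$stress / 1e6), size = 0.4, alpha = 0.4) +
    geom_line(aes(y = .data$fitted / 1e6), colour = "firebrick") +
    labs(x = "time since hold start (s)", y = "stress (MPa)",
         subtitle = sprintf("n = %d element(s), chi2 = %.4g",
                            object$selected_n, object$chi2)) +
    theme_minimal()
}

#' Plot the chi2 drop across Maxwell model orders
#'
#' @param fit A `maxwell_fit` from [select_order()].
#' @return A ggplot of chi2 (log scale) against the number of elements.
#' @export
plot_chi2_path <- function(fit) {
  stopifnot(inherits(fit, "maxwell_fit"))
  df <- tibble(n = as.integer(names(fit$chi2_path)), chi2 = unname(fit$chi2_path))
  ggplot(df, aes(x = .data$n, y = .data$chi2)) +
    geom_line(colour = "grey40") + geom_point() +
    geom_vline(xintercept = fit$selected_n, linetype = "dashed",
               colour = "firebrick") +
    ggplot2::scale_y_log10() +
    labs(x = "number of Maxwell elements", y = expression(chi^2)) +
    theme_minimal()
}

#' Plot friction force against normal force
#'
#' @param object A `friction_result` from [friction_coefficient()].
#' @param ... Unused.
#' @return A ggplot with the per-load mean friction forces and the COF line.
#' @export
autoplot.friction_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$load * 1e9, y = .data$friction * 1e9)) +
    geom_point() +
    geom_abline(slope = object$cof, intercept = object$adhesion_offset * 1e9,
                colour = "firebrick") +
    labs(x = "normal force (nN)", y = "friction force (nN)",
         subtitle = sprintf("COF = %.3g, adhesion = %.3g nN",
                            object$cof, object$adhesion_offset * 1e9)) +
    theme_minimal()
}

#' Plot a Hertz fit
#'
#' @param object A `hertz_fit` from [fit_hertz()].
#' @param ... Unused.
#' @return A ggplot of the baseline-corrected curve and the fitted model.
#' @export
autoplot.hertz_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$position * 1e6)) +
    geom_point(aes(y = .data$force * 1e9), size = 0.5, alpha = 0.5) +
    geom_line(aes(y = .data$fitted * 1e9), colour = "firebrick") +
    geom_vline(xintercept = object$contact_point * 1e6, linetype = "dashed") +
    labs(x = "piezo position (um)", y = "force (nN)",
         subtitle = sprintf("E = %.3g kPa", object$E / 1e3)) +
    theme_minimal()
}
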