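#' Hemisphere box plot of the ALPS index
#'
#' Box plot of the ipsilateral and contralateral index over included
#' patients, optionally with the healthy-control hemispheres alongside.
#'
#' @param patients an `alps_subjects` patients table
#' @param controls optional `alps_subjects` controls table
#' @return a ggplot
#' @export
plot_alps_hemispheres <- function(patients, controls = NULL) {
  inc <- included_patients(patients)
  long <- dplyr::bind_rows(
    tibble(group = "tumor ipsilateral", index = inc$alps_ipsi),
    tibble(group = "tumor contralateral", index = inc$alps_contra),
    if (!is.null(controls)) dplyr::bind_rows(
      tibble(group = "HC right", index = controls$alps_right),
      tibble(group = "HC left", index = controls$alps_left)
    )
  )
  long$group <- factor(long$group, levels = unique(long$group))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$index)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.55) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1.6) +
    ggplot2::labs(x = NULL, y = "DTI-ALPS index") +
    ggplot2::theme_minimal()
}

#' Scatter plot of ALPS index against a predictor
#'
#' One panel per hemisphere with the OLS line, mirroring the study's
#' regression figures (index vs age, index vs tumor ADC).
#'
#' @param patients an `alps_subjects` patients table
#' @param predictor `"age"` or `"tumor_adc"`
#' @return a ggplot
#' @export
plot_alps_regression <- function(patients, predictor = c("age", "tumor_adc")) {
  predictor <- match.arg(predictor)
  inc <- included_patients(patients)
  long <- tidyr::pivot_longer(
    inc[c("id", predictor, "alps_ipsi", "alps_contra")],
    cols = c("alps_ipsi", "alps_contra"),
    names_to = "hemisphere", values_to = "index"
  )
  xlab <- if (predictor == "age") "age (years)" else
    "tumor ADC (1e-6 mm²/s)"
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[predictor]], y = .data$index)) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~hemisphere) +
    ggplot2::labs(x = xlab, y = "DTI-ALPS index") +
    ggplot2::theme_minimal()
}

#' @method autoplot alps_study_report
#' @export
autoplot.alps_study_report <- function(object, ...) {
  h <- object$hemisphere$descriptives
  long <- tidyr::pivot_longer(
    tibble(hemisphere = h$hemisphere, mean = h$mean, sd = h$sd),
    cols = "mean", values_to = "index"
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$hemisphere, y = .data$index)) +
    ggplot2::geom_col(width = 0.5) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$index - .data$sd,
                   ymax = .data$index + .data$sd), width = 0.15) +
    ggplot2::labs(x = NULL, y = "DTI-ALPS index (mean ± sd)") +
    ggplot2::theme_minimal()
}
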