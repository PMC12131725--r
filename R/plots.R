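# ggplot2 displays for fits and diagnostics

#' Goodness-of-fit panels for a fitted model
#'
#' The standard four diagnostic panels: observed vs individual predictions,
#' observed vs population predictions, conditional weighted residuals vs
#' population predictions and vs time after dose.
#'
#' @param object A `pk_fit`.
#' @param ... Unused.
#' @return A ggplot object (faceted).
#' @export
autoplot.pk_fit <- function(object, ...) {
  g <- gof_table(object)
  long <- dplyr::bind_rows(
    tibble(panel = "DV ~ IPRED", x = g$IPRED, y = g$DV),
    tibble(panel = "DV ~ PRED", x = g$PRED, y = g$DV),
    tibble(panel = "CWRES ~ PRED", x = g$PRED, y = g$CWRES),
    tibble(panel = "CWRES ~ TAD", x = g$TAD, y = g$CWRES)
  )
  ref_id <- tibble(panel = c("DV ~ IPRED", "DV ~ PRED"),
                   slope = 1, intercept = 0)
  ref_h <- tibble(panel = c("CWRES ~ PRED", "CWRES ~ TAD"), y0 = 0)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(data = ref_id,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept),
                         linetype = 2, colour = "grey40") +
    ggplot2::geom_hline(data = ref_h,
                        ggplot2::aes(yintercept = .data$y0),
                        linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
}

#' VPC plot
#'
#' Observed percentile curves over the simulated 95% confidence bands of
#' the same percentiles, by time after dose.
#'
#' @param object A `pk_vpc`.
#' @param ... Unused.
#' @export
autoplot.pk_vpc <- function(object, ...) {
  tb <- object$table
  tb$percentile <- factor(tb$percentile, levels = c(5, 50, 95),
                          labels = c("5th", "50th", "95th"))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$tad_mid, group = .data$percentile)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lower,
                                      ymax = .data$sim_upper),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_median),
                       colour = "steelblue", linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "red") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "red") +
    ggplot2::labs(x = "Time after dose (h)", y = "Concentration (mg/L)") +
    ggplot2::theme_bw()
}

#' NPDE diagnostics plot
#'
#' Histogram of the NPDE with the standard-normal density, and a
#' quantile-quantile panel.
#'
#' @param object A `pk_npde`.
#' @param ... Unused.
#' @export
autoplot.pk_npde <- function(object, ...) {
  x <- object$table$npde
  qq <- tibble(theoretical = qnorm(stats::ppoints(length(x))),
               sample = sort(x), panel = "Q-Q")
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$theoretical, y = .data$sample)) +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::labs(x = "Standard normal quantiles", y = "NPDE") +
    ggplot2::theme_bw()
}

#' Clearance vs covariate scatter from empirical Bayes estimates
#'
#' Individual clearance (at the EBE etas) against a chosen covariate,
#' stratified by diuretic use when available.
#'
#' @param fit A `pk_fit`.
#' @param covariate Covariate column name (e.g. `"SCR"`, `"DFI"`).
#' @return A ggplot object.
#' @export
plot_cl_covariate <- function(fit, covariate = "SCR") {
  ebe <- ebe_parameters(fit)
  if (!covariate %in% names(ebe)) {
    abort(paste0("Covariate ", covariate, " not in the dataset."))
  }
  aes <- ggplot2::aes(x = .data[[covariate]], y = .data$CL)
  p <- ggplot2::ggplot(ebe, aes)
  if ("DA" %in% names(ebe)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(shape = factor(.data$DA)),
                                 alpha = 0.7) +
      ggplot2::scale_shape_manual(values = c(`0` = 1, `1` = 2),
                                  name = "Diuretics")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::labs(x = covariate, y = "CL (L/h)") + ggplot2::theme_bw()
}
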