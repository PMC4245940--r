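#' Diagnostic plot of a deamination fit
#'
#' Log of the remaining-CPD fraction against time, with the fitted line.
#' Points excluded from the fit (nonpositive remaining fraction) do not
#' appear, as they have no finite log.
#'
#' @param object A `deamination_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.deamination_fit <- function(object, ...) {
  used <- object$data[object$data$used, , drop = FALSE]
  used$log_remaining <- log(used$remaining_fraction)
  ggplot2::ggplot(used, ggplot2::aes(x = .data$time_h, y = .data$log_remaining)) +
    ggplot2::geom_abline(intercept = object$intercept, slope = -object$k,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "deamination time (h)",
      y = "ln fraction CPD remaining",
      title = if (!is.na(object$site_id)) object$site_id else NULL,
      subtitle = sprintf("k = %.3g h^-1, t1/2 = %.3g h, r^2 = %.3f",
                         object$k, object$half_life_h, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cleavage profile with its periodicity fit
#'
#' @param object A `phasing_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.phasing_fit <- function(object, ...) {
  grid <- tibble::tibble(
    position = seq(min(object$data$position), max(object$data$position),
                   length.out = 400)
  )
  grid$fitted <- predict(object, grid$position)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_hline(yintercept = object$baseline, linetype = "dotted") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity), size = 1.2) +
    ggplot2::labs(
      x = "sequence position (bp)",
      y = "cleavage intensity",
      subtitle = sprintf("period %.2f bp, maximum at %.1f bp",
                         object$period_bp, object$phase_bp)
    ) +
    ggplot2::theme_minimal()
}

#' Bar profile of a per-position quantity
#'
#' Convenience bar chart of any per-rotational-position column (yield fold,
#' rate fold, free-energy difference, mutagenic potential ...) with an
#' optional reference line at the free-DNA level.
#'
#' @param data Data frame with a `position` column.
#' @param y Column to plot (tidy-eval).
#' @param reference Optional y-value for a dashed reference line (e.g. 1 for
#'   fold changes).
#' @return A ggplot.
#' @export
plot_rotational_profile <- function(data, y, reference = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = factor(.data$position),
                                          y = {{ y }})) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "rotational position") +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_hline(yintercept = reference, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}
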