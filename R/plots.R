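# ggplot2 views of the main result types.

#' @rdname autoplot-allogrades
#' @export
autoplot.pgls_fit <- function(object, ...) {
  vars <- all.vars(object$formula)
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[vars[2]]], y = .data[[vars[1]]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$coefficients[1],
                         slope = object$coefficients[2]) +
    ggplot2::labs(
      subtitle = sprintf("PGLS: n = %d, lambda = %.2f", object$n, object$lambda)
    ) +
    ggplot2::theme_minimal()
}

#' Plots of allometric-shift results
#'
#' `autoplot()` methods: a PGLS scatter with its fitted line
#' (`pgls_fit`), log-log scatter with one line per grade (`grade_model`),
#' per-branch posterior shift probabilities with the acceptance threshold
#' (`shift_summary`), and parameter traces per chain (`posterior_chains`).
#'
#' @param object a fitted object from this package.
#' @param ... unused.
#' @return a ggplot object.
#' @name autoplot-allogrades
NULL

#' @rdname autoplot-allogrades
#' @export
autoplot.grade_model <- function(object, ...) {
  d <- object$fit$data
  d$grade <- object$groups[d[[object$fit$species_col]]]
  gl <- grade_lines(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[object$x]],
                                  y = .data[[object$y]],
                                  colour = .data$grade)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(
      data = gl,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$group)
    ) +
    ggplot2::labs(colour = "grade") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-allogrades
#' @export
autoplot.shift_summary <- function(object, ...) {
  d <- object$branches
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$label, .data$pp),
                                  y = .data$pp)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$label, yend = 0),
                          colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$accepted)) +
    ggplot2::geom_hline(yintercept = object$pp_threshold, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "branch", y = "posterior shift probability") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-allogrades
#' @export
autoplot.posterior_chains <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("alpha", "sigma2", "k", "theta_root", "beta_root"),
                        names_to = "parameter", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$value,
                                  colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(colour = "chain") +
    ggplot2::theme_minimal()
}
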