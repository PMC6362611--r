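#' Plot a reflectivity dataset
#'
#' Reflectivity versus Q on a log10 y axis with error bars.
#' @param object A [refl_data] tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.slabs_data <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$q, y = .data$r)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$r - .data$dr,
                                        ymax = .data$r + .data$dr),
                           width = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Q ~ (ring(A)^-1)), y = "R",
                  title = attr(object, "name")) +
    ggplot2::theme_minimal()
}

#' Plot an objective: data with the current model curve
#'
#' @param object A `slabs_objective` or `slabs_global_objective`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.slabs_objective <- function(object, ...) {
  d <- tibble::as_tibble(object$data)
  d$model <- generative(object)
  d$dataset <- if (nzchar(object$name)) object$name else "data"
  plot_curves(d)
}

#' @exportS3Method ggplot2::autoplot
autoplot.slabs_global_objective <- function(object, ...) {
  d <- dplyr::bind_rows(lapply(object$objectives, function(o) {
    x <- tibble::as_tibble(o$data)
    x$model <- generative(o)
    x$dataset <- if (nzchar(o$name)) o$name else "data"
    x
  }))
  plot_curves(d)
}

plot_curves <- function(d) {
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q, colour = .data$dataset)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$r - .data$dr,
                                        ymax = .data$r + .data$dr),
                           width = 0, alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(y = .data$r), size = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$model)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Q ~ (ring(A)^-1)), y = "R") +
    ggplot2::theme_minimal()
}

#' Plot the SLD depth profile of a structure
#' @param object A `slabs_structure`.
#' @param ... Passed to [sld_profile()].
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.slabs_structure <- function(object, ...) {
  prof <- sld_profile(object, ...)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$z, y = .data$sld)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(z ~ (ring(A))),
                  y = expression(SLD ~ (10^-6 ~ ring(A)^-2)),
                  title = object$name) +
    ggplot2::theme_minimal()
}

#' Trace plot of an MCMC chain
#' @param object A `slabs_chain`.
#' @param ... Ignored.
#' @return A ggplot object with one facet per parameter showing every
#'   walker's trajectory.
#' @exportS3Method ggplot2::autoplot
autoplot.slabs_chain <- function(object, ...) {
  dm <- dim(object$samples)
  d <- dplyr::bind_rows(lapply(seq_len(dm[3]), function(j) {
    tibble::tibble(
      step = rep(seq_len(dm[1]), dm[2]),
      walker = rep(seq_len(dm[2]), each = dm[1]),
      value = as.vector(object$samples[, , j]),
      parameter = object$par_names[j])
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$value,
                                  group = .data$walker)) +
    ggplot2::geom_line(alpha = 0.2, linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
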