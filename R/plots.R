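#' Plot an estimate set with its scaling curve
#'
#' Scatter of parameter estimates against mean polygon population with the
#' fitted scaling curve and its extrapolated intercept at the minimal
#' level, on log-x axes as in the scaling fits.
#'
#' @param set An estimate set tibble (one parameter's rows of
#'   [estimate_across_ensemble()] output).
#' @param curve The matching [fit_scaling_curve()] result.
#' @param x_minimal Minimal-level mean polygon population; when supplied
#'   the extrapolated intercept is drawn.
#' @return A ggplot object.
#' @export
plot_scaling_curve <- function(set, curve, x_minimal = NULL) {
  xr <- range(set$mean_polygon_population)
  if (!is.null(x_minimal)) xr[1] <- min(xr[1], x_minimal)
  grid_x <- exp(seq(log(xr[1]), log(xr[2]), length.out = 200))
  pred <- vapply(grid_x, function(x) extrapolate_intercept(curve, x), numeric(1))
  p <- ggplot2::ggplot(set, ggplot2::aes(x = .data$mean_polygon_population,
                                         y = .data$estimate)) +
    ggplot2::geom_point(shape = 1, alpha = 0.7) +
    ggplot2::geom_line(data = tibble::tibble(mean_polygon_population = grid_x,
                                             estimate = pred),
                       colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean polygon population",
                  y = paste(curve$parameter, "estimate"),
                  title = paste("Scaling of", curve$parameter,
                                "across zonation scales"))
  if (!is.null(x_minimal)) {
    ei <- extrapolate_intercept(curve, x_minimal)
    p <- p + ggplot2::annotate("point", x = x_minimal, y = ei,
                               colour = "firebrick", size = 3) +
      ggplot2::geom_vline(xintercept = x_minimal, linetype = "dotted")
  }
  p
}

#' @method autoplot simulation_interval
#' @export
autoplot.simulation_interval <- function(object, ...) {
  est <- dplyr::filter(object$estimates, .data$parameter == "beta")
  p <- plot_scaling_curve(est, object$curves$beta)
  p +
    ggplot2::geom_hline(yintercept = c(object$lower, object$upper),
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$ei_beta, colour = "firebrick",
                        linetype = "dotted") +
    ggplot2::labs(title = sprintf("%g%% simulation interval [%.4g, %.4g]",
                                  100 * object$coverage, object$lower,
                                  object$upper))
}

#' @method autoplot shift_estimates
#' @export
autoplot.shift_estimates <- function(object, ...) {
  d <- dplyr::mutate(object, rank = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$beta)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi),
                           width = 0, alpha = 0.5) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "configuration (ordered by point estimate)",
                  y = "minimal-level slope estimate",
                  title = "Estimates across minimal-grid shifts")
}

#' Plot overlay counts on the lattice
#'
#' Heat map of the number of zonations flagging each minimal unit, for
#' maps whose unit ids follow the lattice `r<i>c<j>` convention.
#'
#' @param counts Output of [overlay_counts()].
#' @return A ggplot object.
#' @export
plot_overlay <- function(counts) {
  rc <- id_to_rowcol(counts$id)
  d <- dplyr::mutate(counts, row = rc$row, col = rc$col)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "lightyellow", high = "navy",
                                 limits = c(0, max(d$n_zonations))) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "zonations\nflagged",
                  title = "Flagged-area overlay across zonations")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
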