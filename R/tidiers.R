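#' Tidy a scaling curve
#'
#' @param x A [fit_scaling_curve()] result.
#' @param ... Unused.
#' @return A tibble with one row per polynomial coefficient (ascending
#'   powers of the transformed x).
#' @method tidy scaling_curve
#' @export
tidy.scaling_curve <- function(x, ...) {
  tibble::tibble(term = paste0("tx^", 0:x$degree),
                 estimate = x$coefficients)
}

#' @rdname tidy.scaling_curve
#' @method glance scaling_curve
#' @export
glance.scaling_curve <- function(x, ...) {
  tibble::tibble(parameter = x$parameter, degree = x$degree,
                 requested_degree = x$requested_degree,
                 n_points = x$n_points, n_scales = x$n_scales,
                 x_transform = x$x_transform, y_transform = x$y_transform,
                 sign = x$sign, residual_ss = x$residual_ss)
}

#' Tidy a simulation interval
#'
#' @param x A [construct_si()] result.
#' @param ... Unused.
#' @return A one-row tibble with the bounds and the extrapolated
#'   intercepts.
#' @method tidy simulation_interval
#' @export
tidy.simulation_interval <- function(x, ...) {
  tibble::tibble(lower = x$lower, upper = x$upper, ei_beta = x$ei_beta,
                 ei_alpha = x$ei_alpha, ei_nuisance = x$ei_nuisance,
                 coverage = x$coverage)
}

#' @rdname tidy.simulation_interval
#' @method glance simulation_interval
#' @export
glance.simulation_interval <- function(x, ...) {
  tibble::tibble(coverage = x$coverage, converged = x$converged,
                 iterations = x$iterations, monotone = x$monotone,
                 n_inner_sim = x$n_inner_sim,
                 convergence_tol_frac = x$convergence_tol_frac,
                 stopping_point = x$stopping_point %||% NA_real_,
                 seed = x$seed)
}

#' Tidy a zonation
#'
#' @param x A [design_zonation()] result.
#' @param ... Unused.
#' @return The assignment tibble (`id`, `zone`).
#' @method tidy zonation
#' @export
tidy.zonation <- function(x, ...) x$assignment

#' @rdname tidy.zonation
#' @method glance zonation
#' @export
glance.zonation <- function(x, ...) {
  tibble::tibble(n_zones = x$n_zones,
                 target_population = x$target_population,
                 threshold_min = x$threshold_min,
                 mean_polygon_population = x$mean_polygon_population,
                 objective = x$objective, seed = x$seed)
}

#' Tidy a coverage experiment
#'
#' @param x A [coverage_experiment()] result.
#' @param ... Unused.
#' @return The per-replicate results tibble.
#' @method tidy si_coverage
#' @export
tidy.si_coverage <- function(x, ...) x$results

#' @rdname tidy.si_coverage
#' @method glance si_coverage
#' @export
glance.si_coverage <- function(x, ...) {
  tibble::tibble(proportion = x$proportion, hits = x$hits,
                 n_reps = x$n_reps, nominal = x$nominal,
                 ci_lo = x$ci[1], ci_hi = x$ci[2],
                 conf_level = x$conf_level)
}
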