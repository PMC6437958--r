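#' Declare an association model
#'
#' The model relates the outcome to a single covariate at whatever level of
#' aggregation the data are supplied:
#' * `negbin_rate`: negative-binomial counts with a `log(population)`
#'   offset (NB2: variance `mu + mu^2 / theta`); `beta` is a log
#'   rate-ratio per unit covariate.
#' * `poisson_rate`: Poisson counts with a `log(population)` offset.
#' * `gaussian_weighted`: continuous outcome, weighted least squares with
#'   weights equal to zone population; the nuisance parameter is the
#'   (population-inflated) residual standard error.
#' * `poisson_individual`: Poisson counts with no offset, for data whose
#'   minimal unit is an individual (population 1 per unit).
#'
#' @param family One of `"negbin_rate"`, `"poisson_rate"`,
#'   `"gaussian_weighted"`, `"poisson_individual"`.
#' @param covariate_name Label used in printed output.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("negbin_rate", "poisson_rate",
                                  "gaussian_weighted", "poisson_individual"),
                       covariate_name = "covariate") {
  family <- match.arg(family)
  offset <- if (family %in% c("negbin_rate", "poisson_rate")) "log_population" else "none"
  structure(list(family = family, offset = offset,
                 covariate_name = covariate_name),
            class = "model_spec")
}

is_count_family <- function(spec) {
  spec$family %in% c("negbin_rate", "poisson_rate", "poisson_individual")
}

#' Aggregate minimal-level data to a zonation
#'
#' Populations and count outcomes are summed within zones (so totals are
#' conserved exactly); continuous outcomes and the covariate are
#' aggregated as population-weighted means (plain means with
#' `weighted = FALSE`).
#'
#' @param map A [bb_map()].
#' @param zonation A [design_zonation()] result (or any list with an
#'   `assignment` tibble of `id`, `zone`).
#' @param spec A [model_spec()].
#' @param weighted Population-weight the covariate / continuous outcome?
#' @return A tibble with one row per zone: `zone`, `population`, `outcome`,
#'   `covariate`, `n_units`; attributes `mean_polygon_population`, `scale`,
#'   `seed` carry provenance.
#' @export
aggregate_units <- function(map, zonation, spec, weighted = TRUE) {
  u <- map$units
  idx <- match(u$id, zonation$assignment$id)
  if (anyNA(idx)) stop("zonation is not defined over all the map's units")
  dat <- dplyr::mutate(u, zone = zonation$assignment$zone[idx])
  wmean <- function(x, w) {
    if (!weighted) return(mean(x))
    if (sum(w) <= 0) stop("zone with zero total population: weighted mean undefined")
    sum(x * w) / sum(w)
  }
  agg <- dat |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(
      outcome = if (is_count_family(spec)) sum(.data$outcome)
                else wmean(.data$outcome, .data$population),
      covariate = wmean(.data$covariate, .data$population),
      population = sum(.data$population),
      n_units = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("zone", "population", "outcome", "covariate", "n_units")
  attr(agg, "mean_polygon_population") <- sum(u$population) / nrow(agg)
  attr(agg, "scale") <- zonation$scale %||% zonation$target_population
  attr(agg, "seed") <- zonation$seed
  agg
}

#' Fit the association model to an aggregated dataset
#'
#' Fits by maximum likelihood (`negbin_rate` via [MASS::glm.nb()] with the
#' dispersion profiled, Poisson families via [stats::glm()]) or weighted
#' least squares (`gaussian_weighted` via [stats::lm()] with weights equal
#' to population).  Rate families use a `log(population)` offset so `beta`
#' is a per-unit-covariate log rate ratio.  The 95% CI is Wald on the link
#' scale.
#'
#' @param agg An aggregated dataset from [aggregate_units()] (or a
#'   minimal-level units table with the same columns).
#' @param spec A [model_spec()].
#' @param min_zones Minimum number of rows to attempt a fit (default 5;
#'   fits on fewer zones are numerically fragile).
#' @return A one-row tibble: `family`, `beta`, `alpha`, `nuisance`
#'   (dispersion theta for negbin, residual standard error for gaussian,
#'   `NA` for poisson), `se_beta`, `ci_lo`, `ci_hi`, `rr`, `n_zones`,
#'   `mean_polygon_population`, `scale`, `seed`, `converged`.
#' @export
fit_model <- function(agg, spec, min_zones = 5) {
  if (nrow(agg) < max(2, min_zones)) {
    stop("only ", nrow(agg), " zones; below the minimum of ", max(2, min_zones))
  }
  if (length(unique(agg$covariate)) < 2) stop("covariate is constant across zones")
  fam <- spec$family
  converged <- TRUE
  if (fam == "negbin_rate") {
    fit <- withCallingHandlers(
      MASS::glm.nb(outcome ~ covariate + offset(log(population)), data = agg),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    nuis <- fit$theta
  } else if (fam == "poisson_rate") {
    fit <- stats::glm(outcome ~ covariate + offset(log(population)),
                      family = stats::poisson(), data = agg)
    nuis <- NA_real_
    converged <- fit$converged
  } else if (fam == "poisson_individual") {
    fit <- stats::glm(outcome ~ covariate, family = stats::poisson(), data = agg)
    nuis <- NA_real_
    converged <- fit$converged
  } else {
    fit <- stats::lm(outcome ~ covariate, weights = population, data = agg)
    nuis <- summary(fit)$sigma
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  beta <- unname(cf["covariate"])
  se_beta <- unname(se["covariate"])
  zq <- stats::qnorm(0.975)
  tibble::tibble(
    family = fam,
    beta = beta,
    alpha = unname(cf["(Intercept)"]),
    nuisance = nuis,
    se_beta = se_beta,
    ci_lo = beta - zq * se_beta,
    ci_hi = beta + zq * se_beta,
    rr = exp(beta),
    n_zones = nrow(agg),
    mean_polygon_population = attr(agg, "mean_polygon_population") %||%
      (sum(agg$population) / nrow(agg)),
    scale = attr(agg, "scale") %||% NA_real_,
    seed = attr(agg, "seed") %||% NA_integer_,
    converged = converged
  )
}

#' Fit the model at the minimal level
#'
#' Fits directly to the unit table of the map, giving the minimal-level
#' estimate and its 95% Wald CI (the benchmark the simulation interval is
#' compared against when minimal-level fitting is feasible at all).
#'
#' @inheritParams fit_model
#' @param map A [bb_map()].
#' @return A one-row tibble as from [fit_model()].
#' @export
fit_minimal <- function(map, spec, min_zones = 5) {
  u <- map$units
  agg <- tibble::tibble(zone = u$id, population = u$population,
                        outcome = u$outcome, covariate = u$covariate,
                        n_units = 1L)
  attr(agg, "mean_polygon_population") <- map$minimal_mean_population
  fit_model(agg, spec, min_zones = min_zones)
}

#' Fit the model at every zonation of an ensemble
#'
#' Aggregates the map to each zonation and fits the model, collecting the
#' parameter estimates into one long tibble (`parameter` in `beta`,
#' `alpha`, `nuisance`) with one point per parameter per successful fit.
#' Fits that error are dropped with a warning naming their scale and seed.
#'
#' @param map A [bb_map()].
#' @param ensemble A list of zonations from [generate_ensemble()].
#' @param spec A [model_spec()].
#' @param min_zones Passed to [fit_model()].
#' @return A tibble: `parameter`, `scale`, `seed`,
#'   `mean_polygon_population`, `estimate`, `se`.
#' @export
estimate_across_ensemble <- function(map, ensemble, spec, min_zones = 5) {
  if (length(ensemble) == 0) stop("ensemble is empty")
  rows <- purrr::map(ensemble, function(z) {
    agg <- aggregate_units(map, z, spec)
    fit <- tryCatch(fit_model(agg, spec, min_zones = min_zones),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning("fit failed at scale ", z$scale %||% z$target_population,
              ", seed ", z$seed, "; point dropped", call. = FALSE)
      return(NULL)
    }
    tidyr::pivot_longer(
      fit[, c("beta", "alpha", "nuisance")],
      dplyr::everything(), names_to = "parameter", values_to = "estimate"
    ) |>
      dplyr::mutate(scale = fit$scale, seed = fit$seed,
                    mean_polygon_population = fit$mean_polygon_population,
                    se = ifelse(.data$parameter == "beta", fit$se_beta, NA_real_))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("all fits failed across the ensemble")
  out <- out[!is.na(out$estimate),
             c("parameter", "scale", "seed", "mean_polygon_population",
               "estimate", "se")]
  tibble::as_tibble(out)
}

#' Restrict an estimate set to scales above a stopping point
#'
#' A stopping point is a minimum mean polygon population below which model
#' estimates are unavailable (e.g. because of sparse events); points below
#' it are removed before curve fitting.
#'
#' @param set A tibble with a `mean_polygon_population` column.
#' @param min_mean_population The stopping-point population size.
#' @return The filtered tibble; errors if nothing survives.
#' @export
apply_stopping_point <- function(set, min_mean_population) {
  out <- dplyr::filter(set, .data$mean_polygon_population >= min_mean_population)
  if (nrow(out) == 0) {
    stop("stopping point ", min_mean_population, " removes every estimate")
  }
  out
}
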