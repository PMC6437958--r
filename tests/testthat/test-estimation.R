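spec_nb <- model_spec("negbin_rate")
spec_pois <- model_spec("poisson_rate")
spec_gauss <- model_spec("gaussian_weighted")

one_zone <- function(m) {
  structure(list(assignment = tibble::tibble(id = m$units$id, zone = "z001"),
                 target_population = sum(m$units$population), seed = 0L,
                 n_zones = 1L,
                 mean_polygon_population = sum(m$units$population),
                 threshold_min = 1, objective = 0),
            class = "zonation")
}

identity_zonation <- function(m) {
  structure(list(assignment = tibble::tibble(id = m$units$id, zone = m$units$id),
                 target_population = 1, seed = 0L,
                 n_zones = nrow(m$units),
                 mean_polygon_population = m$minimal_mean_population,
                 threshold_min = 0.1, objective = 0),
            class = "zonation")
}

test_that("aggregation conserves totals and takes population-weighted means", {
  m <- make_path_map(c(100, 300), outcome = c(2, 6), covariate = c(10, 20))
  agg <- aggregate_units(m, one_zone(m), spec_nb)
  expect_equal(agg$population, 400)
  expect_equal(agg$outcome, 8)
  expect_equal(agg$covariate, 17.5)

  # unweighted flag
  aggu <- aggregate_units(m, one_zone(m), spec_nb, weighted = FALSE)
  expect_equal(aggu$covariate, 15)

  # continuous outcome: weighted mean, not sum
  aggc <- aggregate_units(m, one_zone(m), spec_gauss)
  expect_equal(aggc$outcome, (100 * 2 + 300 * 6) / 400)

  # identity zonation reproduces the unit table
  aggi <- aggregate_units(m, identity_zonation(m), spec_nb)
  aggi <- aggi[match(m$units$id, aggi$zone), ]
  expect_equal(aggi$population, m$units$population)
  expect_equal(aggi$outcome, m$units$outcome)
  expect_equal(aggi$covariate, m$units$covariate)
})

test_that("nested aggregations agree on totals", {
  m <- make_lattice_map(4, 4, pop = 50, seed = 8)
  fine <- design_zonation(m, 100, threshold_min = 60, n_runs = 3, seed = 1)
  coarse <- design_zonation(m, 400, threshold_min = 240, n_runs = 3, seed = 1)
  af <- aggregate_units(m, fine, spec_nb)
  ac <- aggregate_units(m, coarse, spec_nb)
  expect_equal(sum(af$population), sum(ac$population))
  expect_equal(sum(af$outcome), sum(ac$outcome))
  expect_equal(sum(af$outcome), sum(m$units$outcome))
})

test_that("two-zone Poisson fit matches the saturated closed form", {
  agg <- tibble::tibble(zone = c("a", "b"), population = c(1000, 2000),
                        outcome = c(30, 20), covariate = c(1, 4),
                        n_units = 1L)
  fit <- fit_model(agg, spec_pois, min_zones = 2)
  r1 <- 30 / 1000; r2 <- 20 / 2000
  expect_equal(fit$beta, (log(r2) - log(r1)) / (4 - 1), tolerance = 1e-8)
  expect_equal(fit$rr, exp(fit$beta), tolerance = 1e-15)
})

test_that("noise-free gaussian data is recovered exactly", {
  x <- c(1, 3, 5, 9, 11, 14)
  agg <- tibble::tibble(zone = letters[1:6], population = c(10, 20, 30, 40, 50, 60),
                        outcome = 2.5 - 0.75 * x, covariate = x, n_units = 1L)
  fit <- fit_model(agg, spec_gauss)
  expect_equal(fit$beta, -0.75, tolerance = 1e-10)
  expect_equal(fit$alpha, 2.5, tolerance = 1e-10)
  expect_lt(fit$nuisance, 1e-8)
})

test_that("minimal-level NB fit recovers the generating parameters", {
  n <- 5000
  withr::with_seed(314, {
    units <- tibble::tibble(
      id = sprintf("u%05d", 1:n),
      population = round(stats::rlnorm(n, log(400) - 0.045, 0.3)),
      covariate = stats::runif(n, 0, 100))
  })
  m <- bb_map(dplyr::mutate(units, outcome = 0),
              data.frame(id_a = units$id[-n], id_b = units$id[-1]))
  m$units$outcome <- simulate_minimal_dataset(m, spec_nb, -3.97, -0.0144,
                                              2.7851, seed = 271)
  fit <- fit_minimal(m, spec_nb)
  expect_lt(abs(fit$beta - (-0.0144)), 3 * fit$se_beta)
  expect_lt(abs(fit$alpha - (-3.97)), 0.2)
  expect_gt(fit$nuisance, 2)
  expect_lt(fit$nuisance, 3.7)
  expect_true(fit$ci_lo < fit$beta & fit$beta < fit$ci_hi)
})

test_that("degenerate fits are refused", {
  agg <- tibble::tibble(zone = letters[1:6], population = 100,
                        outcome = rpois(6, 5), covariate = 1, n_units = 1L)
  expect_error(fit_model(agg, spec_nb), "constant")
  expect_error(fit_model(agg[1:3, ], spec_nb), "below the minimum")
})

test_that("ensemble estimation returns one point per parameter per fit", {
  m <- make_lattice_map(6, 6, pop = 400, seed = 4)
  m$units$outcome <- simulate_minimal_dataset(m, spec_nb, -3.97, -0.0144,
                                              2.7851, seed = 5)
  ens <- generate_ensemble(m, c(1500, 3000), n_per_scale = 3, base_seed = 2,
                           n_runs = 3, n_swap_cycles = 3)
  est <- suppressWarnings(estimate_across_ensemble(m, ens, spec_nb))
  expect_setequal(unique(est$parameter), c("beta", "alpha", "nuisance"))
  expect_true(all(est$mean_polygon_population > 0))
  expect_lte(nrow(est), 3 * length(ens))

  est2 <- suppressWarnings(estimate_across_ensemble(m, ens, spec_nb))
  expect_identical(est, est2)

  # an ensemble of one identity zonation reproduces the minimal fit
  ens_id <- list(identity_zonation(m))
  est_id <- estimate_across_ensemble(m, ens_id, spec_nb)
  fmin <- fit_minimal(m, spec_nb)
  expect_equal(est_id$estimate[est_id$parameter == "beta"], fmin$beta,
               tolerance = 1e-8)
  expect_equal(est_id$estimate[est_id$parameter == "nuisance"], fmin$nuisance,
               tolerance = 1e-6)
})

test_that("stopping points filter estimate sets", {
  set <- tibble::tibble(parameter = "beta",
                        mean_polygon_population = c(430, 2500, 8000),
                        estimate = c(-0.01, -0.02, -0.03))
  expect_equal(nrow(apply_stopping_point(set, 0)), 3)
  expect_equal(nrow(apply_stopping_point(set, 2000)), 2)
  expect_error(apply_stopping_point(set, 10000), "removes every")
})
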