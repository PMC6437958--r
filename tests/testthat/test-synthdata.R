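spec_nb <- model_spec("negbin_rate")

test_that("shift enumeration matches the closed form", {
  for (s in c(1:10, 50)) {
    cfg <- enumerate_shifted_zonations(s)
    expect_equal(nrow(cfg), 2 * (s - 1) + 1)
    expect_true(all(cfg$offset < s))
  }
  expect_equal(nrow(enumerate_shifted_zonations(50)), 99)
  expect_equal(enumerate_shifted_zonations(1)$direction, "none")
  expect_error(enumerate_shifted_zonations(0), ">= 1")
})

test_that("scenario generation is seeded and respects the population model", {
  scn <- synth_scenario(nrows = 8, ncols = 8, seed = 77)
  m1 <- generate_scenario(scn)
  m2 <- generate_scenario(scn)
  expect_identical(m1$units, m2$units)
  expect_true(all(m1$units$population > 0))
  expect_equal(mean(m1$units$population), 400, tolerance = 0.1)
  expect_equal(attr(m1, "true_effect"), -0.0144)

  mc <- generate_scenario(synth_scenario(nrows = 5, ncols = 5,
                                         population = "constant", seed = 1))
  expect_true(all(mc$units$population == 400))

  mi <- generate_scenario(synth_scenario(
    nrows = 5, ncols = 5, spec = model_spec("poisson_individual"),
    true_alpha = 0.5, true_beta = 0.01, seed = 2))
  expect_true(all(mi$units$population == 1))

  ms <- generate_scenario(synth_scenario(nrows = 10, ncols = 10,
                                         covariate = "smoothed", seed = 3))
  expect_equal(mean(ms$units$covariate), mean(
    generate_scenario(synth_scenario(nrows = 10, ncols = 10, seed = 3))$units$covariate),
    tolerance = 1e-9)
})

test_that("a null-effect scenario gives nominal minimal-level CI coverage", {
  scn <- synth_scenario(nrows = 10, ncols = 10, true_beta = 0, seed = 55)
  map <- generate_scenario(scn)
  hits <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    map$units$outcome <- simulate_minimal_dataset(map, spec_nb, -3.97, 0,
                                                  2.7851, seed = 1000 + r)
    fit <- fit_minimal(map, spec_nb)
    hits <- hits + as.integer(fit$ci_lo < 0 && 0 < fit$ci_hi)
  }
  prop <- hits / n_rep
  expect_lt(abs(prop - 0.95), 3 * sqrt(0.95 * 0.05 / n_rep))
})

test_that("grid shifts conserve retained subcell totals and drop the rest", {
  scn <- synth_scenario(nrows = 4, ncols = 4, subcell_factor = 3, seed = 9)
  map <- generate_scenario(scn)
  nr <- 12; nc <- 12
  for (off in 0:2) {
    agg <- maupsi:::shift_aggregate(map, nr, nc, 3, "right", off, spec_nb)
    rc <- maupsi:::id_to_rowcol(map$units$id)
    keep_cols <- (rc$col - 1 - off) >= 0 &
      (rc$col - 1 - off) < 3 * ((nc - off) %/% 3)
    expect_equal(sum(agg$population), sum(map$units$population[keep_cols]))
    expect_equal(sum(agg$outcome), sum(map$units$outcome[keep_cols]))
    expect_equal(attr(agg, "dropped_subcells"), sum(!keep_cols))
  }
})

test_that("s = 1 reduces to the minimal fit and column-constant fields are shift-invariant", {
  scn <- synth_scenario(nrows = 6, ncols = 6, subcell_factor = 1, seed = 13)
  map <- generate_scenario(scn)
  est <- estimates_across_shifts(map, s = 1, spec_nb)
  fmin <- fit_minimal(map, spec_nb)
  expect_equal(nrow(est), 1)
  expect_equal(est$beta, fmin$beta, tolerance = 1e-10)

  # a field that varies only by row is invariant to right shifts
  nr <- 12; nc <- 12
  units <- tibble::tibble(
    id = maupsi:::lattice_ids(nr, nc),
    population = 100,
    covariate = rep(seq(10, 90, length.out = nr), each = nc))
  units$outcome <- round(units$population * exp(-4 + 0.015 * units$covariate))
  m <- bb_map(units, build_lattice_graph(nr, nc))
  spec_p <- model_spec("poisson_rate")
  betas <- vapply(0:2, function(off) {
    agg <- maupsi:::shift_aggregate(m, nr, nc, 3, "right", off, spec_p)
    fit_model(agg, spec_p, min_zones = 3)$beta
  }, numeric(1))
  expect_equal(betas[2], betas[1], tolerance = 1e-10)
  expect_equal(betas[3], betas[1], tolerance = 1e-10)
})

test_that("estimates across shifts are ordered with a reproducibility summary", {
  scn <- synth_scenario(nrows = 10, ncols = 10, subcell_factor = 3,
                        true_beta = -0.0144, seed = 21)
  map <- generate_scenario(scn)
  est <- estimates_across_shifts(map, s = 3, spec_nb)
  expect_equal(nrow(est), 5)
  expect_true(!is.unsorted(est$beta))
  rep_sum <- attr(est, "reproducibility")
  expect_equal(rep_sum$frac_negative + rep_sum$frac_positive +
                 rep_sum$frac_crossing_zero, 1, tolerance = 1e-12)
  expect_true(all(est$ci_lo < est$beta & est$beta < est$ci_hi))
})
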