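test_that("threshold coefficients solve the anchor system exactly", {
  # independent oracle: direct 2x2 matrix inversion
  oracle <- function(s1, s2, f1, f2) {
    M <- matrix(c(s1, s2, s1^2, s2^2), 2, 2)
    drop(solve(M) %*% c(f1 * s1, f2 * s2))
  }
  co <- solve_threshold_coefficients(2000, 50000, 0.6, 0.8)
  expect_equal(c(co$a, co$b), oracle(2000, 50000, 0.6, 0.8), tolerance = 1e-12)

  # equal fractions force a linear threshold
  co2 <- solve_threshold_coefficients(100, 200, 0.5, 0.5)
  expect_equal(co2$a, 0.5, tolerance = 1e-12)
  expect_equal(co2$b, 0, tolerance = 1e-15)

  # anchors are reproduced exactly and the function is monotone between them
  co3 <- solve_threshold_coefficients(500, 10000)
  expect_equal(min_threshold(co3, 500), 300, tolerance = 1e-9)
  expect_equal(min_threshold(co3, 10000), 8000, tolerance = 1e-9)
  ts <- seq(500, 10000, by = 100)
  expect_true(all(diff(min_threshold(co3, ts)) > 0))

  expect_error(solve_threshold_coefficients(500, 500), "singular")
})

test_that("a four-unit path splits into the unique feasible two-zone shape", {
  m <- make_path_map(c(100, 100, 100, 100))
  z <- design_zonation(m, target_population = 200, threshold_min = 150,
                       n_runs = 5, seed = 3)
  expect_equal(z$n_zones, 2)
  validate_zonation(m, z)
  # exhaustive enumeration: contiguous 2-partitions of a path are cuts;
  # only the middle cut keeps both halves at 150+
  zones <- split(z$assignment$id, z$assignment$zone)
  expect_setequal(vapply(zones, length, integer(1)), c(2L, 2L))
  expect_true(all(sort(zones[[1]]) %in% c("u01", "u02")) ||
                all(sort(zones[[1]]) %in% c("u03", "u04")))
})

test_that("degenerate and infeasible zonations are handled", {
  m1 <- bb_map(tibble::tibble(id = "a", population = 500, outcome = 1,
                              covariate = 1),
               data.frame(id_a = character(), id_b = character()))
  z1 <- design_zonation(m1, target_population = 400, seed = 1)
  expect_equal(z1$n_zones, 1)

  m <- make_path_map(c(10, 10, 10))
  expect_error(design_zonation(m, target_population = 30, threshold_min = 31),
               "threshold_min")
  expect_error(design_zonation(m, target_population = 100, threshold_min = 50),
               "infeasible")
})

test_that("different seeds give different but valid zonations; same seed is identical", {
  m <- make_lattice_map(8, 8, pop = 100)
  za <- design_zonation(m, 800, n_runs = 3, seed = 1)
  zb <- design_zonation(m, 800, n_runs = 3, seed = 2)
  validate_zonation(m, za)
  validate_zonation(m, zb)
  expect_false(identical(za$assignment, zb$assignment))

  za2 <- design_zonation(m, 800, n_runs = 3, seed = 1)
  expect_identical(za$assignment, za2$assignment)
  expect_identical(za$objective, za2$objective)
})

test_that("ensembles satisfy the invariants at every scale and reproduce by seed", {
  m <- make_lattice_map(10, 10, pop = 100, seed = 5)
  scales <- c(500, 1000, 2000)
  ens <- generate_ensemble(m, scales, n_per_scale = 4, base_seed = 11,
                           n_runs = 3, n_swap_cycles = 3)
  expect_length(ens, 12)
  for (z in ens) validate_zonation(m, z)

  # thresholds follow the quadratic anchored at the scale range
  co <- solve_threshold_coefficients(500, 2000)
  got_thr <- vapply(ens, function(z) z$threshold_min, numeric(1))
  expect_equal(got_thr, min_threshold(co, rep(scales, each = 4)),
               tolerance = 1e-12)

  # scale ordering: coarser targets give larger mean polygon populations
  mpp <- vapply(ens, function(z) z$mean_polygon_population, numeric(1))
  tgt <- vapply(ens, function(z) z$target_population, numeric(1))
  expect_gt(suppressWarnings(cor(tgt, mpp, method = "spearman")), 0.95)

  ens2 <- generate_ensemble(m, scales, n_per_scale = 4, base_seed = 11,
                            n_runs = 3, n_swap_cycles = 3)
  expect_identical(lapply(ens, function(z) z$assignment),
                   lapply(ens2, function(z) z$assignment))
})

test_that("zero-population units are absorbed into zones", {
  pops <- c(100, 0, 100, 100)
  m <- make_path_map(pops)
  z <- design_zonation(m, 150, threshold_min = 100, n_runs = 5, seed = 2)
  validate_zonation(m, z)
  # the zero-population unit cannot stand alone as a zone
  zero_zone <- z$assignment$zone[z$assignment$id == "u02"]
  expect_gte(sum(z$assignment$zone == zero_zone), 2)
})

test_that("disconnected maps need per_component and then zonate each part", {
  units <- tibble::tibble(id = c("a1", "a2", "b1", "b2"),
                          population = c(100, 100, 100, 100),
                          outcome = 1, covariate = 1:4)
  pairs <- data.frame(id_a = c("a1", "b1"), id_b = c("a2", "b2"))
  m <- suppressWarnings(bb_map(units, pairs))
  expect_error(design_zonation(m, 200, seed = 1), "disconnected")
  z <- design_zonation(m, 200, seed = 1, per_component = TRUE)
  validate_zonation(m, z)
  expect_equal(z$n_zones, 2)
})
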