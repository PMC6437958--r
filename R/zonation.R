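#' Solve the quadratic minimum-threshold coefficients
#'
#' The minimum population threshold of a zone is tied to the target
#' population of its scale through `threshold = a * t + b * t^2`.  The two
#' coefficients are obtained by anchoring the threshold at the smallest and
#' largest scales to fixed fractions of the target population there
#' (60% and 80% by default) and solving the resulting 2x2 linear system.
#'
#' @param scale_min,scale_max Smallest and largest target populations of
#'   the ensemble; must differ.
#' @param frac_min,frac_max Threshold fractions anchored at `scale_min` and
#'   `scale_max` respectively; in (0, 1].
#' @return A list with elements `a` and `b`.
#' @examples
#' solve_threshold_coefficients(500, 10000)  # a ~ 0.589, b ~ 2.11e-5
#' @export
solve_threshold_coefficients <- function(scale_min, scale_max,
                                         frac_min = 0.6, frac_max = 0.8) {
  if (scale_min >= scale_max) stop("scale_min must be < scale_max (system is singular otherwise)")
  if (any(c(frac_min, frac_max) <= 0) || any(c(frac_min, frac_max) > 1)) {
    stop("threshold fractions must lie in (0, 1]")
  }
  A <- rbind(c(scale_min, scale_min^2),
             c(scale_max, scale_max^2))
  rhs <- c(frac_min * scale_min, frac_max * scale_max)
  ab <- solve(A, rhs)
  list(a = unname(ab[1]), b = unname(ab[2]))
}

#' Minimum population threshold at a target population
#'
#' @param coeffs Coefficients from [solve_threshold_coefficients()].
#' @param target_population Positive target population.
#' @return `a * t + b * t^2`.
#' @export
min_threshold <- function(coeffs, target_population) {
  coeffs$a * target_population + coeffs$b * target_population^2
}

#' Design one contiguity-constrained zonation
#'
#' Aggregates the minimal building-block units of a map into contiguous
#' zones whose populations all reach `threshold_min`, aiming at
#' `target_population` per zone.  The algorithm is AZP-style: `n_runs`
#' independent runs of (i) seeded random region growing — a random
#' unassigned unit seeds a zone which absorbs random adjacent unassigned
#' units until its population reaches the threshold, stopping once further
#' growth would overshoot the target; under-threshold remnants are
#' dissolved and merged into the adjacent zone with the smallest
#' population — followed by (ii) `n_swap_cycles` cycles of boundary-unit
#' swaps that are accepted when they reduce the objective
#' `sum(abs(zone_population - target_population))` while keeping the donor
#' zone contiguous and above threshold.  The best run by the objective is
#' returned.  No maximum population constraint is applied.
#'
#' Results are deterministic given the map, the configuration, and `seed`;
#' unit ids are ordered lexicographically internally so the input row
#' order never affects the result.
#'
#' @param map A [bb_map()].
#' @param target_population Target zone population.
#' @param threshold_min Minimum zone population; defaults to
#'   `0.6 * target_population`.
#' @param n_runs,n_swap_cycles Run and swap-cycle counts (defaults 50, 10).
#' @param seed Integer seed.
#' @param per_component If `TRUE`, a disconnected contiguity graph is
#'   zonated one component at a time; otherwise disconnection is an error.
#' @return An object of class `zonation`: list with `assignment` (tibble
#'   `id`, `zone`), `target_population`, `threshold_min`, `seed`,
#'   `n_zones`, `mean_polygon_population`, `objective`.
#' @export
design_zonation <- function(map, target_population, threshold_min = NULL,
                            n_runs = 50, n_swap_cycles = 10, seed = 1L,
                            per_component = FALSE) {
  stopifnot(inherits(map, "bb_map"))
  if (is.null(threshold_min)) threshold_min <- 0.6 * target_population
  if (threshold_min <= 0 || threshold_min > target_population) {
    stop("need 0 < threshold_min <= target_population")
  }
  if (n_runs < 1 || n_swap_cycles < 0) stop("n_runs >= 1 and n_swap_cycles >= 0 required")

  ids <- sort(map$units$id)
  pops <- map$units$population[match(ids, map$units$id)]
  adj <- adjacency_index(map$graph, ids)

  comp <- igraph::components(map$graph)
  if (comp$no > 1 && !per_component) {
    stop("contiguity graph is disconnected; set per_component = TRUE to zonate each component separately")
  }
  membership <- comp$membership[ids]

  zone_of <- integer(length(ids))
  objective <- 0
  next_label <- 0L
  withr::with_seed(seed, {
    for (k in seq_len(comp$no)) {
      in_comp <- which(membership == k)
      if (sum(pops[in_comp]) < threshold_min) {
        stop("total population of a component (", sum(pops[in_comp]),
             ") is below threshold_min (", threshold_min, "): infeasible")
      }
      best <- NULL
      for (run in seq_len(n_runs)) {
        cand <- azp_one_run(in_comp, adj, pops, target_population,
                            threshold_min, n_swap_cycles)
        if (is.null(best) || cand$objective < best$objective) best <- cand
      }
      zone_of[in_comp] <- best$zone_of[in_comp] + next_label
      next_label <- next_label + max(best$zone_of[in_comp])
      objective <- objective + best$objective
    }
  })

  n_zones <- length(unique(zone_of))
  zone_lab <- sprintf("z%03d", match(zone_of, sort(unique(zone_of))))
  structure(
    list(assignment = tibble::tibble(id = ids, zone = zone_lab),
         target_population = target_population,
         threshold_min = threshold_min,
         seed = seed,
         n_zones = n_zones,
         mean_polygon_population = sum(pops) / n_zones,
         objective = objective),
    class = "zonation"
  )
}

#' @export
print.zonation <- function(x, ...) {
  cat("<zonation> ", x$n_zones, " zones, target ", x$target_population,
      ", threshold ", format(x$threshold_min, digits = 5),
      ", mean polygon population ",
      format(x$mean_polygon_population, digits = 6),
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# adjacency as a list of integer indices in the order of `ids`
adjacency_index <- function(graph, ids) {
  nbr <- igraph::as_adj_list(graph)
  names(nbr) <- igraph::V(graph)$name
  lapply(ids, function(id) {
    nm <- names(nbr[[id]])
    if (is.null(nm)) nm <- igraph::V(graph)$name[as.integer(nbr[[id]])]
    sort(match(nm, ids))
  })
}

# One region-growing + swap run restricted to the unit indices `in_comp`.
# Uses the current RNG stream.  Returns zone_of (integer labels, 0 outside
# the component) and the objective value.
azp_one_run <- function(in_comp, adj, pops, target, threshold, n_swap_cycles) {
  n <- length(pops)
  zone_of <- integer(n)
  unassigned <- rep(FALSE, n)
  unassigned[in_comp] <- TRUE
  zone_pop <- numeric(0)

  while (any(unassigned)) {
    free <- which(unassigned)
    u <- if (length(free) == 1) free else free[sample.int(length(free), 1)]
    z <- length(zone_pop) + 1L
    zone_of[u] <- z
    unassigned[u] <- FALSE
    pop <- pops[u]
    frontier <- adj[[u]][unassigned[adj[[u]]]]
    repeat {
      if (pop >= target) break
      frontier <- frontier[unassigned[frontier]]
      if (length(frontier) == 0) break
      c_idx <- if (length(frontier) == 1) frontier else frontier[sample.int(length(frontier), 1)]
      if (pop >= threshold && pop + pops[c_idx] > target) break
      zone_of[c_idx] <- z
      unassigned[c_idx] <- FALSE
      pop <- pop + pops[c_idx]
      frontier <- sort(unique(c(frontier, adj[[c_idx]][unassigned[adj[[c_idx]]]])))
    }
    zone_pop <- c(zone_pop, pop)
  }

  # dissolve under-threshold zones and merge their units into neighbours
  weak <- which(zone_pop < threshold)
  if (length(weak) > 0) {
    leftovers <- which(zone_of %in% weak)
    zone_of[leftovers] <- 0L
    keep <- setdiff(seq_along(zone_pop), weak)
    relab <- integer(length(zone_pop)); relab[keep] <- seq_along(keep)
    pos <- zone_of > 0L
    zone_of[pos] <- relab[zone_of[pos]]
    zone_pop <- zone_pop[keep]
    while (length(leftovers) > 0) {
      progressed <- FALSE
      ord <- if (length(leftovers) == 1) leftovers else sample(sort(leftovers))
      for (u in ord) {
        nz <- unique(zone_of[adj[[u]]])
        nz <- nz[nz > 0L]
        if (length(nz) > 0) {
          z <- nz[which.min(zone_pop[nz])]
          zone_of[u] <- z
          zone_pop[z] <- zone_pop[z] + pops[u]
          progressed <- TRUE
        }
      }
      leftovers <- which(zone_of == 0L & seq_along(zone_of) %in% in_comp)
      if (!progressed && length(leftovers) > 0) {
        # an entire component's zones dissolved: make it one zone
        z <- length(zone_pop) + 1L
        zone_of[leftovers] <- z
        zone_pop <- c(zone_pop, sum(pops[leftovers]))
        leftovers <- integer(0)
      }
    }
  }

  # swap optimisation
  for (cycle in seq_len(n_swap_cycles)) {
    boundary <- in_comp[vapply(in_comp, function(u) {
      any(zone_of[adj[[u]]] != zone_of[u])
    }, logical(1))]
    if (length(boundary) == 0) break
    ord <- if (length(boundary) == 1) boundary else sample(sort(boundary))
    moved <- FALSE
    for (u in ord) {
      z1 <- zone_of[u]
      members <- which(zone_of == z1)
      if (length(members) <= 1) next
      nz <- unique(zone_of[adj[[u]]])
      nz <- nz[nz != z1 & nz > 0L]
      if (length(nz) == 0) next
      w <- pops[u]
      d <- (abs(zone_pop[z1] - w - target) + abs(zone_pop[nz] + w - target)) -
        (abs(zone_pop[z1] - target) + abs(zone_pop[nz] - target))
      best <- which.min(d)
      if (d[best] >= -1e-9) next
      if (zone_pop[z1] - w < threshold) next
      if (!connected_after_removal(members, u, adj)) next
      z2 <- nz[best]
      zone_of[u] <- z2
      zone_pop[z1] <- zone_pop[z1] - w
      zone_pop[z2] <- zone_pop[z2] + w
      moved <- TRUE
    }
    if (!moved) break
  }

  list(zone_of = zone_of, objective = sum(abs(zone_pop - target)))
}

# BFS check that `members` minus `u` stays connected
connected_after_removal <- function(members, u, adj) {
  rest <- setdiff(members, u)
  if (length(rest) <= 1) return(TRUE)
  inset <- logical(length(adj))
  inset[rest] <- TRUE
  visited <- logical(length(adj))
  queue <- rest[1]
  visited[queue] <- TRUE
  count <- 1L
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]
    nb <- nb[inset[nb] & !visited[nb]]
    if (length(nb) > 0) {
      visited[nb] <- TRUE
      count <- count + length(nb)
      queue <- c(queue, nb)
    }
  }
  count == length(rest)
}

#' Generate a multi-scale ensemble of zonations
#'
#' Builds `n_per_scale` zonations at each target-population scale, with the
#' minimum threshold at each scale obtained from the quadratic threshold
#' function anchored at the smallest and largest scales
#' ([solve_threshold_coefficients()]).  Seeds are derived deterministically
#' as `base_seed + index` so an ensemble is exactly reproducible.
#'
#' @param map A [bb_map()].
#' @param scales Vector of target populations.
#' @param n_per_scale Zonations per scale (default 100).
#' @param base_seed Integer base seed.
#' @param frac_min,frac_max Threshold anchor fractions (defaults 0.6, 0.8).
#' @param n_runs,n_swap_cycles Passed to [design_zonation()].
#' @param per_component Passed to [design_zonation()].
#' @return A list of [design_zonation()] results, with attribute `scales`.
#' @export
generate_ensemble <- function(map, scales, n_per_scale = 100, base_seed = 1L,
                              frac_min = 0.6, frac_max = 0.8,
                              n_runs = 50, n_swap_cycles = 10,
                              per_component = FALSE) {
  if (length(scales) == 0) stop("scales must be non-empty")
  scales <- as.numeric(scales)
  if (length(unique(scales)) > 1) {
    coeffs <- solve_threshold_coefficients(min(scales), max(scales),
                                           frac_min, frac_max)
    thresholds <- min_threshold(coeffs, scales)
  } else {
    thresholds <- frac_min * scales
  }
  grid <- tidyr::expand_grid(scale_i = seq_along(scales), rep = seq_len(n_per_scale))
  out <- purrr::pmap(grid, function(scale_i, rep) {
    idx <- (scale_i - 1L) * n_per_scale + rep
    z <- design_zonation(map, scales[scale_i],
                         threshold_min = thresholds[scale_i],
                         n_runs = n_runs, n_swap_cycles = n_swap_cycles,
                         seed = base_seed + idx - 1L,
                         per_component = per_component)
    z$scale <- scales[scale_i]
    z
  })
  attr(out, "scales") <- scales
  out
}

#' Check the structural invariants of a zonation
#'
#' Verifies that the assignment is a total partition of the map's units,
#' every zone is contiguous, and every zone's population reaches the
#' threshold used at construction.
#'
#' @param map A [bb_map()].
#' @param zonation A [design_zonation()] result.
#' @return Invisibly `TRUE`; errors with a message otherwise.
#' @export
validate_zonation <- function(map, zonation) {
  a <- zonation$assignment
  if (!setequal(a$id, map$units$id) || nrow(a) != nrow(map$units)) {
    stop("assignment is not a total partition of the map's units")
  }
  pops <- map$units$population[match(a$id, map$units$id)]
  by_zone <- split(seq_len(nrow(a)), a$zone)
  for (z in names(by_zone)) {
    idx <- by_zone[[z]]
    if (!is_contiguous(map$graph, a$id[idx])) stop("zone ", z, " is not contiguous")
    if (sum(pops[idx]) < zonation$threshold_min - 1e-9) {
      stop("zone ", z, " population ", sum(pops[idx]),
           " below threshold ", zonation$threshold_min)
    }
  }
  invisible(TRUE)
}
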