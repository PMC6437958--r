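# Independent oracles used across the suite.

# flood-fill connectivity over a raw pair list (no igraph)
flood_fill_connected <- function(pairs, subset) {
  subset <- as.character(subset)
  if (length(subset) <= 1) return(TRUE)
  nbrs <- function(v) {
    unique(c(pairs[[2]][pairs[[1]] == v], pairs[[1]][pairs[[2]] == v]))
  }
  seen <- subset[1]
  frontier <- subset[1]
  while (length(frontier) > 0) {
    nxt <- setdiff(intersect(unique(unlist(lapply(frontier, nbrs))), subset), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(subset)
}

# brute-force lattice adjacency by coordinate comparison
brute_lattice_edges <- function(nrows, ncols, rule) {
  cells <- expand.grid(r = seq_len(nrows), c = seq_len(ncols))
  n <- nrow(cells)
  count <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dr <- abs(cells$r[i] - cells$r[j]); dc <- abs(cells$c[i] - cells$c[j])
      adj <- if (rule == "rook") dr + dc == 1 else max(dr, dc) == 1
      if (adj) count <- count + 1L
    }
  }
  count
}

# small path-graph map with given populations
make_path_map <- function(pops, outcome = NULL, covariate = NULL) {
  n <- length(pops)
  ids <- sprintf("u%02d", seq_len(n))
  units <- tibble::tibble(
    id = ids, population = pops,
    outcome = outcome %||% stats::rpois(n, pmax(pops, 1) * 0.01),
    covariate = covariate %||% seq_len(n))
  pairs <- data.frame(id_a = ids[-n], id_b = ids[-1])
  bb_map(units, pairs)
}

# lattice map with constant or supplied attributes
make_lattice_map <- function(nr, nc, pop = 100, outcome = NULL,
                             covariate = NULL, seed = 1) {
  n <- nr * nc
  withr::with_seed(seed, {
    units <- tibble::tibble(
      id = maupsi:::lattice_ids(nr, nc),
      population = rep(pop, length.out = n),
      outcome = outcome %||% stats::rpois(n, 5),
      covariate = covariate %||% stats::runif(n, 0, 100))
  })
  bb_map(units, build_lattice_graph(nr, nc))
}

# direct construction of a flag set for overlay oracles
make_flag_set <- function(flagged, all_units) {
  structure(list(flagged_zones = NULL, flagged_units = sort(flagged),
                 all_units = sort(all_units),
                 direction = "above", alpha_level = 0.05,
                 test = "poisson_exact"),
            class = "flag_set")
}

`%||%` <- rlang::`%||%`
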