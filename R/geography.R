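#' Build a contiguity graph from an adjacency pair list
#'
#' Constructs a symmetric, simple (no self-loop) undirected graph over a
#' given set of unit identifiers from an edge list.  Duplicate and reversed
#' pairs are collapsed to a single edge.  Identifiers appearing in `ids` but
#' in no pair become isolated nodes; a warning lists them, since isolated
#' building blocks can never be aggregated into a multi-unit zone.
#'
#' @param pairs A data frame with two columns (`id_a`, `id_b`, or any two
#'   columns taken positionally) giving adjacent unit pairs, or a
#'   two-column matrix.  May have zero rows.
#' @param ids Character vector of all unit identifiers the graph must cover.
#' @return An [igraph::igraph] object whose vertex names are exactly `ids`.
#' @examples
#' g <- build_graph_from_pairs(data.frame(a = "1", b = "2"), ids = c("1", "2"))
#' igraph::ecount(g)
#' @export
build_graph_from_pairs <- function(pairs, ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate unit ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) > 0) {
    a <- as.character(pairs[[1]])
    b <- as.character(pairs[[2]])
    unknown <- setdiff(c(a, b), ids)
    if (length(unknown) > 0) {
      stop("adjacency pairs reference unknown unit ids: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    # canonical orientation so (u,v) and (v,u) dedup to one edge
    lo <- pmin(a, b); hi <- pmax(a, b)
    edges <- unique(data.frame(lo = lo, hi = hi, stringsAsFactors = FALSE))
  } else {
    edges <- data.frame(lo = character(), hi = character())
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  iso <- ids[igraph::degree(g)[ids] == 0]
  if (length(iso) > 0 && length(ids) > 1) {
    warning("isolated unit ids (no contiguity): ",
            paste(utils::head(iso, 10), collapse = ", "))
  }
  g
}

#' Build the contiguity graph of a regular lattice
#'
#' Cells are laid out row-major and named `"r<i>c<j>"`.  Under the rook rule
#' cells sharing an edge are adjacent; under the queen rule diagonal
#' neighbours are adjacent too.
#'
#' @param nrows,ncols Positive lattice dimensions.
#' @param adjacency_rule `"rook"` (default) or `"queen"`.
#' @return An [igraph::igraph] with `nrows * ncols` named vertices.
#' @export
build_lattice_graph <- function(nrows, ncols, adjacency_rule = c("rook", "queen")) {
  adjacency_rule <- match.arg(adjacency_rule)
  if (nrows < 1 || ncols < 1) stop("lattice dimensions must be positive")
  ids <- lattice_ids(nrows, ncols)
  idx <- function(r, c) (r - 1L) * ncols + c
  e_from <- integer(0); e_to <- integer(0)
  if (ncols > 1) {
    r <- rep(seq_len(nrows), each = ncols - 1L)
    c <- rep(seq_len(ncols - 1L), times = nrows)
    e_from <- c(e_from, idx(r, c)); e_to <- c(e_to, idx(r, c + 1L))
  }
  if (nrows > 1) {
    r <- rep(seq_len(nrows - 1L), each = ncols)
    c <- rep(seq_len(ncols), times = nrows - 1L)
    e_from <- c(e_from, idx(r, c)); e_to <- c(e_to, idx(r + 1L, c))
  }
  if (adjacency_rule == "queen" && nrows > 1 && ncols > 1) {
    r <- rep(seq_len(nrows - 1L), each = ncols - 1L)
    c <- rep(seq_len(ncols - 1L), times = nrows - 1L)
    e_from <- c(e_from, idx(r, c), idx(r, c + 1L))
    e_to   <- c(e_to, idx(r + 1L, c + 1L), idx(r + 1L, c))
  }
  edges <- data.frame(lo = ids[e_from], hi = ids[e_to])
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = ids))
}

lattice_ids <- function(nrows, ncols) {
  paste0("r", rep(seq_len(nrows), each = ncols),
         "c", rep(seq_len(ncols), times = nrows))
}

#' Is a subset of units contiguous?
#'
#' @param graph A contiguity graph.
#' @param subset Non-empty character vector of unit ids, all present in
#'   `graph`.
#' @return `TRUE` iff the induced subgraph is connected.
#' @export
is_contiguous <- function(graph, subset) {
  subset <- as.character(subset)
  if (length(subset) == 0) stop("subset must be non-empty")
  missing <- setdiff(subset, igraph::V(graph)$name)
  if (length(missing) > 0) {
    stop("subset ids not in graph: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  sub <- igraph::induced_subgraph(graph, subset)
  igraph::is_connected(sub)
}

#' Assemble a building-block map
#'
#' Bundles the minimal-areal-unit attribute table with its contiguity
#' graph.  The units table must have columns `id`, `population`, `outcome`,
#' and `covariate`; `population` must be non-negative.  The mean unit
#' population (`minimal_mean_population`) is the x-coordinate of the
#' minimal level on all scaling curves.
#'
#' @param units Data frame with columns `id`, `population`, `outcome`,
#'   `covariate`.
#' @param adjacency Either a two-column data frame of adjacent id pairs, or
#'   an [igraph::igraph] over exactly the unit ids.
#' @return An object of class `bb_map`: a list with elements `units`
#'   (tibble), `graph` (igraph), and `minimal_mean_population`.
#' @export
bb_map <- function(units, adjacency) {
  required <- c("id", "population", "outcome", "covariate")
  miss <- setdiff(required, names(units))
  if (length(miss) > 0) {
    stop("units table missing column(s): ", paste(miss, collapse = ", "))
  }
  units <- tibble::as_tibble(units)
  units$id <- as.character(units$id)
  if (anyDuplicated(units$id)) stop("duplicate unit ids in units table")
  if (any(units$population < 0)) stop("populations must be non-negative")
  if (igraph::is_igraph(adjacency)) {
    graph <- adjacency
    if (!setequal(igraph::V(graph)$name, units$id)) {
      stop("graph node set must equal the unit id set")
    }
  } else {
    graph <- build_graph_from_pairs(adjacency, units$id)
  }
  structure(
    list(units = units,
         graph = graph,
         minimal_mean_population = sum(units$population) / nrow(units)),
    class = "bb_map"
  )
}

#' @export
print.bb_map <- function(x, ...) {
  cat("<bb_map> ", nrow(x$units), " units, ",
      igraph::ecount(x$graph), " adjacencies, mean unit population ",
      format(x$minimal_mean_population, digits = 5), "\n", sep = "")
  invisible(x)
}
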