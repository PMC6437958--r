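#' Read a unit attribute table
#'
#' Expects a CSV with header `id,population,outcome,covariate`.  A missing
#' column is reported by name.
#'
#' @param path CSV file path.
#' @return A tibble with `id` as character.
#' @export
read_units <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("id", "population", "outcome", "covariate")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("units file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df$id <- as.character(df$id)
  bad <- which(!is.finite(df$population) | df$population < 0)
  if (length(bad) > 0) {
    stop("invalid population at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  df[required]
}

#' Read an adjacency pair list
#'
#' Expects a CSV with header `id_a,id_b`.
#'
#' @param path CSV file path.
#' @return A tibble of character id pairs.
#' @export
read_adjacency <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(c("id_a", "id_b"), names(df))
  if (length(miss) > 0) {
    stop("adjacency file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df$id_a <- as.character(df$id_a)
  df$id_b <- as.character(df$id_b)
  df[c("id_a", "id_b")]
}

#' Derive adjacency from a GeoJSON FeatureCollection of polygons
#'
#' Polygons are used only to derive contiguity: two features are
#' rook-adjacent when they share a boundary segment (two consecutive
#' vertices) and queen-adjacent when they share at least one vertex.
#' Feature ids are taken from the `id` property (or feature `id`).
#' Coordinates are matched after rounding to 9 decimals; no
#' coordinate-reference-system handling is performed.
#'
#' @param path GeoJSON file path.
#' @param adjacency_rule `"rook"` (default, census-geography convention)
#'   or `"queen"`.
#' @return A tibble `id_a`, `id_b` of adjacent feature pairs.
#' @export
read_geojson_adjacency <- function(path, adjacency_rule = c("rook", "queen")) {
  adjacency_rule <- match.arg(adjacency_rule)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  feats <- gj$features
  ids <- vapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    as.character(f$properties$id %||% f$id %||% i)
  }, character(1))
  rings <- lapply(feats, function(f) {
    g <- f$geometry
    coords <- if (identical(g$type, "Polygon")) list(g$coordinates) else
      if (identical(g$type, "MultiPolygon")) g$coordinates else
        stop("unsupported geometry type: ", g$type)
    pts <- list()
    for (poly in coords) {
      ring <- poly[[1]]  # outer ring only; holes do not create contiguity
      pts <- c(pts, lapply(ring, function(p) {
        sprintf("%.9f_%.9f", as.numeric(p[[1]]), as.numeric(p[[2]]))
      }))
    }
    unlist(pts)
  })
  verts <- lapply(rings, unique)
  segs <- lapply(rings, function(r) {
    if (length(r) < 2) return(character(0))
    a <- r[-length(r)]; b <- r[-1]
    unique(paste(pmin(a, b), pmax(a, b), sep = "|"))
  })
  n <- length(feats)
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      touch <- if (adjacency_rule == "rook") {
        length(intersect(segs[[i]], segs[[j]])) > 0
      } else {
        length(intersect(verts[[i]], verts[[j]])) > 0
      }
      if (touch) pairs[[length(pairs) + 1]] <- c(ids[i], ids[j])
    }
  }
  if (length(pairs) == 0) {
    return(tibble::tibble(id_a = character(0), id_b = character(0)))
  }
  m <- do.call(rbind, pairs)
  tibble::tibble(id_a = m[, 1], id_b = m[, 2])
}

#' Write a zonation to CSV with a JSON sidecar
#'
#' The CSV holds the `id,zone_label` assignment; the sidecar
#' (`<path>.json`) records target population, threshold, seed, mean
#' polygon population, and the objective value, so the zonation is fully
#' described by its files.
#'
#' @param zonation A [design_zonation()] result.
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_zonation <- function(zonation, path) {
  readr::write_csv(
    dplyr::rename(zonation$assignment, zone_label = "zone"), path)
  meta <- list(target_population = zonation$target_population,
               threshold_min = zonation$threshold_min,
               seed = zonation$seed,
               n_zones = zonation$n_zones,
               mean_polygon_population = zonation$mean_polygon_population,
               objective_value = zonation$objective,
               objective = "sum(abs(zone_population - target_population))")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a zonation written by [write_zonation()]
#'
#' @param path CSV path (the `.json` sidecar must sit beside it).
#' @return A `zonation` object.
#' @export
read_zonation <- function(path) {
  a <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(c("id", "zone_label"), names(a))
  if (length(miss) > 0) stop("zonation file missing column(s): ",
                             paste(miss, collapse = ", "))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(assignment = tibble::tibble(id = as.character(a$id),
                                     zone = as.character(a$zone_label)),
         target_population = meta$target_population,
         threshold_min = meta$threshold_min,
         seed = meta$seed,
         n_zones = meta$n_zones %||% length(unique(a$zone_label)),
         mean_polygon_population = meta$mean_polygon_population,
         objective = meta$objective_value),
    class = "zonation")
}

#' Write an estimate set to CSV
#'
#' Columns `parameter,scale,seed,mean_polygon_population,estimate,se`,
#' full precision.
#'
#' @param set Output of [estimate_across_ensemble()].
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_estimates <- function(set, path) {
  readr::write_csv(set, path)
  invisible(path)
}

#' Write a simulation interval to JSON
#'
#' @param si A [construct_si()] result.
#' @param path Output JSON path.
#' @return Invisibly `path`.
#' @export
write_si <- function(si, path) {
  out <- list(A = si$lower, B = si$upper, EI_beta = si$ei_beta,
              EI_alpha = si$ei_alpha, EI_nuisance = si$ei_nuisance,
              coverage = si$coverage, converged = si$converged,
              iterations = si$iterations,
              n_inner_sim = si$n_inner_sim,
              convergence_tol_frac = si$convergence_tol_frac,
              stopping_point = si$stopping_point,
              seed = si$seed,
              quantile_type = 7,
              diagnostics = si$diagnostics)
  if (!is.null(si$rr)) out$rate_ratio <- si$rr
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a run manifest
#'
#' Records the package version, the seed, and every setting of a run so a
#' published result file is reproducible from its manifest alone.
#'
#' @param settings Named list of the run's settings.
#' @param path Output JSON path.
#' @return Invisibly `path`.
#' @export
write_manifest <- function(settings, path) {
  manifest <- c(list(package = "maupsi",
                     version = as.character(utils::packageVersion("maupsi")),
                     timestamp = NULL),
                settings)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
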