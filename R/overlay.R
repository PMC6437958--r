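#' Flag statistically extreme zones and expand to minimal units
#'
#' Identifies zones whose rate (or population-weighted mean) is
#' statistically above (or below) the study-wide reference at the given
#' one-sided level, then expands the flagged zones to their member
#' minimal units.  For count outcomes the default test is the exact
#' one-sided Poisson tail of the zone count against the expected count
#' `zone population * study-wide rate`; `"normal_approx"` uses the
#' corresponding z-test.  For continuous outcomes (`"gaussian_mean"`) the
#' zone's weighted mean is z-tested against the study-wide weighted mean
#' with a per-person variance estimated across zones.  No multiplicity
#' adjustment is applied; the flagging rule is a display convention, so
#' repeat-appearance probabilities are rule-dependent.
#'
#' @param agg Aggregated dataset from [aggregate_units()].
#' @param zonation The zonation that produced `agg` (for unit membership).
#' @param direction `"above"` (high-rate) or `"below"` (e.g. low-income).
#' @param alpha_level One-sided test level (default 0.05).
#' @param test `"poisson_exact"`, `"normal_approx"`, or `"gaussian_mean"`.
#' @return An object of class `flag_set`: `flagged_zones`,
#'   `flagged_units`, `all_units`, plus the rule fields.
#' @export
flag_zones <- function(agg, zonation, direction = c("above", "below"),
                       alpha_level = 0.05,
                       test = c("poisson_exact", "normal_approx", "gaussian_mean")) {
  direction <- match.arg(direction)
  test <- match.arg(test)
  if (alpha_level <= 0 || alpha_level >= 1) stop("alpha_level must be in (0,1)")
  if (test %in% c("poisson_exact", "normal_approx")) {
    if (sum(agg$outcome) == 0) stop("zero total events: rate test undefined")
    rate <- sum(agg$outcome) / sum(agg$population)
    expected <- agg$population * rate
    p <- if (test == "poisson_exact") {
      if (direction == "above") {
        stats::ppois(agg$outcome - 1, expected, lower.tail = FALSE)
      } else {
        stats::ppois(agg$outcome, expected)
      }
    } else {
      z <- (agg$outcome - expected) / sqrt(expected)
      if (direction == "above") stats::pnorm(z, lower.tail = FALSE) else stats::pnorm(z)
    }
  } else {
    m <- sum(agg$population * agg$outcome) / sum(agg$population)
    sigma2 <- sum(agg$population * (agg$outcome - m)^2) / nrow(agg)
    z <- (agg$outcome - m) / sqrt(sigma2 / agg$population)
    p <- if (direction == "above") stats::pnorm(z, lower.tail = FALSE) else stats::pnorm(z)
  }
  flagged <- agg$zone[p < alpha_level]
  units <- zonation$assignment
  structure(
    list(flagged_zones = flagged,
         flagged_units = sort(units$id[units$zone %in% flagged]),
         all_units = sort(units$id),
         direction = direction, alpha_level = alpha_level, test = test),
    class = "flag_set"
  )
}

#' Per-unit overlay counts across a zonation ensemble
#'
#' Counts, for each minimal unit, the number of zonations in which it lay
#' inside a flagged zone.  Units never flagged get count 0 (the "white
#' areas" of an overlay map).
#'
#' @param flagsets A list of [flag_zones()] results over the same map.
#' @return A tibble `id`, `count`, `n_zonations`.
#' @export
overlay_counts <- function(flagsets) {
  if (length(flagsets) == 0) stop("no flag sets supplied")
  all_units <- flagsets[[1]]$all_units
  for (fs in flagsets) {
    if (!identical(fs$all_units, all_units)) stop("flag sets cover different maps")
  }
  counts <- integer(length(all_units))
  names(counts) <- all_units
  for (fs in flagsets) {
    counts[fs$flagged_units] <- counts[fs$flagged_units] + 1L
  }
  tibble::tibble(id = all_units, count = unname(counts),
                 n_zonations = length(flagsets))
}

#' Repeat-appearance probability between two zonations
#'
#' The probability that a minimal unit flagged in zonation `i` is also
#' flagged in zonation `j`: the number of flagged units common to both,
#' divided by the number flagged in `i`.
#'
#' @param flags_i,flags_j [flag_zones()] results over the same map.
#' @return A probability in `[0, 1]`; `NA` (with a warning) when nothing
#'   is flagged in `i`.
#' @export
repeat_probability <- function(flags_i, flags_j) {
  if (length(flags_i$flagged_units) == 0) {
    warning("no units flagged in zonation i; probability undefined")
    return(NA_real_)
  }
  length(intersect(flags_i$flagged_units, flags_j$flagged_units)) /
    length(flags_i$flagged_units)
}

#' Average repeat-appearance probabilities across an ensemble
#'
#' For each zonation `i` with a non-empty flag set, computes the mean of
#' the pairwise repeat probabilities over all other zonations `j != i`.
#' A unit flagged in zonation `i` carries that zonation's average; the
#' 2.5% and 97.5% quantiles of the distribution of the per-zonation
#' averages summarise the uncertainty.
#'
#' @param flagsets A list of [flag_zones()] results over the same map.
#' @return A list of class `repeat_summary`: `by_zonation` (tibble `i`,
#'   `n_flagged`, `p_avg`), `by_unit` (tibble `id`, `p_avg` averaged over
#'   the zonations flagging that unit), `mean`, `q_low`, `q_high`.
#' @export
average_repeat_probability <- function(flagsets) {
  if (length(flagsets) < 2) stop("need at least two flag sets")
  sets <- lapply(flagsets, function(fs) fs$flagged_units)
  nonempty <- which(lengths(sets) > 0)
  if (length(nonempty) == 0) stop("no unit flagged in any zonation")
  p_avg <- vapply(nonempty, function(i) {
    js <- setdiff(seq_along(sets), i)
    mean(vapply(js, function(j) {
      length(intersect(sets[[i]], sets[[j]])) / length(sets[[i]])
    }, numeric(1)))
  }, numeric(1))
  by_zonation <- tibble::tibble(i = nonempty,
                                n_flagged = lengths(sets)[nonempty],
                                p_avg = p_avg)
  unit_rows <- dplyr::bind_rows(purrr::map2(nonempty, p_avg, function(i, p) {
    tibble::tibble(id = sets[[i]], p_avg = p)
  }))
  by_unit <- unit_rows |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(p_avg = mean(.data$p_avg), .groups = "drop")
  q <- stats::quantile(p_avg, c(0.025, 0.975), type = 7, names = FALSE)
  structure(list(by_zonation = by_zonation, by_unit = by_unit,
                 mean = mean(p_avg), q_low = q[1], q_high = q[2]),
            class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat("<repeat_summary> mean repeat-appearance probability ",
      format(x$mean, digits = 4), " (95% quantile range ",
      format(x$q_low, digits = 4), "-", format(x$q_high, digits = 4),
      ") over ", nrow(x$by_zonation), " zonations\n", sep = "")
  invisible(x)
}
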