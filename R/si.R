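#' Simulate a minimal-level outcome vector
#'
#' Draws one outcome per unit of the map from the declared model family at
#' the given parameter values: negative-binomial or Poisson counts with
#' mean `population * exp(alpha + beta * covariate)` (no population factor
#' for `poisson_individual`), or Gaussian values with mean
#' `alpha + beta * covariate` and per-unit standard deviation
#' `nuisance / sqrt(population)` (the nuisance being the
#' population-inflated residual standard error).
#'
#' @param map A [bb_map()].
#' @param spec A [model_spec()].
#' @param alpha,beta Intercept and slope at the minimal level.
#' @param nuisance Dispersion theta (`negbin_rate`, > 0) or residual
#'   standard error (`gaussian_weighted`, > 0); ignored for Poisson.
#' @param seed Integer seed; the draw is reproducible.
#' @return Numeric vector of outcomes in the order of `map$units`.
#' @export
simulate_minimal_dataset <- function(map, spec, alpha, beta, nuisance = NULL,
                                     seed = 1L) {
  u <- map$units
  n <- nrow(u)
  withr::with_seed(seed, {
    if (spec$family == "negbin_rate") {
      if (is.null(nuisance) || !is.finite(nuisance) || nuisance <= 0) {
        stop("negbin_rate requires dispersion theta > 0")
      }
      mu <- u$population * exp(alpha + beta * u$covariate)
      stats::rnbinom(n, mu = mu, size = nuisance)
    } else if (spec$family == "poisson_rate") {
      stats::rpois(n, u$population * exp(alpha + beta * u$covariate))
    } else if (spec$family == "poisson_individual") {
      stats::rpois(n, exp(alpha + beta * u$covariate))
    } else {
      if (is.null(nuisance) || !is.finite(nuisance) || nuisance <= 0) {
        stop("gaussian_weighted requires a residual standard error > 0")
      }
      if (any(u$population <= 0)) stop("gaussian simulation needs positive populations")
      stats::rnorm(n, mean = alpha + beta * u$covariate,
                   sd = nuisance / sqrt(u$population))
    }
  })
}

# Default y-axis transform for a parameter's scaling curve, by family.
# Rate families log-transform both axes (signed magnitude for parameters
# that may be negative, plain log for the positive dispersion); the
# weighted-Gaussian variant log-transforms only the RSE.
default_y_transform <- function(spec, parameter) {
  if (spec$family == "gaussian_weighted") {
    if (parameter == "nuisance") "log" else "identity"
  } else {
    if (parameter == "nuisance") "log" else "log_abs_signed"
  }
}

# Precomputed context shared by every inner-density evaluation: the
# restricted ensemble's aggregation maps, the curve design, and common
# random numbers (one uniform / gamma / normal deviate per unit per inner
# dataset, reused across candidate values V so the quantile functions are
# smooth and monotone in V).
make_si_context <- function(map, ensemble, spec, ei_alpha, ei_nuisance,
                            n_inner_sim, degree, y_transform, seed,
                            stopping_point = NULL) {
  if (!is.null(stopping_point)) {
    ensemble <- Filter(function(z) z$mean_polygon_population >= stopping_point,
                       ensemble)
    if (length(ensemble) == 0) stop("stopping point removes every zonation")
  }
  u <- map$units
  n <- nrow(u)
  zinfo <- lapply(ensemble, function(z) {
    grp <- z$assignment$zone[match(u$id, z$assignment$id)]
    pop <- as.vector(rowsum(u$population, grp))
    cov <- as.vector(rowsum(u$population * u$covariate, grp)) / pop
    list(group = grp, population = pop, covariate = cov,
         x = z$mean_polygon_population)
  })
  scales <- vapply(ensemble, function(z) z$scale %||% z$target_population,
                   numeric(1))
  n_scales <- length(unique(scales))
  deg <- max(1, min(degree, n_scales - 1))
  withr::with_seed(seed, {
    U <- matrix(stats::runif(n * n_inner_sim), n, n_inner_sim)
    G <- if (spec$family == "negbin_rate") {
      matrix(stats::rgamma(n * n_inner_sim, shape = ei_nuisance,
                           rate = ei_nuisance), n, n_inner_sim)
    } else if (spec$family == "gaussian_weighted") {
      matrix(stats::rnorm(n * n_inner_sim), n, n_inner_sim)
    } else NULL
  })
  list(map = map, spec = spec, zinfo = zinfo, cache = new.env(parent = emptyenv()),
       xvals = vapply(zinfo, function(z) z$x, numeric(1)),
       degree = deg, y_transform = y_transform,
       x_minimal = map$minimal_mean_population,
       ei_alpha = ei_alpha, ei_nuisance = ei_nuisance,
       n_inner_sim = n_inner_sim, U = U, G = G, seed = seed)
}

# Simulate the inner minimal-level datasets at candidate slope V using the
# context's common random numbers.  Counts are inverse-cdf coupled
# (qpois of a fixed uniform, with a fixed gamma frailty for the NB
# mixture), so each unit's outcome is non-decreasing in its mean and the
# resulting quantile curves are smooth in V.
simulate_inner <- function(ctx, V, cols = NULL) {
  u <- ctx$map$units
  U <- ctx$U; G <- ctx$G
  if (!is.null(cols)) {
    U <- U[, cols, drop = FALSE]
    if (!is.null(G)) G <- G[, cols, drop = FALSE]
  }
  fam <- ctx$spec$family
  if (fam == "negbin_rate") {
    mu <- u$population * exp(ctx$ei_alpha + V * u$covariate)
    matrix(stats::qpois(U, mu * G), nrow(U), ncol(U))
  } else if (fam == "poisson_rate") {
    mu <- u$population * exp(ctx$ei_alpha + V * u$covariate)
    matrix(stats::qpois(U, mu), nrow(U), ncol(U))
  } else if (fam == "poisson_individual") {
    mu <- exp(ctx$ei_alpha + V * u$covariate)
    matrix(stats::qpois(U, mu), nrow(U), ncol(U))
  } else {
    mean <- ctx$ei_alpha + V * u$covariate
    mean + (ctx$ei_nuisance / sqrt(u$population)) * G
  }
}

# One density of extrapolated intercepts EI_{beta i | V}.
ei_density_impl <- function(ctx, V) {
  Y <- simulate_inner(ctx, V)
  m <- ncol(Y)
  B <- matrix(NA_real_, length(ctx$zinfo), m)
  for (k in seq_along(ctx$zinfo)) {
    z <- ctx$zinfo[[k]]
    Yz <- rowsum(Y, z$group)
    key <- paste0("z", k)
    f <- fit_family_batch(Yz, z$covariate, z$population, ctx$spec,
                          start = ctx$cache[[key]])
    if (ctx$spec$family == "negbin_rate") {
      ctx$cache[[key]] <- list(alpha = f$alpha, beta = f$beta, theta = f$theta)
    }
    B[k, ] <- f$beta
  }
  ex <- extrapolate_batch(ctx$xvals, B, ctx$degree, "log", ctx$y_transform,
                          ctx$x_minimal)
  samples <- ex$ei
  # failed inner pipelines: one deterministic redraw pass, then dropped
  failed <- which(!is.finite(samples))
  for (attempt in seq_len(3)) {
    if (length(failed) == 0) break
    for (j in failed) {
      redraw_seed <- ctx$seed + 100003L * attempt + j
      withr::with_seed(redraw_seed, {
        n <- nrow(ctx$U)
        ctx$U[, j] <- stats::runif(n)
        if (!is.null(ctx$G)) {
          ctx$G[, j] <- if (ctx$spec$family == "negbin_rate") {
            stats::rgamma(n, shape = ctx$ei_nuisance, rate = ctx$ei_nuisance)
          } else stats::rnorm(n)
        }
      })
    }
    Yf <- simulate_inner(ctx, V, cols = failed)
    Bf <- matrix(NA_real_, length(ctx$zinfo), length(failed))
    for (k in seq_along(ctx$zinfo)) {
      z <- ctx$zinfo[[k]]
      Yz <- rowsum(Yf, z$group)
      f <- fit_family_batch(Yz, z$covariate, z$population, ctx$spec)
      Bf[k, ] <- f$beta
    }
    exf <- extrapolate_batch(ctx$xvals, Bf, ctx$degree, "log",
                             ctx$y_transform, ctx$x_minimal)
    samples[failed] <- exf$ei
    failed <- which(!is.finite(samples))
  }
  if (length(failed) > 0.2 * m) {
    stop("more than 20% of inner simulation pipelines failed; density unreliable")
  }
  samples[is.finite(samples)]
}

#' Density of extrapolated intercepts at a candidate true effect
#'
#' Repeatedly simulates minimal-level data with slope `V` (intercept and
#' nuisance fixed at their extrapolated intercepts), pushes each dataset
#' through the full aggregate-fit-curve-extrapolate pipeline over the
#' given ensemble, and returns the resulting density of extrapolated
#' intercepts with its tail quantiles.
#'
#' @param V Candidate minimal-level slope.
#' @param map A [bb_map()].
#' @param ensemble A zonation ensemble ([generate_ensemble()]).
#' @param spec A [model_spec()].
#' @param ei_alpha,ei_nuisance Extrapolated intercepts of the intercept
#'   and nuisance parameters, held fixed during simulation.
#' @param n_inner_sim Number of inner datasets (default 500).
#' @param coverage Nominal SI coverage; tail quantiles are
#'   `(1 - coverage)/2` and `1 - (1 - coverage)/2`.
#' @param degree Requested curve degree (falls back as in
#'   [fit_scaling_curve()]).
#' @param y_transform y-transform for the inner beta curves (default the
#'   family's convention).
#' @param stopping_point Optional minimum mean polygon population; must
#'   match the one used for the observed curves.
#' @param seed Integer seed.
#' @return A list of class `ei_density`: `candidate_value`, `samples`,
#'   `q_low_value`, `q_high_value`.
#' @export
ei_density <- function(V, map, ensemble, spec, ei_alpha, ei_nuisance = NULL,
                       n_inner_sim = 500, coverage = 0.95, degree = 2,
                       y_transform = NULL, stopping_point = NULL, seed = 1L) {
  if (n_inner_sim < 2) stop("n_inner_sim must be >= 2")
  if (is.null(y_transform)) y_transform <- default_y_transform(spec, "beta")
  ctx <- make_si_context(map, ensemble, spec, ei_alpha, ei_nuisance,
                         n_inner_sim, degree, y_transform, seed,
                         stopping_point)
  samples <- ei_density_impl(ctx, V)
  q <- stats::quantile(samples, probs = c((1 - coverage) / 2,
                                          1 - (1 - coverage) / 2),
                       type = 7, names = FALSE)
  structure(list(candidate_value = V, samples = samples,
                 q_low_value = q[1], q_high_value = q[2]),
            class = "ei_density")
}

# Root search for one SI bound.  The lower bound A solves
# q_high(A) = ei_beta; the upper bound B solves q_low(B) = ei_beta, where
# q_low / q_high are the tail quantiles of the EI density at V.  Under
# the monotonicity of these quantile curves in V (checked empirically on
# the search trajectory) bracketing plus regula falsi converges; common
# random numbers across V make the curves smooth.
find_bound <- function(which = c("lower", "upper"), ei_beta, ctx,
                       coverage = 0.95, convergence_tol_frac = 0.001,
                       max_search_iter = 40) {
  which <- match.arg(which)
  p <- if (which == "lower") 1 - (1 - coverage) / 2 else (1 - coverage) / 2
  p_other <- 1 - p
  tol <- convergence_tol_frac * abs(ei_beta)
  if (tol == 0) tol <- 1e-10
  # counts make the quantile curve a staircase whose treads can exceed the
  # quantile tolerance; the bound itself is then only determined to the
  # tread width, so the V-bracket is accepted at 10x the quantile tolerance
  width_tol <- 10 * tol
  evals <- list()
  qfun <- function(V) {
    key <- sprintf("v%.17g", V)
    s <- ctx$cache[[key]]
    if (is.null(s)) {
      s <- ei_density_impl(ctx, V)
      ctx$cache[[key]] <- s
    }
    q <- stats::quantile(s, probs = sort(c(p, p_other)), type = 7,
                         names = FALSE)
    evals[[length(evals) + 1]] <<- tibble::tibble(
      V = V, q_low = q[1], q_high = q[2], sd = stats::sd(s),
      n_samples = length(s))
    if (which == "lower") q[2] else q[1]
  }
  f <- function(V) {
    # a density can fail wholesale at absurd candidate values (e.g. all
    # counts underflow to zero); treat that as an unusable evaluation and
    # let the search stop with converged = FALSE rather than error
    q <- tryCatch(qfun(V), error = function(e) NA_real_)
    q - ei_beta
  }

  V0 <- ei_beta
  f0 <- f(V0)
  converged <- FALSE
  root <- V0
  if (abs(f0) <= tol) {
    converged <- TRUE
  } else {
    # walk towards the root: secant steps while the sign is unchanged
    # (the quantile curves are near-linear in V with slope about one, so
    # the residual f approximates the remaining distance); each step is
    # capped at a few residuals, growing only if progress stalls
    dir <- if (f0 > 0) -1 else 1
    base_step <- max(abs(f0), 10 * tol)
    Va <- V0; fa <- f0
    Vprev <- V0; fprev <- f0
    Vb <- NA_real_; fb <- NA_real_
    grow <- 1
    while (length(evals) < max_search_iter) {
      cap <- grow * 4 * max(abs(fa), 10 * tol)
      cand <- base_step
      if (is.finite(fprev) && fprev != fa && Va != Vprev) {
        Vsec <- Va - fa * (Va - Vprev) / (fa - fprev)
        if ((Vsec - Va) * dir > 0) cand <- abs(Vsec - Va)
      }
      Vtry <- Va + dir * min(cand, cap)
      ftry <- f(Vtry)
      if (is.na(ftry)) break
      if (sign(ftry) != sign(f0) || abs(ftry) <= tol) {
        Vb <- Vtry; fb <- ftry
        break
      }
      grow <- if (abs(ftry) > 0.7 * abs(fa)) grow * 2 else 1
      Vprev <- Va; fprev <- fa
      Va <- Vtry; fa <- ftry
    }
    if (!is.na(Vb) && abs(fb) <= tol) {
      root <- Vb; converged <- TRUE
    } else if (!is.na(Vb)) {
      # Illinois-type regula falsi on the bracket [Va, Vb]; counts make the
      # quantile curve a fine staircase, so the bracket width is also an
      # accepted convergence criterion at the same tolerance
      side <- 0L
      while (length(evals) < max_search_iter) {
        if (abs(Vb - Va) <= width_tol) {
          root <- (Va * abs(fb) + Vb * abs(fa)) / (abs(fa) + abs(fb))
          converged <- TRUE
          break
        }
        width_before <- abs(Vb - Va)
        Vn <- (Va * fb - Vb * fa) / (fb - fa)
        # fall back to bisection when regula falsi stalls on a tread
        if (!is.finite(Vn) || abs(Vn - Va) < 0.05 * width_before ||
            abs(Vn - Vb) < 0.05 * width_before) {
          Vn <- (Va + Vb) / 2
        }
        fn <- f(Vn)
        if (is.na(fn)) break
        root <- Vn
        if (abs(fn) <= tol) {
          converged <- TRUE
          break
        }
        if (sign(fn) == sign(fa)) {
          Va <- Vn; fa <- fn
          if (side == -1L) fb <- fb / 2
          side <- -1L
        } else {
          Vb <- Vn; fb <- fn
          if (side == 1L) fa <- fa / 2
          side <- 1L
        }
      }
      if (!converged && abs(Vb - Va) <= width_tol) {
        root <- (Va * abs(fb) + Vb * abs(fa)) / (abs(fa) + abs(fb))
        converged <- TRUE
      }
    } else {
      root <- Va
    }
  }
  diag <- dplyr::bind_rows(evals)
  diag$bound <- which
  ord <- order(diag$V)
  # tail quantiles of m samples carry a Monte Carlo standard error of
  # roughly sqrt(p(1-p)/m) / f(q) ~ 0.27 * sd for p = 0.975, m = 100;
  # decreases beyond twice that are flagged as monotonicity violations
  mc_se <- 0.27 * diag$sd[ord] * sqrt(100 / diag$n_samples[ord])
  slack <- 2 * pmax(mc_se[-1], mc_se[-length(mc_se)])
  monotone <- all(diff(diag$q_low[ord]) >= -slack) &&
    all(diff(diag$q_high[ord]) >= -slack)
  list(value = root, converged = converged, iterations = length(evals),
       diagnostics = diag, monotone = monotone)
}

#' Construct a minimal-level simulation interval
#'
#' Runs the full pipeline: fits the model at every zonation of the
#' ensemble, restricts to scales above the stopping point, fits scaling
#' curves for the slope, intercept, and nuisance parameter, extrapolates
#' them to the minimal level (the EIs), and then searches for the bounds
#' `A` and `B` whose inner-simulation EI densities have their
#' `1 - (1-coverage)/2` (at `A`) and `(1-coverage)/2` (at `B`) quantiles
#' equal to the observed EI of the slope, to within
#' `convergence_tol_frac * abs(EI_beta)`.  `(A, B)` is the simulation
#' interval: the range of minimal-level true effects that could plausibly
#' have generated the observed multiscale estimate set.  Note the SI need
#' not contain the EI itself in extreme cases; the EI is an interim
#' quantity, not an estimate.
#'
#' @param map A [bb_map()] carrying the observed outcomes.
#' @param ensemble A zonation ensemble ([generate_ensemble()]).
#' @param spec A [model_spec()].
#' @param coverage Nominal coverage (default 0.95).
#' @param n_inner_sim Inner datasets per density (default 500).
#' @param convergence_tol_frac Quantile-matching tolerance as a fraction
#'   of `abs(EI_beta)` (default 0.001).
#' @param max_search_iter Maximum density evaluations per bound.
#' @param degree Requested scaling-curve degree (default 2; falls back to
#'   a straight line when only two scales are available).
#' @param stopping_point Optional minimum mean polygon population below
#'   which estimates are discarded before curve fitting.
#' @param min_zones Minimum zones per fit ([fit_model()]).
#' @param seed Integer seed driving the inner simulations and search.
#' @return An object of class `simulation_interval`: bounds `lower` and
#'   `upper`, `ei_beta`, `ei_alpha`, `ei_nuisance`, `coverage`,
#'   `converged`, `iterations`, a `diagnostics` tibble of the search
#'   trajectory `(V, q_low, q_high, bound)`, `monotone`, the fitted
#'   `curves`, the estimate set, and rate-ratio companions for rate
#'   families.
#' @export
construct_si <- function(map, ensemble, spec, coverage = 0.95,
                         n_inner_sim = 500, convergence_tol_frac = 0.001,
                         max_search_iter = 40, degree = 2,
                         stopping_point = NULL, min_zones = 5, seed = 1L) {
  est <- estimate_across_ensemble(map, ensemble, spec, min_zones = min_zones)
  if (!is.null(stopping_point)) est <- apply_stopping_point(est, stopping_point)

  params <- c("beta", "alpha", if (spec$family %in% c("negbin_rate", "gaussian_weighted")) "nuisance")
  curves <- lapply(stats::setNames(params, params), function(p) {
    fit_scaling_curve(dplyr::filter(est, .data$parameter == p),
                      degree = degree,
                      y_transform = default_y_transform(spec, p),
                      parameter = p)
  })
  x_min <- map$minimal_mean_population
  ei <- lapply(curves, extrapolate_intercept, x_minimal = x_min)
  ei_nuis <- ei$nuisance %||% NA_real_

  ctx <- make_si_context(map, ensemble, spec, ei$alpha, ei_nuis,
                         n_inner_sim, degree,
                         curves$beta$y_transform, seed, stopping_point)
  # the inner curves must mirror the observed beta curve's fallback degree
  ctx$degree <- curves$beta$degree

  lower <- find_bound("lower", ei$beta, ctx, coverage,
                      convergence_tol_frac, max_search_iter)
  upper <- find_bound("upper", ei$beta, ctx, coverage,
                      convergence_tol_frac, max_search_iter)
  if (!lower$monotone || !upper$monotone) {
    warning("quantile curves were not monotone along the search trajectory; ",
            "consider increasing n_inner_sim")
  }
  is_rate <- spec$family %in% c("negbin_rate", "poisson_rate")
  structure(
    list(lower = lower$value, upper = upper$value,
         ei_beta = ei$beta, ei_alpha = ei$alpha, ei_nuisance = ei_nuis,
         coverage = coverage,
         converged = lower$converged && upper$converged,
         iterations = lower$iterations + upper$iterations,
         diagnostics = dplyr::bind_rows(lower$diagnostics, upper$diagnostics),
         monotone = lower$monotone && upper$monotone,
         curves = curves, estimates = est,
         rr = if (is_rate) list(lower = exp(lower$value),
                                upper = exp(upper$value),
                                ei_beta = exp(ei$beta)) else NULL,
         n_inner_sim = n_inner_sim,
         convergence_tol_frac = convergence_tol_frac,
         stopping_point = stopping_point,
         seed = seed),
    class = "simulation_interval"
  )
}

#' @export
print.simulation_interval <- function(x, ...) {
  cat("<simulation_interval> ", format(100 * x$coverage), "% SI: [",
      format(x$lower, digits = 6), ", ", format(x$upper, digits = 6),
      "]  EI_beta = ", format(x$ei_beta, digits = 6),
      if (x$converged) "  (converged" else "  (NOT converged",
      ", ", x$iterations, " density evaluations)\n", sep = "")
  if (!is.null(x$rr)) {
    cat("  rate-ratio scale: [", format(x$rr$lower, digits = 6), ", ",
        format(x$rr$upper, digits = 6), "]\n", sep = "")
  }
  invisible(x)
}

#' Empirical coverage of simulation intervals on a synthetic scenario
#'
#' Repeatedly simulates minimal-level outcomes from the scenario's true
#' parameters on a fixed geography and zonation ensemble, constructs a
#' simulation interval for each replicate, and reports the fraction of
#' intervals containing the true slope with an exact binomial confidence
#' interval.
#'
#' @param scenario A [synth_scenario()].
#' @param scales Target populations for the ensemble.
#' @param n_reps Number of replicates.
#' @param n_per_scale Zonations per scale (default 5).
#' @param n_inner_sim Inner datasets per density (default 100).
#' @param coverage Nominal SI coverage (default 0.95).
#' @param base_seed Integer seed for the ensemble and replicates.
#' @param n_runs,n_swap_cycles Zone-design effort per zonation.
#' @param stopping_point,degree Passed to [construct_si()].
#' @param conf_level Confidence level of the binomial CI (default 0.99).
#' @return A list of class `si_coverage`: `proportion`, `ci`, `n_reps`,
#'   `hits`, `true_beta`, and a `results` tibble (one row per replicate
#'   with bounds and convergence flags).
#' @export
coverage_experiment <- function(scenario, scales, n_reps, n_per_scale = 5,
                                n_inner_sim = 100, coverage = 0.95,
                                base_seed = 1L, n_runs = 10, n_swap_cycles = 5,
                                stopping_point = NULL, degree = 2,
                                conf_level = 0.99) {
  map <- generate_scenario(scenario)
  truth <- attr(map, "true_effect")
  spec <- scenario$spec
  ensemble <- generate_ensemble(map, scales, n_per_scale = n_per_scale,
                                base_seed = base_seed, n_runs = n_runs,
                                n_swap_cycles = n_swap_cycles)
  rows <- purrr::map(seq_len(n_reps), function(r) {
    rep_seed <- base_seed + 10000L + r
    m <- map
    m$units$outcome <- simulate_minimal_dataset(
      map, spec, scenario$true_alpha, scenario$true_beta,
      scenario$true_nuisance, seed = rep_seed)
    si <- tryCatch(
      construct_si(m, ensemble, spec, coverage = coverage,
                   n_inner_sim = n_inner_sim, degree = degree,
                   stopping_point = stopping_point, seed = rep_seed),
      error = function(e) NULL)
    if (is.null(si)) {
      return(tibble::tibble(rep = r, lower = NA_real_, upper = NA_real_,
                            ei_beta = NA_real_, converged = FALSE,
                            hit = NA))
    }
    tibble::tibble(rep = r, lower = si$lower, upper = si$upper,
                   ei_beta = si$ei_beta, converged = si$converged,
                   hit = si$lower < truth & truth < si$upper)
  })
  results <- dplyr::bind_rows(rows)
  ok <- !is.na(results$hit)
  hits <- sum(results$hit[ok])
  bt <- stats::binom.test(hits, sum(ok), p = coverage,
                          conf.level = conf_level)
  structure(
    list(proportion = hits / sum(ok),
         ci = as.numeric(bt$conf.int),
         conf_level = conf_level,
         n_reps = sum(ok),
         hits = hits,
         true_beta = truth,
         nominal = coverage,
         results = results),
    class = "si_coverage"
  )
}

#' @export
print.si_coverage <- function(x, ...) {
  cat("<si_coverage> ", x$hits, "/", x$n_reps, " intervals covered the true slope (",
      format(100 * x$proportion, digits = 4), "%; nominal ",
      format(100 * x$nominal), "%, ",
      format(100 * x$conf_level), "% binomial CI ",
      format(x$ci[1], digits = 4), "-", format(x$ci[2], digits = 4), ")\n",
      sep = "")
  invisible(x)
}
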