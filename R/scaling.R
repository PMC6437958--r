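#' Fit a scaling curve to an estimate set
#'
#' Fits an ordinary least-squares polynomial (quadratic by default) to the
#' parameter estimates as a function of mean polygon population, in
#' transformed coordinates.  The x-axis is log-transformed by default.
#' For sign-definite parameters the y-axis uses a signed log-magnitude
#' transform (`"log_abs_signed"`): the common sign of the estimates is
#' stored and `log(abs(y))` is fitted, so extrapolation can never cross
#' zero; positive parameters such as a dispersion can use a plain `"log"`.
#' If the estimates do not share one sign the transform falls back to
#' `"identity"` with a warning.  When fewer distinct scales are available
#' than the requested degree needs, the degree falls back to
#' `n_distinct_scales - 1` (at least 1) — with estimates at only two
#' scales a straight line is fitted.
#'
#' @param set A tibble with columns `mean_polygon_population`, `estimate`
#'   and (optionally) `scale` and `parameter`; typically one parameter's
#'   rows of [estimate_across_ensemble()] output.
#' @param degree Requested polynomial degree (default 2).
#' @param x_transform `"log"` (default) or `"identity"`.
#' @param y_transform `"log_abs_signed"`, `"log"`, or `"identity"`.
#' @param parameter Optional label; taken from the `parameter` column when
#'   unique.
#' @return An object of class `scaling_curve`: coefficients in transformed
#'   space (ascending powers), the transforms, the stored sign, the
#'   fitted degree, and bookkeeping fields.
#' @export
fit_scaling_curve <- function(set, degree = 2,
                              x_transform = c("log", "identity"),
                              y_transform = c("log_abs_signed", "log", "identity"),
                              parameter = NULL) {
  x_transform <- match.arg(x_transform)
  y_transform <- match.arg(y_transform)
  set <- set[!is.na(set$estimate), ]
  x <- set$mean_polygon_population
  y <- set$estimate
  if (any(x <= 0)) stop("mean polygon populations must be positive")
  scales <- if ("scale" %in% names(set)) set[["scale"]] else x
  n_scales <- length(unique(scales))
  if (n_scales < 2) stop("need estimates at >= 2 distinct scales to fit a curve")
  if (is.null(parameter)) {
    parameter <- if ("parameter" %in% names(set) &&
                     length(unique(set[["parameter"]])) == 1) {
      unique(set[["parameter"]])
    } else "estimate"
  }

  deg <- min(degree, n_scales - 1)
  if (deg < degree) {
    message("degree fallback: only ", n_scales,
            " distinct scales; fitting degree ", deg)
  }
  sign_common <- 1
  if (y_transform == "log_abs_signed") {
    s <- unique(sign(y[y != 0]))
    if (length(s) != 1 || any(y == 0)) {
      warning("estimates are not sign-definite; falling back to identity y-transform")
      y_transform <- "identity"
    } else {
      sign_common <- s
    }
  }
  if (y_transform == "log" && any(y <= 0)) {
    stop("log y-transform requires strictly positive estimates")
  }
  tx <- if (x_transform == "log") log(x) else x
  ty <- switch(y_transform,
               log_abs_signed = log(abs(y)),
               log = log(y),
               identity = y)
  X <- stats::poly(tx, degree = deg, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), ty)
  structure(
    list(parameter = parameter,
         degree = deg,
         requested_degree = degree,
         coefficients = unname(fit$coefficients),
         x_transform = x_transform,
         y_transform = y_transform,
         sign = sign_common,
         n_points = length(y),
         n_scales = n_scales,
         residual_ss = sum(fit$residuals^2)),
    class = "scaling_curve"
  )
}

#' @export
print.scaling_curve <- function(x, ...) {
  cat("<scaling_curve> ", x$parameter, ": degree ", x$degree,
      ", ", x$n_points, " points over ", x$n_scales, " scales (",
      x$x_transform, " x, ", x$y_transform, " y)\n", sep = "")
  invisible(x)
}

#' Extrapolate a scaling curve to the minimal level
#'
#' Evaluates the fitted polynomial at the (transformed) minimal mean
#' polygon population and back-transforms, restoring the stored sign for
#' the signed log-magnitude transform.  The result is the extrapolated
#' intercept (EI) for the curve's parameter — an interim quantity used in
#' constructing a simulation interval, not itself an estimate of the
#' minimal-level parameter.
#'
#' @param curve A [fit_scaling_curve()] result.
#' @param x_minimal The minimal-level mean polygon population (e.g. the
#'   map's `minimal_mean_population`; 1 for individual-level units).
#' @return The EI on the natural parameter scale (a single number).
#' @export
extrapolate_intercept <- function(curve, x_minimal) {
  if (x_minimal <= 0) stop("x_minimal must be positive")
  tx <- if (curve$x_transform == "log") log(x_minimal) else x_minimal
  v <- sum(curve$coefficients * tx^(0:curve$degree))
  switch(curve$y_transform,
         log_abs_signed = curve$sign * exp(v),
         log = exp(v),
         identity = v)
}

#' Convert a link-scale value to its natural scale
#'
#' `exp()` of a log rate-ratio gives the rate ratio; `exp()` of a
#' log-dispersion gives the dispersion.
#'
#' @param value Numeric value(s) on the log scale.
#' @param kind `"log_rr_to_rr"` or `"log_theta_to_theta"` (both are
#'   `exp`; the argument documents intent).
#' @return `exp(value)`.
#' @examples
#' natural_scale(-0.0144)  # rate ratio 0.9857
#' @export
natural_scale <- function(value, kind = c("log_rr_to_rr", "log_theta_to_theta")) {
  match.arg(kind)
  exp(value)
}

# Batched curve fit + extrapolation used in the inner simulation loop:
# one fixed design (transformed x, degree) and many estimate columns.
# Mirrors fit_scaling_curve()'s conventions, including the per-column
# fallback to an identity y-transform when a column is not sign-definite.
# Returns list(ei = numeric(m), fallback = logical(m)).
extrapolate_batch <- function(x, Y, degree, x_transform, y_transform, x_minimal) {
  tx <- if (x_transform == "log") log(x) else x
  tx0 <- if (x_transform == "log") log(x_minimal) else x_minimal
  X <- cbind(1, stats::poly(tx, degree = degree, raw = TRUE))
  xrow <- tx0^(0:degree)
  # hat vector: ei_transformed = xrow %*% (X'X)^-1 X' ty
  h <- drop(xrow %*% solve(crossprod(X), t(X)))
  m <- ncol(Y)
  ei <- rep(NA_real_, m)
  fallback <- rep(FALSE, m)
  ok <- colSums(!is.finite(Y)) == 0
  if (y_transform == "identity") {
    ei[ok] <- drop(h %*% Y[, ok, drop = FALSE])
  } else if (y_transform == "log") {
    pos <- ok & colSums(Y <= 0) == 0
    ei[pos] <- exp(drop(h %*% log(Y[, pos, drop = FALSE])))
    fallback[ok & !pos] <- TRUE
    if (any(fallback)) {
      ei[fallback] <- drop(h %*% Y[, fallback, drop = FALSE])
    }
  } else { # log_abs_signed
    sgn <- sign(Y[1, ])
    definite <- ok & vapply(seq_len(m), function(j) {
      all(sign(Y[, j]) == sgn[j]) && all(Y[, j] != 0)
    }, logical(1))
    if (any(definite)) {
      ei[definite] <- sgn[definite] *
        exp(drop(h %*% log(abs(Y[, definite, drop = FALSE]))))
    }
    fallback[ok & !definite] <- TRUE
    if (any(fallback)) {
      ei[fallback] <- drop(h %*% Y[, fallback, drop = FALSE])
    }
  }
  list(ei = ei, fallback = fallback)
}
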