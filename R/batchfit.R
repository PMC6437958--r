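# Batch maximum-likelihood fitters for the inner simulation loop.
#
# The simulation-interval search refits the same two-parameter model
# (intercept + one covariate, optional log-population offset) to hundreds
# of simulated outcome vectors sharing one design.  These fitters solve
# the per-dataset 2x2 IRLS normal equations in closed form across all
# datasets at once, so a whole batch costs a handful of matrix
# operations.  They are cross-checked against MASS::glm.nb / stats::glm /
# stats::lm in the test suite.

# Poisson IRLS for Y (n x m), covariate x (n), offset logoff (n).
# Returns list(alpha, beta) of length-m vectors (NA where diverged).
fit_poisson_batch <- function(Y, x, logoff = NULL, maxit = 30, tol = 1e-10) {
  n <- nrow(Y); m <- ncol(Y)
  if (is.null(logoff)) logoff <- numeric(n)
  mu <- Y + 0.5
  eta <- log(mu)
  A <- rep(0, m); B <- rep(0, m)
  for (it in seq_len(maxit)) {
    mu <- exp(eta)
    W <- mu
    Z <- (eta - logoff) + (Y - mu) / mu
    S11 <- colSums(W); S12 <- colSums(W * x); S22 <- colSums(W * x^2)
    T1 <- colSums(W * Z); T2 <- colSums(W * x * Z)
    det <- S11 * S22 - S12^2
    A_new <- (S22 * T1 - S12 * T2) / det
    B_new <- (S11 * T2 - S12 * T1) / det
    delta <- max(abs(c(A_new - A, B_new - B)), na.rm = TRUE)
    A <- A_new; B <- B_new
    eta <- outer(x, B) + matrix(A, n, m, byrow = TRUE) + logoff
    if (!is.finite(delta) || delta < tol) break
  }
  bad <- !is.finite(A) | !is.finite(B)
  A[bad] <- NA_real_; B[bad] <- NA_real_
  list(alpha = A, beta = B)
}

# NB2 (variance mu + mu^2/theta) ML with theta profiled, batched.
# Alternates weighted IRLS for (alpha, beta) given theta with Newton steps
# for log(theta) given mu, as in the usual alternating NB fit.  Columns
# are retired from the working set as they converge, so late iterations
# only touch the stragglers.
fit_nb_batch <- function(Y, x, logoff = NULL, outer_iter = 15, tol = 1e-7,
                         theta_min = 1e-3, theta_max = 1e5, start = NULL) {
  n <- nrow(Y); m <- ncol(Y)
  if (is.null(logoff)) logoff <- numeric(n)
  if (is.null(start)) {
    init <- fit_poisson_batch(Y, x, logoff)
    A <- init$alpha; B <- init$beta
    A[!is.finite(A)] <- 0; B[!is.finite(B)] <- 0
    eta <- outer(x, B) + rep(A, each = n) + logoff
    mu <- exp(eta)
    # moment start for theta: sum(mu^2) / sum((y-mu)^2 - mu)
    denom <- colSums((Y - mu)^2 - mu)
    theta <- colSums(mu^2) / pmax(denom, 1e-8)
    theta <- pmin(pmax(theta, theta_min), theta_max)
  } else {
    # warm start from a previous fit on a nearby problem
    A <- start$alpha; B <- start$beta; theta <- start$theta
    bad <- !is.finite(A) | !is.finite(B) | !is.finite(theta)
    if (any(bad)) {
      A[bad] <- stats::median(A[!bad], na.rm = TRUE)
      B[bad] <- stats::median(B[!bad], na.rm = TRUE)
      theta[bad] <- stats::median(theta[!bad], na.rm = TRUE)
      if (!all(is.finite(c(A, B, theta)))) {
        A[!is.finite(A)] <- 0; B[!is.finite(B)] <- 0
        theta[!is.finite(theta)] <- 1
      }
    }
    theta <- pmin(pmax(theta, theta_min), theta_max)
  }

  active <- seq_len(m)
  for (it in seq_len(outer_iter)) {
    Ya <- Y[, active, drop = FALSE]
    Aa <- A[active]; Ba <- B[active]; tha <- theta[active]
    na <- length(active)
    A0 <- Aa; B0 <- Ba; th0 <- tha
    eta <- outer(x, Ba) + rep(Aa, each = n) + logoff
    # IRLS for (alpha, beta) given theta
    for (inner in 1:10) {
      Ap <- Aa; Bp <- Ba
      mu <- exp(eta)
      W <- mu / (1 + mu * rep(1 / tha, each = n))
      Z <- (eta - logoff) + (Ya - mu) / mu
      S11 <- colSums(W); S12 <- colSums(W * x); S22 <- colSums(W * x^2)
      T1 <- colSums(W * Z); T2 <- colSums(W * x * Z)
      det <- S11 * S22 - S12^2
      Aa <- (S22 * T1 - S12 * T2) / det
      Ba <- (S11 * T2 - S12 * T1) / det
      Aa[!is.finite(Aa)] <- NA_real_; Ba[!is.finite(Ba)] <- NA_real_
      eta <- outer(x, Ba) + rep(Aa, each = n) + logoff
      if (max(abs(c(Aa - Ap, Ba - Bp)), na.rm = TRUE) < tol) break
    }
    mu <- exp(eta)
    # Newton for log(theta) given mu
    for (step in 1:2) {
      TH <- rep(tha, each = n)
      dim(TH) <- c(n, na)
      score <- colSums(digamma(Ya + TH) - digamma(TH) + log(TH) + 1 -
                         log(TH + mu) - (Ya + TH) / (TH + mu))
      dscore <- colSums(trigamma(Ya + TH) - trigamma(TH) + 1 / TH -
                          2 / (TH + mu) + (Ya + TH) / (TH + mu)^2)
      g <- tha * score                     # d loglik / d log(theta)
      h <- tha^2 * dscore + tha * score    # second derivative in log(theta)
      stp <- ifelse(is.finite(g) & is.finite(h) & h < 0, -g / h, 0)
      stp <- pmin(pmax(stp, -2), 2)
      tha <- exp(pmin(pmax(log(tha) + stp, log(theta_min)), log(theta_max)))
      if (max(abs(stp), na.rm = TRUE) < tol) break
    }
    A[active] <- Aa; B[active] <- Ba; theta[active] <- tha
    ch <- abs(Aa - A0)
    ch <- pmax(ch, abs(Ba - B0), abs(log(tha) - log(th0)))
    ch[!is.finite(ch)] <- 0  # diverged columns are reported NA below
    active <- active[ch >= tol]
    if (length(active) == 0) break
  }
  bad <- !is.finite(A) | !is.finite(B) | !is.finite(theta)
  A[bad] <- NA_real_; B[bad] <- NA_real_; theta[bad] <- NA_real_
  list(alpha = A, beta = B, theta = theta)
}

# Weighted least squares, batched; weights w (n), shared design.
fit_gaussian_batch <- function(Y, x, w) {
  n <- nrow(Y)
  S11 <- sum(w); S12 <- sum(w * x); S22 <- sum(w * x^2)
  det <- S11 * S22 - S12^2
  T1 <- colSums(w * Y); T2 <- colSums(w * x * Y)
  A <- (S22 * T1 - S12 * T2) / det
  B <- (S11 * T2 - S12 * T1) / det
  fitted <- outer(x, B) + matrix(A, n, ncol(Y), byrow = TRUE)
  rse <- sqrt(colSums(w * (Y - fitted)^2) / (n - 2))
  list(alpha = A, beta = B, rse = rse)
}

# Dispatch helper used by the inner SI pipeline: fits one family to a
# batch and returns parameter vectors named like the estimate sets.
fit_family_batch <- function(Y, x, population, spec, start = NULL) {
  if (spec$family == "negbin_rate") {
    f <- fit_nb_batch(Y, x, log(population), start = start)
    list(beta = f$beta, alpha = f$alpha, nuisance = f$theta, theta = f$theta)
  } else if (spec$family == "poisson_rate") {
    f <- fit_poisson_batch(Y, x, log(population))
    list(beta = f$beta, alpha = f$alpha, nuisance = rep(NA_real_, ncol(Y)))
  } else if (spec$family == "poisson_individual") {
    f <- fit_poisson_batch(Y, x, NULL)
    list(beta = f$beta, alpha = f$alpha, nuisance = rep(NA_real_, ncol(Y)))
  } else {
    f <- fit_gaussian_batch(Y, x, population)
    list(beta = f$beta, alpha = f$alpha, nuisance = f$rse)
  }
}
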