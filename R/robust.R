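# Tukey bisquare family, rho normalised so that rho(Inf) = 1.

bisquare_rho <- function(u, c) {
  a2 <- (u / c)^2
  a2[a2 > 1] <- 1
  1 - (1 - a2)^3
}

bisquare_weight <- function(u, c) {
  a2 <- (u / c)^2
  w <- (1 - a2)^2
  w[a2 >= 1] <- 0
  w
}

bisquare_psi <- function(u, c) u * bisquare_weight(u, c)

bisquare_psi_prime <- function(u, c) {
  a2 <- (u / c)^2
  w <- (1 - a2) * (1 - 5 * a2)
  w[a2 >= 1] <- 0
  w
}

# M-estimate of scale: solve mean(rho(r/s)) = b, Newton steps with a
# fixed-point fallback. With b = 0.5 and c = 1.548 this is the 50%-breakdown
# scale of the bisquare family. `s0` warm-starts the iteration.
m_scale <- function(r, c, b = 0.5, tol = 1e-8, max_iter = 50, s0 = NULL) {
  s <- if (!is.null(s0) && s0 > 0) s0 else median(abs(r)) / 0.6744898
  if (s <= 0) {
    # more than half the residuals are exactly zero -> the M-scale is zero
    if (mean(r != 0) <= b) return(0)
    s <- mean(abs(r)) / 0.6744898
    if (s <= 0) return(0)
  }
  n <- length(r)
  for (i in seq_len(max_iter)) {
    t <- (r / (s * c))^2
    t[t > 1] <- 1
    one_t <- 1 - t
    m <- sum(1 - one_t^3) / n
    if (m <= 0) return(0)
    # d mean(rho)/ds = -(6/(n s)) * sum(t (1-t)^2)
    fp <- -6 * sum(t * one_t^2) / (n * s)
    s_new <- if (fp < 0) s - (m - b) / fp else NA_real_
    if (!is.finite(s_new) || s_new <= 0) s_new <- s * sqrt(m / b)
    if (abs(s_new - s) <= tol * s) return(s_new)
    s <- s_new
  }
  s
}

#' Control parameters for MM-type robust regression
#'
#' @param c_m Bisquare tuning constant of the efficient M-step; the default
#'   4.685 gives 95 percent asymptotic efficiency at the Gaussian model.
#' @param c_s Bisquare tuning constant of the initial S-estimate; the default
#'   1.548 gives a 50 percent breakdown point.
#' @param max_iter Maximum IRLS iterations of the M-step.
#' @param tol Relative coefficient-change convergence tolerance.
#' @param nsamp Number of random elemental subsets tried for the initial
#'   S-estimate (an ordinary least-squares candidate is always included).
#' @param subset_seed Seed of the private stream that draws the elemental
#'   subsets; fits are fully deterministic and do not touch the global RNG.
#' @param s_steps Maximum refinement (IRLS) steps of the S-stage.
#' @return A list of class `mm_control`.
#' @export
mm_control <- function(c_m = 4.685, c_s = 1.548, max_iter = 50, tol = 1e-8,
                       nsamp = 20, subset_seed = 77003, s_steps = 30) {
  stopifnot(c_m > c_s, c_s > 0, max_iter >= 1, tol > 0, nsamp >= 1)
  structure(list(c_m = c_m, c_s = c_s, max_iter = max_iter, tol = tol,
                 nsamp = nsamp, subset_seed = subset_seed, s_steps = s_steps),
            class = "mm_control")
}

# Draw elemental subsets and cache their solvers. X is shared across an entire
# EWAS, so this is computed once and reused for every probe.
mm_prepare <- function(X, control = mm_control()) {
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) abort("need more observations than regressors")
  qx <- qr(X)
  if (qx$rank < p) abort("design matrix is rank deficient")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(control$subset_seed)
  solvers <- list()
  tries <- 0
  while (length(solvers) < control$nsamp && tries < 20 * control$nsamp) {
    tries <- tries + 1
    idx <- sample.int(n, p)
    Xi <- X[idx, , drop = FALSE]
    inv <- tryCatch(solve(Xi), error = function(e) NULL)
    if (!is.null(inv)) solvers[[length(solvers) + 1]] <- list(idx = idx, inv = inv)
  }
  list(X = X, qx = qx, solvers = solvers, n = n, p = p,
       xtx_inv = chol2inv(qr.R(qx)))
}

# Weighted least squares via the normal equations (p is small and the
# crossproduct well-conditioned after the candidate screen).
wls_solve <- function(X, y, w) {
  A <- crossprod(X * w, X)
  b <- crossprod(X * w, y)
  out <- tryCatch(solve(A, b), error = function(e) NULL)
  if (!is.null(out)) drop(out) else NULL
}

mm_fit_prepared <- function(y, prep, control = mm_control()) {
  X <- prep$X
  n <- prep$n
  p <- prep$p
  coef_names <- colnames(X)
  if (is.null(coef_names)) coef_names <- paste0("x", seq_len(p))

  # Candidate coefficients: OLS plus elemental subsets. All candidate
  # residuals come from one matrix product; the exact bisquare M-scale is
  # only solved for the few most promising candidates (smallest median
  # absolute residual).
  beta_ols <- qr.coef(prep$qx, y)
  B <- matrix(beta_ols, p, 1)
  for (cand in prep$solvers) B <- cbind(B, drop(cand$inv %*% y[cand$idx]))
  B <- B[, colSums(!is.finite(B)) == 0, drop = FALSE]
  R <- y - X %*% B
  madn <- apply(abs(R), 2, median)
  top <- order(madn)[seq_len(min(3L, ncol(B)))]
  best_j <- top[1]
  best_s <- Inf
  for (j in top) {
    s <- m_scale(R[, j], control$c_s, tol = 1e-4, max_iter = 30)
    if (s < best_s) {
      best_s <- s
      best_j <- j
    }
  }
  best_beta <- B[, best_j]
  best_r <- R[, best_j]
  if (best_s > 0) best_s <- m_scale(best_r, control$c_s)

  scale_floor <- 1e-10 * max(1, mean(abs(y)))
  if (best_s <= scale_floor) {
    # the M-scale is (near) zero: more than half the points lie exactly on a
    # hyperplane. Refit least squares on that consensus set and report zero
    # scale with undefined p-values.
    tol_in <- max(scale_floor, 1e-8 * mad(y))
    inlier <- abs(best_r) <= tol_in
    beta <- best_beta
    if (sum(inlier) >= p) {
      cand <- wls_solve(X, y, as.numeric(inlier))
      if (!is.null(cand)) beta <- cand
    }
    fitted <- drop(X %*% beta)
    return(structure(list(
      coefficients = setNames(drop(beta), coef_names),
      std_error = setNames(rep(0, p), coef_names),
      p_value = setNames(rep(NA_real_, p), coef_names),
      sigma = 0, iterations = 0L, converged = TRUE,
      fitted = fitted, residuals = y - fitted,
      weights = as.numeric(abs(y - fitted) <= tol_in), n = n, p = p),
      class = "mm_fit"))
  }

  # S-stage refinement: IRLS steps at c_s, re-solving the M-scale each step.
  beta <- best_beta
  s <- best_s
  r <- best_r
  for (i in seq_len(control$s_steps)) {
    w <- bisquare_weight(r / s, control$c_s)
    if (sum(w > 0) < p) break
    beta_new <- wls_solve(X, y, w)
    if (is.null(beta_new)) break
    r_new <- y - drop(X %*% beta_new)
    s_new <- m_scale(r_new, control$c_s, tol = 1e-5, max_iter = 30, s0 = s)
    step <- max(abs(beta_new - beta)) / max(max(abs(beta)), 1e-10)
    if (s_new <= s) {
      beta <- beta_new
      r <- r_new
      s <- s_new
    }
    if (step < 1e-6) break
  }
  sigma <- m_scale(r, control$c_s, tol = 1e-9, max_iter = 200, s0 = s)
  if (sigma <= scale_floor) {
    fitted <- drop(X %*% beta)
    return(structure(list(
      coefficients = setNames(drop(beta), coef_names),
      std_error = setNames(rep(0, p), coef_names),
      p_value = setNames(rep(NA_real_, p), coef_names),
      sigma = 0, iterations = 0L, converged = TRUE,
      fitted = fitted, residuals = y - fitted,
      weights = rep(1, n), n = n, p = p), class = "mm_fit"))
  }

  # Efficient M-step: IRLS with the wide bisquare at fixed scale sigma.
  iterations <- 0L
  converged <- FALSE
  for (i in seq_len(control$max_iter)) {
    iterations <- i
    w <- bisquare_weight(r / sigma, control$c_m)
    if (sum(w > 0) < p) break
    beta_new <- wls_solve(X, y, w)
    if (is.null(beta_new)) break
    step <- max(abs(beta_new - beta)) / max(max(abs(beta)), 1e-10)
    beta <- beta_new
    r <- y - drop(X %*% beta)
    if (step < control$tol) {
      converged <- TRUE
      break
    }
  }

  # Asymptotic covariance: sigma^2 * [mean psi^2 / (mean psi')^2] * (X'X)^-1,
  # with the n/(n-p) degrees-of-freedom correction and Huber's small-sample
  # factor 1 + (p/n) var(psi')/mean(psi')^2. Two-sided p-values use the t
  # distribution on n - p degrees of freedom (the robust-regression
  # convention; the normal limit is anticonservative at moderate n).
  u <- r / sigma
  psi <- bisquare_psi(u, control$c_m)
  psip <- bisquare_psi_prime(u, control$c_m)
  mp <- mean(psip)
  kappa <- if (mp > 0) {
    (n / (n - p)) * mean(psi^2) / mp^2 *
      (1 + (p / n) * stats::var(psip) / mp^2)
  } else {
    NA_real_
  }
  se <- sqrt(pmax(sigma^2 * kappa, 0) * diag(prep$xtx_inv))
  z <- drop(beta) / se
  pv <- 2 * stats::pt(-abs(z), df = n - p)

  fitted <- drop(X %*% beta)
  structure(list(
    coefficients = setNames(drop(beta), coef_names),
    std_error = setNames(se, coef_names),
    p_value = setNames(pv, coef_names),
    sigma = sigma, iterations = iterations, converged = converged,
    fitted = fitted, residuals = y - fitted,
    weights = bisquare_weight((y - fitted) / sigma, control$c_m),
    n = n, p = p), class = "mm_fit")
}

#' MM-type robust linear regression
#'
#' Fits a linear model by the MM procedure: a high-breakdown S-estimate of
#' coefficients and residual scale using the Tukey bisquare loss at `c_s`
#' (random elemental subsets plus IRLS refinement), followed by an efficient
#' M-step -- iteratively reweighted least squares with the bisquare psi at
#' `c_m`, holding the S-scale fixed -- until the relative coefficient change
#' drops below `tol`. Standard errors use the usual asymptotic MM covariance
#' with Huber's small-sample correction; two-sided p-values are referred to
#' the t distribution on n - p degrees of freedom.
#'
#' The fit is deterministic: elemental subsets are drawn from a private stream
#' seeded by `control$subset_seed` and the global RNG state is untouched.
#'
#' @param y Numeric response vector.
#' @param X Numeric design matrix (include the intercept column yourself, or
#'   use the formula-free helpers that build it); must have full column rank
#'   and fewer columns than rows.
#' @param control A [mm_control()] list.
#' @return An object of class `mm_fit` with elements `coefficients`,
#'   `std_error`, `p_value`, robust scale `sigma`, `iterations`, `converged`,
#'   `fitted`, `residuals` and the final IRLS `weights`. A perfect linear fit
#'   is returned with `sigma = 0` and undefined p-values.
#' @examples
#' x <- seq_len(30)
#' y <- 2 + 3 * x + c(rnorm(29, sd = 0.1), 50)  # one gross outlier
#' fit <- fit_mm_regression(y, cbind(1, x))
#' coef(fit)
#' @export
fit_mm_regression <- function(y, X, control = mm_control()) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (length(y) != nrow(X)) abort("length(y) must equal nrow(X)")
  if (anyNA(y) || anyNA(X)) abort("missing values in y or X; impute or drop first")
  prep <- mm_prepare(X, control)
  mm_fit_prepared(y, prep, control)
}

#' @export
coef.mm_fit <- function(object, ...) object$coefficients

#' @export
print.mm_fit <- function(x, ...) {
  cat("MM-type robust regression (bisquare)\n")
  cat(sprintf("  n = %d, p = %d, robust scale = %.4g, converged = %s (%d iter)\n",
              x$n, x$p, x$sigma, x$converged, x$iterations))
  print(round(rbind(estimate = x$coefficients, std_error = x$std_error), 5))
  invisible(x)
}

#' Tidy an MM regression fit
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$std_error),
         statistic = unname(x$coefficients / x$std_error),
         p.value = unname(x$p_value))
}

#' One-row summary of an MM regression fit
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @return A tibble with `sigma`, `iterations`, `converged`, `nobs`.
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(sigma = x$sigma, iterations = x$iterations,
         converged = x$converged, nobs = x$n)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
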