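#' Axial Cauchy stress of an incompressible uniaxial specimen
#'
#' Converts a measured axial force into Cauchy (true) stress under the
#' incompressible uniaxial convention: the current cross-section is the
#' reference area divided by the stretch, so \eqn{T_{11} = f \lambda / A_0}.
#' With force in N and area in mm^2 the result is in MPa (N/mm^2 = MPa).
#'
#' @param force axial force (N), non-negative.
#' @param A0 reference cross-sectional area (mm^2), positive.
#' @param lam stretch ratio (deformed length / reference length), >= 1.
#' @return Cauchy stress in MPa (vectorized over `force` and `lam`).
#' @examples
#' cauchy_stress(0.1, circle_area(1.42), 1.1)
#' @export
cauchy_stress <- function(force, A0, lam) {
  if (!is.numeric(A0) || any(A0 <= 0)) stop("A0 must be positive")
  if (any(lam < 1)) stop("stretch ratio must be >= 1")
  if (any(force < 0)) stop("force must be non-negative")
  force * lam / A0
}

#' Cross-sectional area of a circular section
#'
#' @param d0 diameter (mm).
#' @return area in mm^2, \eqn{\pi (d_0/2)^2}.
#' @export
circle_area <- function(d0) pi * (d0 / 2)^2

#' Uniaxial Cauchy stress of the two-parameter polynomial hyperelastic model
#'
#' The two-parameter polynomial strain-energy function of Raghavan and Vorp,
#' \eqn{W = \alpha (I_1 - 3) + \beta (I_1 - 3)^2}, gives for an incompressible
#' isotropic specimen in uniaxial tension (where \eqn{I_1 - 3 =
#' \lambda^2 + 2/\lambda - 3})
#' \deqn{T_{11} = [2\alpha + 4\beta(\lambda^2 + 2\lambda^{-1} - 3)]
#'       (\lambda^2 - \lambda^{-1}).}
#' The stress vanishes at the reference state \eqn{\lambda = 1} for any
#' parameters, and is strictly increasing on \eqn{\lambda \ge 1} whenever
#' \eqn{\alpha > 0, \beta \ge 0}.
#'
#' @param alpha first material parameter (MPa), >= 0 for a convex response.
#' @param beta second material parameter (MPa), >= 0.
#' @param lam stretch ratio, > 0; vectorized.
#' @return Cauchy stress in MPa.
#' @examples
#' model_stress(0.183, 1.88, 1.1)   # cohort-average rat sciatic response
#' @export
model_stress <- function(alpha, beta, lam) {
  if (any(lam <= 0)) stop("stretch ratio must be positive")
  i1m3 <- lam^2 + 2 / lam - 3
  (2 * alpha + 4 * beta * i1m3) * (lam^2 - 1 / lam)
}

# regressor pair of the model, which is linear in (alpha, beta):
# T = alpha * [2 g(lam)] + beta * [4 (I1-3) g(lam)],  g = lam^2 - 1/lam
.stress_basis <- function(lam) {
  g <- lam^2 - 1 / lam
  cbind(a = 2 * g, b = 4 * (lam^2 + 2 / lam - 3) * g)
}

#' Fit the two-parameter hyperelastic model to stress-stretch data
#'
#' Least-squares fit of [model_stress()] to per-increment Cauchy stress,
#' subject to the physical bounds \eqn{\alpha, \beta \ge 0}. The model is
#' linear in its parameters, so the bounded solution is found exactly: the
#' unconstrained least-squares solution is taken when it is feasible,
#' otherwise the best of the boundary solutions (one parameter pinned at
#' zero) is the global optimum of this 2-parameter problem.
#'
#' Input is either a data frame with columns `lam` and `stress` (MPa), or
#' `lam` and `force` (N) together with a reference area `A0` (mm^2), in which
#' case stress is computed with [cauchy_stress()] first.
#'
#' @param trials data frame of stretch trials; columns `lam` plus `stress`
#'   or `force`. At least 3 distinct stretch levels including lam = 1.
#' @param A0 reference cross-sectional area (mm^2); required when stress has
#'   to be derived from force.
#' @param weights optional per-point weights for weighted least squares
#'   (default unweighted).
#' @return an object of class `constitutive_fit` with components `alpha`,
#'   `beta` (MPa), `r2`, `residuals`, `fitted`, `data`, `converged`.
#' @examples
#' lam <- seq(1, 1.2, by = 0.025)
#' d <- data.frame(lam = lam, stress = model_stress(0.305, 3.40, lam))
#' fit <- fit_constitutive(d)
#' coef(fit)
#' @export
fit_constitutive <- function(trials, A0 = NULL, weights = NULL) {
  if (is.list(trials) && !is.data.frame(trials)) trials <- as.data.frame(trials)
  if (!"lam" %in% names(trials)) stop("trials must have a 'lam' column")
  lam <- trials$lam
  if (!"stress" %in% names(trials)) {
    if (!"force" %in% names(trials) || is.null(A0))
      stop("need a 'stress' column, or a 'force' column plus A0")
    trials$stress <- cauchy_stress(trials$force, A0, lam)
  }
  y <- trials$stress
  if (length(unique(lam)) < 3) stop("need at least 3 distinct stretch levels")
  if (any(lam < 1)) stop("stretch ratios must be >= 1")
  X <- .stress_basis(lam)
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  sw <- sqrt(w)

  ls2 <- function(Xs) {
    cf <- stats::lm.fit(Xs * sw, y * sw)$coefficients
    cf[is.na(cf)] <- 0
    cf
  }
  cand <- list()
  full <- ls2(X)
  if (all(full >= 0)) {
    cand[[1]] <- full
  } else {
    # KKT: active-set enumeration over the two bound constraints
    ca <- c(ls2(X[, 1, drop = FALSE]), 0)  # beta = 0
    cb <- c(0, ls2(X[, 2, drop = FALSE]))  # alpha = 0
    cand <- Filter(function(p) all(p >= 0), list(ca, cb, c(0, 0)))
  }
  sse <- vapply(cand, function(p) sum(w * (y - X %*% p)^2), numeric(1))
  par <- cand[[which.min(sse)]]
  fitted <- drop(X %*% par)
  res <- y - fitted
  sstot <- sum(w * (y - stats::weighted.mean(y, w))^2)
  r2 <- if (sstot > 0) 1 - min(sse) / sstot else 1
  structure(list(alpha = unname(par[1]), beta = unname(par[2]), r2 = r2,
                 residuals = res, fitted = fitted,
                 data = data.frame(lam = lam, stress = y),
                 weights = w, converged = TRUE),
            class = "constitutive_fit")
}

#' @export
print.constitutive_fit <- function(x, ...) {
  cat("Two-parameter hyperelastic fit (uniaxial Cauchy stress)\n")
  cat(sprintf("  alpha = %.4g MPa, beta = %.4g MPa, R^2 = %.4f  (n = %d)\n",
              x$alpha, x$beta, x$r2, nrow(x$data)))
  invisible(x)
}

#' @export
coef.constitutive_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
residuals.constitutive_fit <- function(object, ...) object$residuals

#' Predicted Cauchy stress from a constitutive fit
#'
#' @param object a `constitutive_fit`.
#' @param lam stretch ratios at which to evaluate (default: fitted data).
#' @param ... unused.
#' @return Cauchy stress in MPa.
#' @export
predict.constitutive_fit <- function(object, lam = NULL, ...) {
  if (is.null(lam)) return(object$fitted)
  model_stress(object$alpha, object$beta, lam)
}

#' @export
summary.constitutive_fit <- function(object, ...) {
  out <- list(coefficients = coef(object), r2 = object$r2,
              n = nrow(object$data),
              lam_range = range(object$data$lam),
              rmse = sqrt(mean(object$residuals^2)))
  class(out) <- "summary.constitutive_fit"
  out
}

#' @export
print.summary.constitutive_fit <- function(x, ...) {
  cat("Two-parameter hyperelastic fit\n")
  cat(sprintf("  alpha = %.4g MPa\n  beta  = %.4g MPa\n", x$coefficients[1],
              x$coefficients[2]))
  cat(sprintf("  R^2 = %.4f, RMSE = %.3g MPa, n = %d, lambda in [%.3f, %.3f]\n",
              x$r2, x$rmse, x$n, x$lam_range[1], x$lam_range[2]))
  invisible(x)
}

#' @export
plot.constitutive_fit <- function(x, lam_max = NULL, ...) {
  lmax <- if (is.null(lam_max)) max(x$data$lam) else lam_max
  grid <- seq(1, lmax, length.out = 200)
  graphics::plot(x$data$lam, x$data$stress, xlab = "stretch ratio",
                 ylab = "Cauchy stress (MPa)", ...)
  graphics::lines(grid, predict(x, grid), col = 2)
  invisible(x)
}

#' Simulate stress-stretch data from a fitted constitutive model
#'
#' Draws replicate stress tables from the fitted response with multiplicative
#' lognormal noise, matching the noise model of the synthetic cohort
#' generator.
#'
#' @param object a `constitutive_fit`.
#' @param nsim number of replicate tables.
#' @param seed optional RNG seed.
#' @param lam stretch levels (default: the fitted levels).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param ... unused.
#' @return a list of `nsim` data frames with columns `lam`, `stress`.
#' @export
simulate.constitutive_fit <- function(object, nsim = 1, seed = NULL,
                                      lam = NULL, noise_cv = 0.02, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lam)) lam <- object$data$lam
  mu <- predict(object, lam)
  sdlog <- sqrt(log(1 + noise_cv^2))
  lapply(seq_len(nsim), function(i) {
    fac <- exp(stats::rnorm(length(lam), -sdlog^2 / 2, sdlog))
    data.frame(lam = lam, stress = mu * ifelse(lam > 1, fac, 1))
  })
}

#' Extrapolate a fitted stress-stretch curve
#'
#' Dense evaluation of the fitted model on a uniform stretch grid, flagging
#' points beyond the stretch range that was actually tested (the model is
#' routinely read out past the terminal trial, e.g. to 1.175).
#'
#' @param fit a `constitutive_fit`.
#' @param lam_max upper end of the grid, >= 1.
#' @param by grid spacing in stretch (default 1e-3).
#' @return data frame with columns `lam`, `stress` (MPa), `extrapolated`.
#' @export
extrapolate_curve <- function(fit, lam_max, by = 1e-3) {
  if (lam_max < 1) stop("lam_max must be >= 1")
  grid <- seq(1, lam_max, by = by)
  if (grid[length(grid)] < lam_max) grid <- c(grid, lam_max)
  data.frame(lam = grid, stress = predict(fit, grid),
             extrapolated = grid > max(fit$data$lam))
}
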