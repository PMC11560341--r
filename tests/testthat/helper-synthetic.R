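# shared fixtures and independent oracles for the test suite

# specimen with every generator range collapsed to the cohort-average point
point_specimen <- function(lambda50 = 1.108, width = 0.02, seed = 1,
                           cap_amp0 = 1, noise_sd = 0) {
  cfg <- cohort_config(d0 = c(1.42, 1.42), L0 = c(28.8, 28.8),
                       alpha = c(0.183, 0.183), beta = c(1.88, 1.88),
                       lambda50_mean = lambda50, lambda50_sd = 0,
                       width = width, cap_amp0 = cap_amp0,
                       noise_sd = noise_sd)
  generate_specimen(cfg, seed = seed)
}

# independent closed-form oracle for the logistic reduction truth
logistic_reduction_oracle <- function(lam, lambda50, width) {
  sig <- function(x) exp(x) / (1 + exp(x))   # algebraically distinct form
  s1 <- sig((1 - lambda50) / width)
  100 * (sig((lam - lambda50) / width) - s1) / (1 - 2 * s1)
}

# bounded linear least squares on the constitutive basis via explicit
# normal equations + KKT enumeration (independent of the package's QR path)
normal_equations_fit <- function(lam, stress) {
  g <- lam^2 - 1 / lam
  X <- cbind(2 * g, 4 * (lam^2 + 2 / lam - 3) * g)
  XtX <- t(X) %*% X
  Xty <- t(X) %*% stress
  best <- NULL
  best_sse <- Inf
  cands <- list(drop(solve(XtX, Xty)),
                c(drop(Xty[1] / XtX[1, 1]), 0),
                c(0, drop(Xty[2] / XtX[2, 2])),
                c(0, 0))
  for (p in cands) {
    if (any(p < 0)) next
    sse <- sum((stress - X %*% p)^2)
    if (sse < best_sse) { best_sse <- sse; best <- p }
  }
  c(alpha = best[1], beta = best[2])
}

# closed-form single-section inversion of the rod equilibrium
rod_lambda_oracle <- function(alpha, beta, A0, force, upper = 1.5) {
  if (force == 0) return(1)
  stats::uniroot(function(l)
    (2 * alpha + 4 * beta * (l^2 + 2 / l - 3)) * (l^2 - 1 / l) * A0 / l - force,
    c(1, upper), tol = 1e-14)$root
}

# three collinear (lam, reduction) points: the interpolating natural spline
# through them is the straight line itself
linear_curve <- function(lam0 = 1, lam1 = 1.2, r1 = 100) {
  lams <- c(lam0, (lam0 + lam1) / 2, lam1)
  fit_reduction_spline(data.frame(lam = lams,
                                  reduction = r1 * (lams - lam0) / (lam1 - lam0)),
                       smoothing = 1)
}
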