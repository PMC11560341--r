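#' Smoothing-spline map from stretch ratio to percent CAP reduction
#'
#' Fits a natural cubic smoothing spline to per-trial (stretch, reduction)
#' points. The smoothing parameter `p` follows the [0, 1] convention of the
#' penalized criterion
#' \deqn{p \sum_i (y_i - f(x_i))^2 + (1 - p) \int f''(x)^2 dx,}
#' so `p = 1` reproduces the interpolating natural cubic spline exactly and
#' smaller `p` gives smoother curves (p = 0 is the least-squares line). The
#' solve is the classic penalized normal system \eqn{(I + \mu K) g = y} with
#' \eqn{\mu = (1-p)/p} and K the natural-spline roughness matrix; the fitted
#' curve is the natural cubic interpolant of the fitted values.
#'
#' @param points data frame (or list) with columns `lam` (distinct stretch
#'   ratios, >= 3 points) and `reduction` (percent).
#' @param smoothing p in [0, 1]; default 0.9995 (near-interpolating).
#' @param specimen_id optional label carried in the result.
#' @return a `cap_stretch_curve`: function-like object with knots, fitted
#'   values, domain and the evaluator; use [predict()] or call
#'   [stretch_at_reduction()] to invert it.
#' @export
fit_reduction_spline <- function(points, smoothing = 0.9995,
                                 specimen_id = NA_character_) {
  if (is.list(points) && !is.data.frame(points)) points <- as.data.frame(points)
  x <- points$lam; y <- points$reduction
  if (length(x) < 3) stop("need at least 3 points to fit a spline")
  if (anyDuplicated(x)) stop("stretch values must be distinct")
  if (smoothing < 0 || smoothing > 1) stop("smoothing must be in [0, 1]")
  o <- order(x); x <- x[o]; y <- y[o]
  g <- if (smoothing == 1) y else {
    mu <- (1 - smoothing) / smoothing
    K <- .roughness_matrix(x)
    drop(solve(diag(length(x)) + mu * K, y))
  }
  fun <- stats::splinefun(x, g, method = "natural")
  structure(list(specimen_id = specimen_id,
                 knots = data.frame(lam = x, reduction = y),
                 fitted = g, smoothing = smoothing,
                 domain = range(x), fun = fun),
            class = "cap_stretch_curve")
}

# natural cubic spline roughness matrix K = t(D) W^-1 D (Green & Silverman)
.roughness_matrix <- function(x) {
  n <- length(x)
  h <- diff(x)
  D <- matrix(0, n - 2, n)
  W <- matrix(0, n - 2, n - 2)
  for (i in seq_len(n - 2)) {
    D[i, i] <- 1 / h[i]
    D[i, i + 1] <- -(1 / h[i] + 1 / h[i + 1])
    D[i, i + 2] <- 1 / h[i + 1]
    W[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < n - 2) W[i, i + 1] <- W[i + 1, i] <- h[i + 1] / 6
  }
  t(D) %*% solve(W, D)
}

#' Evaluate a stretch-to-reduction curve
#'
#' @param object a `cap_stretch_curve`.
#' @param lam stretch ratios inside the fitted domain (default: the knots).
#' @param ... unused.
#' @return percent CAP reduction.
#' @export
predict.cap_stretch_curve <- function(object, lam = NULL, ...) {
  if (is.null(lam)) lam <- object$knots$lam
  object$fun(lam)
}

#' @export
print.cap_stretch_curve <- function(x, ...) {
  cat(sprintf("stretch-reduction curve%s: %d knots on [%.3f, %.3f], smoothing %g\n",
              if (is.na(x$specimen_id)) "" else paste0(" (", x$specimen_id, ")"),
              nrow(x$knots), x$domain[1], x$domain[2], x$smoothing))
  invisible(x)
}

#' @export
plot.cap_stretch_curve <- function(x, ...) {
  grid <- seq(x$domain[1], x$domain[2], length.out = 200)
  graphics::plot(x$knots$lam, x$knots$reduction, xlab = "stretch ratio",
                 ylab = "CAP reduction (%)", ...)
  graphics::lines(grid, x$fun(grid), col = 2)
  invisible(x)
}

#' Stretch ratio at which a curve reaches a target CAP reduction
#'
#' Inverts the fitted curve: returns the smallest stretch in the fitted
#' domain at which the curve equals the target (first crossing), located by
#' a fine-grid bracket scan plus bisection to |curve - target| <= 1e-9. No
#' extrapolation: a target outside the range the curve attains is an error.
#'
#' @param curve a `cap_stretch_curve`.
#' @param target percent reduction.
#' @param n_scan grid resolution of the bracket scan.
#' @return stretch ratio.
#' @export
stretch_at_reduction <- function(curve, target, n_scan = 4096) {
  grid <- seq(curve$domain[1], curve$domain[2], length.out = n_scan)
  vals <- curve$fun(grid)
  if (target < min(vals) - 1e-9 || target > max(vals) + 1e-9)
    stop(sprintf("target %g%% outside the curve's attained range [%g, %g]",
                 target, min(vals), max(vals)))
  f <- function(l) curve$fun(l) - target
  d <- vals - target
  hit <- which(abs(d) <= 1e-9)
  cross <- which(d[-1] * d[-n_scan] < 0)
  cands <- numeric(0)
  if (length(hit)) cands <- grid[hit[1]]
  if (length(cross)) {
    lo <- grid[cross[1]]; hi <- grid[cross[1] + 1]
    r <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.8)$root
    # polish by bisection until the value tolerance is met
    flo <- f(lo); fhi <- f(hi)
    a <- lo; b <- hi; fa <- flo
    for (it in 1:200) {
      if (abs(f(r)) <= 1e-9) break
      if (fa * f(r) <= 0) b <- r else { a <- r; fa <- f(r) }
      r <- (a + b) / 2
    }
    cands <- c(cands, r)
  }
  if (!length(cands)) {
    # target equals an extremum to within tolerance: nearest grid point
    cands <- grid[which.min(abs(d))]
  }
  min(cands)
}

#' Cohort confidence intervals for stretch at given CAP reductions
#'
#' At each reduction level on the grid (0 to `max_reduction` percent in
#' `grid_step` increments), every specimen curve that attains the level is
#' inverted with [stretch_at_reduction()]; the per-level Student-t interval
#' is \eqn{\bar\lambda \pm t_{(1+level)/2,\,n-1}\, s/\sqrt{n}}. Levels where
#' fewer than two curves contribute are reported as missing, and the number
#' of curves dropped at each level is recorded.
#'
#' @param curves list of `cap_stretch_curve` objects.
#' @param grid_step reduction increment (percent), default 2.5.
#' @param max_reduction top of the grid (percent), default 50.
#' @param level confidence level, default 0.95.
#' @return a `cohort_ci` data frame: reduction, mean_stretch, half_width,
#'   ci_low, ci_high, n, n_dropped.
#' @export
cohort_ci <- function(curves, grid_step = 2.5, max_reduction = 50,
                      level = 0.95) {
  grid <- seq(0, max_reduction, by = grid_step)
  rows <- lapply(grid, function(r) {
    lams <- numeric(0)
    dropped <- 0L
    for (cv in curves) {
      li <- tryCatch(stretch_at_reduction(cv, r), error = function(e) NA_real_)
      if (is.na(li)) dropped <- dropped + 1L else lams <- c(lams, li)
    }
    n <- length(lams)
    if (n < 2) {
      data.frame(reduction = r, mean_stretch = NA_real_, half_width = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, n = n,
                 n_dropped = dropped)
    } else {
      m <- mean(lams)
      hw <- stats::qt((1 + level) / 2, n - 1) * stats::sd(lams) / sqrt(n)
      data.frame(reduction = r, mean_stretch = m, half_width = hw,
                 ci_low = m - hw, ci_high = m + hw, n = n,
                 n_dropped = dropped)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  class(out) <- c("cohort_ci", "data.frame")
  out
}

#' @export
print.cohort_ci <- function(x, ...) {
  cat(sprintf("Cohort %g%% confidence intervals (stretch at CAP reduction)\n",
              100 * attr(x, "level")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
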