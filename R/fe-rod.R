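#' Build an axisymmetric rod mesh from a diameter profile
#'
#' Uniformly spaced 1-D elements along the nerve axis; each element carries
#' the reference cross-sectional area evaluated from the diameter profile at
#' its midpoint (circular sections).
#'
#' @param profile function mapping axial position z (mm, reference
#'   configuration) to local diameter (mm), or a single number for a uniform
#'   rod.
#' @param length rod length (mm).
#' @param n_elem number of elements (>= 1).
#' @return a `rod_mesh`: z_nodes (mm), A0_elem (mm^2), d_elem (mm), n_elem.
#' @examples
#' build_mesh(1.42, length = 28.8, n_elem = 10)                  # uniform
#' build_mesh(function(z) 1.42 - 0.4 * z / 28.8, 28.8, 20)       # taper
#' @export
build_mesh <- function(profile, length, n_elem = 20) {
  if (n_elem < 1) stop("need at least one element")
  if (length <= 0) stop("rod length must be positive")
  if (is.numeric(profile)) {
    d0 <- profile
    profile <- function(z) rep(d0, length.out = base::length(z))
  }
  z <- seq(0, length, length.out = n_elem + 1)
  zmid <- (z[-1] + z[-(n_elem + 1)]) / 2
  d <- profile(zmid)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("diameter profile must be positive over the rod")
  structure(list(z_nodes = z, A0_elem = circle_area(d), d_elem = d,
                 n_elem = n_elem),
            class = "rod_mesh")
}

#' @export
print.rod_mesh <- function(x, ...) {
  cat(sprintf("rod mesh: %d elements over %.2f mm, A0 in [%.4g, %.4g] mm^2\n",
              x$n_elem, x$z_nodes[length(x$z_nodes)] - x$z_nodes[1],
              min(x$A0_elem), max(x$A0_elem)))
  invisible(x)
}

# safeguarded Newton for the element equilibrium
# g(lam) = T11(lam) * A0 / lam - F = 0 on [1, lam_cap]
.solve_element <- function(alpha, beta, A0, force, lam_cap = 1.5,
                           tol = 1e-10, max_iter = 100) {
  g <- function(l) model_stress(alpha, beta, l) * A0 / l - force
  if (force == 0) return(list(lam = 1, iter = 0L))
  g_hi <- g(lam_cap)
  if (g_hi < 0)
    stop(sprintf("force %g N requires stretch beyond the cap %.3g", force,
                 lam_cap))
  a <- 1; b <- lam_cap
  lam <- min(1 + force / (g(1 + 1e-6) - g(1)) * 1e-6, lam_cap)  # secant guess
  if (!is.finite(lam) || lam <= a || lam >= b) lam <- (a + b) / 2
  h <- 1e-7
  for (it in seq_len(max_iter)) {
    gl <- g(lam)
    if (abs(gl) <= tol) return(list(lam = lam, iter = it))
    if (gl > 0) b <- lam else a <- lam
    dg <- (g(lam + h) - g(lam - h)) / (2 * h)
    step <- if (dg > 0) lam - gl / dg else NA_real_
    lam <- if (is.finite(step) && step > a && step < b) step else (a + b) / 2
  }
  stop("element equilibrium did not converge within max_iter")
}

.rod_solution <- function(mesh, alpha, beta, force, lam, iters) {
  dL <- diff(mesh$z_nodes)
  T11 <- model_stress(alpha, beta, lam)
  structure(list(mesh = mesh, alpha = alpha, beta = beta,
                 lam_elem = lam, T11_elem = T11,
                 reduction_elem = rep(NA_real_, mesh$n_elem),
                 force = force,
                 global_stretch = sum(lam * dL) / sum(dL),
                 converged = TRUE, iterations = iters),
            class = "rod_solution")
}

#' Solve the rod under a prescribed axial force
#'
#' In a statically determinate rod the axial force is spatially constant, so
#' equilibrium decouples element by element: each element's stretch solves
#' \eqn{T_{11}(\lambda)\,A_{0,e}/\lambda = F} by safeguarded Newton
#' (bisection fallback) to |residual| <= 1e-10 N on the bracket
#' [1, `lam_cap`].
#'
#' @param mesh a [build_mesh()] result.
#' @param alpha,beta material parameters (MPa); alpha + beta must be > 0.
#' @param force axial force (N), >= 0.
#' @param lam_cap largest admissible element stretch (default 1.5).
#' @return a `rod_solution`: per-element stretch, axial Cauchy stress (MPa),
#'   predicted CAP reduction (filled by [map_cap_field()]), the force,
#'   global stretch, convergence info.
#' @export
solve_force_controlled <- function(mesh, alpha, beta, force, lam_cap = 1.5) {
  if (force < 0) stop("force must be non-negative")
  if (alpha + beta <= 0) stop("material must be non-degenerate (alpha + beta > 0)")
  sols <- lapply(mesh$A0_elem, function(A0)
    .solve_element(alpha, beta, A0, force, lam_cap))
  .rod_solution(mesh, alpha, beta, force,
                vapply(sols, `[[`, numeric(1), "lam"),
                vapply(sols, `[[`, integer(1), "iter"))
}

#' Solve the rod under a prescribed global stretch
#'
#' Outer scalar solve on the axial force such that the length-weighted mean
#' element stretch matches the prescribed global stretch to <= 1e-8, with
#' the element solves of [solve_force_controlled()] inside.
#'
#' @param mesh a [build_mesh()] result.
#' @param alpha,beta material parameters (MPa).
#' @param global_stretch deformed length / reference length, >= 1.
#' @param lam_cap largest admissible element stretch.
#' @return a `rod_solution`.
#' @export
solve_stretch_controlled <- function(mesh, alpha, beta, global_stretch,
                                     lam_cap = 1.5) {
  if (global_stretch < 1) stop("global stretch must be >= 1")
  if (global_stretch == 1)
    return(solve_force_controlled(mesh, alpha, beta, 0, lam_cap))
  # force at which the smallest element reaches the cap bounds the search
  f_max <- model_stress(alpha, beta, lam_cap) * min(mesh$A0_elem) / lam_cap
  mean_lam <- function(f)
    solve_force_controlled(mesh, alpha, beta, f, lam_cap)$global_stretch
  if (mean_lam(f_max) < global_stretch)
    stop("prescribed stretch unreachable without exceeding the element cap")
  f <- stats::uniroot(function(f) mean_lam(f) - global_stretch,
                      c(0, f_max), tol = 1e-13)$root
  # polish on the stretch residual
  for (it in 1:60) {
    sol <- solve_force_controlled(mesh, alpha, beta, f, lam_cap)
    r <- sol$global_stretch - global_stretch
    if (abs(r) <= 1e-9) break
    df <- 1e-6 * max(f, 1e-6)
    slope <- (mean_lam(f + df) - sol$global_stretch) / df
    f <- f - r / slope
  }
  sol
}

#' Map a stretch-reduction curve onto a rod solution
#'
#' Predicted per-element CAP reduction by linear interpolation of the
#' curve's sampled knot table (step 0.001 in stretch) at each element
#' stretch. Below the calibrated range the reduction is 0; above it the
#' default policy clamps to the boundary value (`"clamp"`), or raises an
#' error (`"error"`), or extends the last linear piece (`"linear"`).
#'
#' @param sol a `rod_solution`.
#' @param curve a `cap_stretch_curve`.
#' @param clamp_policy `"clamp"`, `"error"` or `"linear"`.
#' @param step sampling step of the curve's knot table in stretch units.
#' @return the `rod_solution` with `reduction_elem` filled.
#' @export
map_cap_field <- function(sol, curve, clamp_policy = c("clamp", "error",
                                                       "linear"),
                          step = 1e-3) {
  clamp_policy <- match.arg(clamp_policy)
  lk <- seq(curve$domain[1], curve$domain[2], by = step)
  if (lk[length(lk)] < curve$domain[2]) lk <- c(lk, curve$domain[2])
  rk <- curve$fun(lk)
  lam <- sol$lam_elem
  if (clamp_policy == "error" && any(lam > curve$domain[2]))
    stop("element stretch beyond the calibrated curve range")
  red <- stats::approx(lk, rk, xout = pmin(pmax(lam, lk[1]), lk[length(lk)]))$y
  if (clamp_policy == "linear") {
    hi <- lam > lk[length(lk)]
    if (any(hi)) {
      slope <- (rk[length(rk)] - rk[length(rk) - 1]) / (lk[length(lk)] - lk[length(lk) - 1])
      red[hi] <- rk[length(rk)] + slope * (lam[hi] - lk[length(lk)])
    }
  }
  red[lam < lk[1]] <- 0
  sol$reduction_elem <- red
  sol
}

#' @export
print.rod_solution <- function(x, ...) {
  cat(sprintf("rod solution: F = %.4g N, global stretch %.4f, %d elements\n",
              x$force, x$global_stretch, x$mesh$n_elem))
  cat(sprintf("  stretch in [%.4f, %.4f], T11 in [%.4g, %.4g] MPa\n",
              min(x$lam_elem), max(x$lam_elem), min(x$T11_elem),
              max(x$T11_elem)))
  if (!all(is.na(x$reduction_elem)))
    cat(sprintf("  CAP reduction in [%.1f, %.1f]%%\n",
                min(x$reduction_elem), max(x$reduction_elem)))
  invisible(x)
}

#' @export
summary.rod_solution <- function(object, ...) {
  resid <- object$T11_elem * object$mesh$A0_elem / object$lam_elem -
    object$force
  out <- list(force = object$force, global_stretch = object$global_stretch,
              max_force_residual = max(abs(resid)),
              lam_range = range(object$lam_elem),
              stress_range = range(object$T11_elem))
  class(out) <- "summary.rod_solution"
  out
}

#' @export
print.summary.rod_solution <- function(x, ...) {
  cat(sprintf("F = %.6g N, global stretch %.6f\n", x$force, x$global_stretch))
  cat(sprintf("max |force balance residual| = %.3g N\n",
              x$max_force_residual))
  cat(sprintf("element stretch [%.6f, %.6f], stress [%.4g, %.4g] MPa\n",
              x$lam_range[1], x$lam_range[2], x$stress_range[1],
              x$stress_range[2]))
  invisible(x)
}

#' Field table of a rod solution
#'
#' @param sol a `rod_solution`.
#' @return data frame: z_mid_mm (reference), lam, T11_MPa, reduction_pct.
#' @export
rod_field_table <- function(sol) {
  z <- sol$mesh$z_nodes
  data.frame(z_mid_mm = (z[-1] + z[-length(z)]) / 2, lam = sol$lam_elem,
             T11_MPa = sol$T11_elem, reduction_pct = sol$reduction_elem)
}

#' Export a rod solution as a legacy-ASCII VTK unstructured grid
#'
#' Writes the deformed configuration: node axial positions advance by the
#' cumulative element stretches, and the local radius scales by
#' \eqn{\lambda^{-1/2}} (isochoric uniaxial kinematics). Nodes carry the
#' deformed radius as point data; elements (VTK line cells) carry stretch,
#' axial Cauchy stress and predicted CAP reduction as cell data.
#'
#' @param sol a `rod_solution`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
export_field <- function(sol, path) {
  mesh <- sol$mesh
  n_node <- length(mesh$z_nodes)
  dL <- diff(mesh$z_nodes)
  z_def <- c(0, cumsum(sol$lam_elem * dL)) + mesh$z_nodes[1]
  r_elem <- mesh$d_elem / 2 / sqrt(sol$lam_elem)
  # node radius: average of adjacent element radii
  r_node <- c(r_elem[1], (r_elem[-1] + r_elem[-mesh$n_elem]) / 2,
              r_elem[mesh$n_elem])
  num <- function(x) formatC(x, format = "g", digits = 17)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("deformed axisymmetric nerve rod: stretch, axial stress, CAP reduction")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS ", n_node, " double")
  for (i in seq_len(n_node)) wl("0 0 ", num(z_def[i]))
  wl("CELLS ", mesh$n_elem, " ", 3 * mesh$n_elem)
  for (e in seq_len(mesh$n_elem)) wl("2 ", e - 1, " ", e)
  wl("CELL_TYPES ", mesh$n_elem)
  for (e in seq_len(mesh$n_elem)) wl("3")  # VTK_LINE
  wl("POINT_DATA ", n_node)
  wl("SCALARS radius_mm double 1")
  wl("LOOKUP_TABLE default")
  for (i in seq_len(n_node)) wl(num(r_node[i]))
  wl("CELL_DATA ", mesh$n_elem)
  for (fld in c("stretch", "axial_stress_MPa", "cap_reduction_pct")) {
    vals <- switch(fld, stretch = sol$lam_elem,
                   axial_stress_MPa = sol$T11_elem,
                   cap_reduction_pct = sol$reduction_elem)
    wl("SCALARS ", fld, " double 1")
    wl("LOOKUP_TABLE default")
    for (v in vals) wl(num(v))
  }
  invisible(path)
}
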