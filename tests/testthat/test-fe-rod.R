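test_that("meshes sample the diameter profile at element midpoints", {
  m <- build_mesh(1.42, 28.8, 10)
  expect_equal(m$A0_elem, rep(pi * 0.71^2, 10))
  expect_length(m$z_nodes, 11)

  one <- build_mesh(1.42, 28.8, 1)
  expect_equal(one$z_nodes, c(0, 28.8))

  taper <- build_mesh(function(z) 1.42 - 0.42 * z / 28.8, 28.8, 15)
  expect_true(all(diff(taper$A0_elem) < 0))

  expect_error(build_mesh(function(z) 1 - z / 10, 28.8, 10), "positive")
})

test_that("force-controlled solutions match the closed-form inversion", {
  m <- build_mesh(1.42, 28.8, 10)
  A0 <- pi * 0.71^2
  for (f in c(0.05, 0.2503701, 0.45)) {
    sol <- solve_force_controlled(m, 0.183, 1.88, f)
    lam_star <- rod_lambda_oracle(0.183, 1.88, A0, f)
    expect_true(all(abs(sol$lam_elem - lam_star) <= 1e-8))
    resid <- sol$T11_elem * m$A0_elem / sol$lam_elem - f
    expect_true(all(abs(resid) <= 1e-8))
  }
  sol0 <- solve_force_controlled(m, 0.183, 1.88, 0)
  expect_equal(sol0$lam_elem, rep(1, 10))
  expect_equal(sol0$T11_elem, rep(0, 10))
})

test_that("thinner elements stretch more under the same force", {
  taper <- build_mesh(function(z) 1.42 - 0.42 * z / 28.8, 28.8, 15)
  sol <- solve_force_controlled(taper, 0.183, 1.88, 0.2)
  expect_true(all(diff(sol$lam_elem) > 0))   # area decreases along z
  expect_gt(max(sol$lam_elem), sol$global_stretch)
  expect_lt(min(sol$lam_elem), sol$global_stretch)
})

test_that("stretch control reproduces the prescribed global stretch", {
  m <- build_mesh(1.42, 28.8, 10)
  sol <- solve_stretch_controlled(m, 0.183, 1.88, 1.1)
  expect_equal(sol$global_stretch, 1.1, tolerance = 1e-8)
  expect_equal(sol$force, 0.2503701, tolerance = 1e-4)

  expect_equal(solve_stretch_controlled(m, 0.183, 1.88, 1)$force, 0)

  taper <- build_mesh(function(z) 1.42 - 0.42 * z / 28.8, 28.8, 15)
  ts <- solve_stretch_controlled(taper, 0.183, 1.88, 1.1)
  expect_lt(min(ts$lam_elem), 1.1)
  expect_gt(max(ts$lam_elem), 1.1)

  # round-trip: re-imposing the solved force returns the same stretch field
  back <- solve_force_controlled(taper, 0.183, 1.88, ts$force)
  expect_true(all(abs(back$lam_elem - ts$lam_elem) <= 1e-7))
})

test_that("unreachable stretches and degenerate materials are rejected", {
  m <- build_mesh(1.42, 28.8, 4)
  expect_error(solve_stretch_controlled(m, 0.183, 1.88, 1.49, lam_cap = 1.2),
               "cap")
  expect_error(solve_force_controlled(m, 0, 0, 0.1), "non-degenerate")
})

test_that("CAP mapping linearly interpolates the calibrated curve", {
  m <- build_mesh(1.42, 28.8, 6)
  curve <- linear_curve(1, 1.2, 100)
  sol <- solve_stretch_controlled(m, 0.183, 1.88, 1.05)
  sol <- map_cap_field(sol, curve)
  expect_equal(sol$reduction_elem, rep(25, 6), tolerance = 1e-6)

  sol0 <- map_cap_field(solve_force_controlled(m, 0.183, 1.88, 0), curve)
  expect_equal(sol0$reduction_elem, rep(0, 6))

  # element stretch beyond the curve domain: clamp vs error policies
  hi <- solve_stretch_controlled(m, 0.183, 1.88, 1.3)
  expect_equal(map_cap_field(hi, curve)$reduction_elem, rep(100, 6),
               tolerance = 1e-6)
  expect_error(map_cap_field(hi, curve, clamp_policy = "error"), "beyond")
})

test_that("monotone curves give reductions monotone in imposed stretch", {
  m <- build_mesh(function(z) 1.42 - 0.3 * z / 28.8, 28.8, 8)
  sp <- point_specimen()
  lam <- stretch_protocol()
  curve <- fit_reduction_spline(
    data.frame(lam = lam, reduction = true_reduction(sp, lam)), smoothing = 1)
  reds <- vapply(c(1, 1.05, 1.1, 1.15), function(g) {
    s <- map_cap_field(solve_stretch_controlled(m, 0.183, 1.88, g), curve)
    mean(s$reduction_elem)
  }, numeric(1))
  expect_true(all(diff(reds) > 0))
})

test_that("VTK export writes the deformed geometry and round-trips", {
  m <- build_mesh(1.42, 28.8, 5)
  sol <- solve_stretch_controlled(m, 0.183, 1.88, 1.1)
  sol <- map_cap_field(sol, linear_curve())
  path <- tempfile(fileext = ".vtk")
  export_field(sol, path)
  lines <- readLines(path)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")

  # minimal legacy-format reader: points and named cell-data arrays
  ipts <- grep("^POINTS", lines)
  n_pts <- as.integer(strsplit(lines[ipts], " ")[[1]][2])
  pts <- do.call(rbind, lapply(lines[(ipts + 1):(ipts + n_pts)],
                               function(l) as.numeric(strsplit(l, " +")[[1]])))
  expect_equal(pts[nrow(pts), 3] - pts[1, 3], 28.8 * 1.1, tolerance = 1e-7)

  read_cell_array <- function(name) {
    i <- grep(paste0("^SCALARS ", name), lines)
    as.numeric(lines[(i + 2):(i + 1 + m$n_elem)])
  }
  expect_identical(read_cell_array("stretch"), sol$lam_elem)
  expect_identical(read_cell_array("axial_stress_MPa"), sol$T11_elem)
  expect_identical(read_cell_array("cap_reduction_pct"), sol$reduction_elem)

  # volume conservation of the exported isochoric geometry
  dL <- diff(m$z_nodes)
  vol_ref <- sum(m$A0_elem * dL)
  vol_def <- sum((m$A0_elem / sol$lam_elem) * (sol$lam_elem * dL))
  expect_equal(vol_def, vol_ref)

  # identity deformation leaves the reference geometry untouched
  p0 <- tempfile(fileext = ".vtk")
  export_field(solve_force_controlled(m, 0.183, 1.88, 0), p0)
  l0 <- readLines(p0)
  i0 <- grep("^POINTS", l0)
  z0 <- vapply((i0 + 1):(i0 + n_pts),
               function(i) as.numeric(strsplit(l0[i], " +")[[1]])[3],
               numeric(1))
  expect_equal(z0, m$z_nodes)
  unlink(c(path, p0))
})
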