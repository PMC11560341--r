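# independent classical sums-of-squares oracle for a balanced 2x2 design
balanced_anova_oracle <- function(y, f1, f2) {
  n <- length(y)
  gm <- mean(y)
  m1 <- tapply(y, f1, mean); m2 <- tapply(y, f2, mean)
  m12 <- tapply(y, interaction(f1, f2), mean)
  counts <- table(f1, f2)
  r <- counts[1, 1]
  ss1 <- sum(table(f1) * (m1 - gm)^2)
  ss2 <- sum(table(f2) * (m2 - gm)^2)
  sscell <- r * sum((m12 - gm)^2)
  ss12 <- sscell - ss1 - ss2
  sse <- sum((y - ave(y, interaction(f1, f2)))^2)
  dfe <- n - 4
  f <- c(ss1, ss2, ss12) / (sse / dfe)
  p <- stats::pf(f, 1, dfe, lower.tail = FALSE)
  list(F = f, p = p)
}

test_that("two-way ANOVA matches the classical balanced closed form", {
  set.seed(21)
  sex <- rep(c("male", "female"), each = 10)
  side <- rep(rep(c("left", "right"), each = 5), 2)
  y <- rnorm(20, 10, 1) + 2 * (sex == "male") + 0.5 * (side == "left")
  res <- two_way_anova(y, sex, side)
  oracle <- balanced_anova_oracle(y, factor(sex), factor(side))
  expect_equal(res$F, oracle$F, tolerance = 1e-10)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
})

test_that("constant responses give no effect by convention", {
  res <- two_way_anova(rep(5, 8), rep(c("male", "female"), 4),
                       rep(c("left", "right"), each = 4))
  expect_true(all(res$F == 0))
  expect_true(all(res$p == 1))
})

test_that("a strong factor-1 effect is detected and factor 2 stays null", {
  set.seed(22)
  sex <- rep(c("male", "female"), each = 10)
  side <- rep(rep(c("left", "right"), each = 5), 2)
  y <- ifelse(sex == "male", 20, 10) + rnorm(20, 0, 1)
  res <- two_way_anova(y, sex, side)
  expect_lt(res$p[res$term == "sex"], 1e-6)
  expect_gt(res$p[res$term == "side"], 1e-3)
})

test_that("type-I error of the null two-way ANOVA is calibrated", {
  set.seed(23)
  sex <- rep(c("male", "female"), each = 8)
  side <- rep(rep(c("left", "right"), each = 4), 2)
  rejections <- replicate(600, {
    y <- rnorm(16)
    any(two_way_anova(y, sex, side)$p[1] < 0.05)
  })
  expect_gte(mean(!rejections), 0.92)
})

test_that("degenerate factor layouts error or drop the interaction", {
  expect_error(two_way_anova(rnorm(6), rep("male", 6),
                             rep(c("left", "right"), 3)),
               "2 observed levels")
  sex <- c("male", "male", "female", "female", "male", "female")
  side <- c("left", "left", "left", "left", "right", "left")
  side[5] <- "right"   # male/right occupied, female/right empty
  expect_warning(res <- two_way_anova(rnorm(6), sex, side), "empty cell")
  expect_false("interaction" %in% res$term)
})

test_that("the full pipeline reproduces a noiseless synthetic cohort", {
  dir <- file.path(tempdir(), "pipe_cohort")
  cfg <- cohort_config(noise_sd = 0)
  rec <- recording_config(fs = 2e4, record_duration = 9.2)
  out <- simulate_cohort(n = 4, seed = 5, dir = dir, config = cfg, rec = rec,
                         force_noise_cv = 0, n_fibers_section = 400)
  res <- suppressWarnings(run_pipeline(dir, n_elem = 8))

  truth <- out$specimens
  fits <- res$fits[res$fits$trial != "Average", ]
  for (i in seq_along(truth)) {
    row <- fits[fits$trial == truth[[i]]$id, ]
    expect_equal(row$alpha_MPa, truth[[i]]$alpha_true, tolerance = 1e-6)
    expect_equal(row$beta_MPa, truth[[i]]$beta_true, tolerance = 1e-6)
    expect_equal(row$r2, 1, tolerance = 1e-9)
  }
  # measured reductions track the generating truth closely
  for (i in seq_along(truth)) {
    m <- res$measurements[res$measurements$specimen_id == truth[[i]]$id, ]
    expect_equal(m$reduction_pct, true_reduction(truth[[i]], m$stretch),
                 tolerance = 0.01)
  }
  expect_true(file.exists(file.path(dir, "report", "fits.csv")))
  expect_true(file.exists(file.path(dir, "report", "fe_demo.vtk")))
  expect_s3_class(res$ci, "cohort_ci")
  expect_false(is.null(res$fibers))
  expect_lt(res$fibers$comparison$t_p, 0.05)

  # determinism: an identical second simulation yields byte-identical reports
  dir2 <- file.path(tempdir(), "pipe_cohort2")
  simulate_cohort(n = 4, seed = 5, dir = dir2, config = cfg, rec = rec,
                  force_noise_cv = 0, n_fibers_section = 400)
  suppressWarnings(run_pipeline(dir2, n_elem = 8))
  for (f in c("fits.csv", "measurements.csv", "confidence_intervals.csv",
              "inversions.csv"))
    expect_identical(readLines(file.path(dir, "report", f)),
                     readLines(file.path(dir2, "report", f)))
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("missing inputs fail with an actionable message", {
  empty <- file.path(tempdir(), "empty_cohort")
  dir.create(empty, showWarnings = FALSE)
  expect_error(run_pipeline(empty), "metadata")
  write.csv(data.frame(id = "S01", sex = "male", side = "left",
                       L0_mm = 28.8, d0_mm = 1.42),
            file.path(empty, "metadata.csv"), row.names = FALSE)
  expect_error(run_pipeline(empty), "force")
  unlink(empty, recursive = TRUE)
})

test_that("the bundled reference fits average to the published cohort values", {
  tab <- reference_alpha_beta()
  expect_equal(nrow(tab), 7)
  expect_equal(signif(mean(tab$alpha_MPa), 3), 0.183)
  expect_equal(signif(mean(tab$beta_MPa), 3), 1.88)
})
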