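#' Two-way ANOVA for sex and side effects
#'
#' Fits `value ~ sex * side` and reports per-term F and p from Type II sums
#' of squares, which handle the unbalanced cohorts that arise after specimen
#' exclusions (Type I and II coincide for balanced designs). If some cell is
#' empty the interaction is inestimable and is dropped with a warning.
#'
#' @param values per-specimen scalar response (e.g. stretch at 50% CAP
#'   reduction, or a material parameter).
#' @param sex,side factors with two levels each.
#' @param ss_type sums-of-squares type passed to [car::Anova()] (2 or 3).
#' @return an `anova2_result`: data frame of terms with F, df and p, plus
#'   attributes `ss_type` and `interaction_dropped`.
#' @export
two_way_anova <- function(values, sex, side, ss_type = 2) {
  sex <- factor(sex); side <- factor(side)
  if (nlevels(sex) < 2 || nlevels(side) < 2)
    stop("each factor needs at least 2 observed levels")
  cells <- table(sex, side)
  if (stats::sd(values) == 0) {
    # constant response: every sum of squares vanishes; report no effect
    terms <- c("sex", "side", "interaction")
    out <- data.frame(term = terms, F = 0, df = 1, p = 1)
    return(structure(out, ss_type = ss_type, interaction_dropped = FALSE,
                     class = c("anova2_result", "data.frame")))
  }
  dropped <- FALSE
  if (any(cells == 0)) {
    warning("empty cell: interaction dropped from the model")
    fit <- stats::lm(values ~ sex + side)
    dropped <- TRUE
  } else {
    fit <- stats::lm(values ~ sex * side)
  }
  a <- car::Anova(fit, type = ss_type)
  rows <- rownames(a) != "Residuals"
  out <- data.frame(term = rownames(a)[rows], F = a$`F value`[rows],
                    df = a$Df[rows], p = a$`Pr(>F)`[rows])
  out$term <- sub("sex:side", "interaction", out$term)
  structure(out, ss_type = ss_type, interaction_dropped = dropped,
            class = c("anova2_result", "data.frame"))
}

#' @export
print.anova2_result <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (Type %s SS)%s\n", attr(x, "ss_type"),
              if (attr(x, "interaction_dropped")) ", interaction dropped" else ""))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Published two-parameter constitutive fits for rat sciatic nerves
#'
#' Reads the bundled reference table of per-nerve (alpha, beta) values for
#' seven ex vivo rat sciatic nerve specimens.
#'
#' @return data frame with columns `trial`, `alpha_MPa`, `beta_MPa`.
#' @export
reference_alpha_beta <- function() {
  utils::read.csv(system.file("extdata", "rat_sciatic_alpha_beta.csv",
                              package = "nervestretch"))
}

#' Run the full analysis pipeline on a cohort directory
#'
#' Orchestrates every stage on the file layout written by
#' [simulate_cohort()] (the same layout is expected for real data): per
#' specimen, the raw traces are preprocessed, epoch-averaged and measured;
#' percent CAP reductions follow from the unstretched amplitude; Cauchy
#' stress is computed from the force table and geometry and the constitutive
#' model fitted; a reduction spline is fitted and inverted on the standard
#' grid; cohort confidence intervals, sex-by-side ANOVAs, the latency
#' comparison and the fiber-angle group comparison are assembled; and an FE
#' rod demonstration is solved for the first specimen at its stretch at 50%
#' reduction. All tables are written as CSV under `out_dir`.
#'
#' @param dir cohort input directory.
#' @param out_dir output directory for the report CSVs (default
#'   `file.path(dir, "report")`).
#' @param band,artifact_blank signal-chain settings (see [preprocess()] and
#'   [measure_cap()]).
#' @param smoothing spline smoothing parameter in [0, 1].
#' @param grid_step,max_reduction,level confidence-interval grid settings.
#' @param n_elem elements of the FE demonstration rod.
#' @return invisibly, a list with `measurements`, `fits`, `ci`,
#'   `inversions`, `anova`, `latency_test`, `fibers`, `fe_field`.
#' @export
run_pipeline <- function(dir, out_dir = file.path(dir, "report"),
                         band = c(100, 5000), artifact_blank = 0.5e-3,
                         smoothing = 0.9995, grid_step = 2.5,
                         max_reduction = 50, level = 0.95, n_elem = 20) {
  meta_file <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_file)) stop("missing cohort metadata: ", meta_file)
  meta <- utils::read.csv(meta_file)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  measurements <- NULL
  fits <- NULL
  curves <- list()
  lat_ref <- lat_fin <- numeric(0)
  for (i in seq_len(nrow(meta))) {
    id <- meta$id[i]
    ff <- file.path(dir, sprintf("force_%s.csv", id))
    if (!file.exists(ff)) stop("missing force table: ", ff)
    ft <- utils::read.csv(ff)
    tr_files <- sort(list.files(dir, sprintf("^trace_%s_[0-9.]+\\.csv$", id),
                                full.names = TRUE))
    if (!length(tr_files)) stop("no trace files for specimen ", id)
    lams <- as.numeric(sub(".*_([0-9.]+)\\.csv$", "\\1", tr_files))
    ms <- lapply(tr_files, function(f) {
      tr <- read_cap_trace(f, sub("\\.csv$", "_stims.csv", f))
      process_recording(tr, band = band, artifact_blank = artifact_blank)
    })
    amp <- vapply(ms, `[[`, numeric(1), "amplitude")
    lat <- vapply(ms, `[[`, numeric(1), "latency")
    red <- cap_reduction(amp[lams == 1][1], amp)
    mrows <- data.frame(specimen_id = id, stretch = lams,
                        amplitude_mV = amp, latency_ms = lat,
                        n_sweeps = vapply(ms, `[[`, numeric(1), "n_sweeps"),
                        reduction_pct = red)
    measurements <- rbind(measurements, mrows)
    lat_ref <- c(lat_ref, lat[lams == 1][1])
    lat_fin <- c(lat_fin, lat[length(lat)])

    A0 <- circle_area(meta$d0_mm[i])
    fit <- fit_constitutive(ft, A0 = A0)
    fits <- rbind(fits, data.frame(trial = id, alpha_MPa = fit$alpha,
                                   beta_MPa = fit$beta, r2 = fit$r2))
    curves[[id]] <- fit_reduction_spline(
      data.frame(lam = lams, reduction = red), smoothing = smoothing,
      specimen_id = id)
  }
  fits <- rbind(fits, data.frame(trial = "Average",
                                 alpha_MPa = mean(fits$alpha_MPa),
                                 beta_MPa = mean(fits$beta_MPa),
                                 r2 = mean(fits$r2)))

  ci <- cohort_ci(curves, grid_step, max_reduction, level)
  inv <- do.call(rbind, lapply(names(curves), function(id) {
    grid <- seq(0, max_reduction, by = grid_step)
    lam <- vapply(grid, function(r)
      tryCatch(stretch_at_reduction(curves[[id]], r),
               error = function(e) NA_real_), numeric(1))
    data.frame(specimen_id = id, reduction_pct = grid, stretch = lam)
  }))

  lam50 <- vapply(names(curves), function(id)
    tryCatch(stretch_at_reduction(curves[[id]], 50),
             error = function(e) NA_real_), numeric(1))
  av <- merge(data.frame(id = names(curves), lam_at_50 = lam50), meta,
              by = "id")
  anova_tabs <- list()
  if (sum(!is.na(av$lam_at_50)) >= 4) {
    ok <- !is.na(av$lam_at_50)
    anova_tabs$lam_at_50 <- tryCatch(
      two_way_anova(av$lam_at_50[ok], av$sex[ok], av$side[ok]),
      error = function(e) NULL)
  }
  fa <- merge(fits[fits$trial != "Average", ], meta,
              by.x = "trial", by.y = "id")
  anova_tabs$alpha <- tryCatch(two_way_anova(fa$alpha_MPa, fa$sex, fa$side),
                               error = function(e) NULL)
  anova_tabs$beta <- tryCatch(two_way_anova(fa$beta_MPa, fa$sex, fa$side),
                              error = function(e) NULL)

  lat_test <- if (length(lat_ref) >= 2) compare_latencies(lat_ref, lat_fin)
              else NULL

  fib_file <- file.path(dir, "fiber_angles.csv")
  fibers <- if (file.exists(fib_file))
    analyze_fiber_cohort(utils::read.csv(fib_file)) else NULL

  # FE demonstration: first specimen geometry at its stretch at 50% reduction
  fe_field <- NULL
  if (!is.na(lam50[1])) {
    mesh <- build_mesh(meta$d0_mm[1], meta$L0_mm[1], n_elem)
    sol <- solve_stretch_controlled(mesh, fits$alpha_MPa[1], fits$beta_MPa[1],
                                    lam50[1])
    sol <- map_cap_field(sol, curves[[1]])
    fe_field <- rod_field_table(sol)
    export_field(sol, file.path(out_dir, "fe_demo.vtk"))
    utils::write.csv(fe_field, file.path(out_dir, "fe_field.csv"),
                     row.names = FALSE)
  }

  utils::write.csv(measurements, file.path(out_dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
  utils::write.csv(ci, file.path(out_dir, "confidence_intervals.csv"),
                   row.names = FALSE)
  utils::write.csv(inv, file.path(out_dir, "inversions.csv"),
                   row.names = FALSE)
  invisible(list(measurements = measurements, fits = fits, ci = ci,
                 inversions = inv, anova = anova_tabs,
                 latency_test = lat_test, fibers = fibers,
                 fe_field = fe_field))
}
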