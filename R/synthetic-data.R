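#' Default cohort parameter ranges for synthetic rat sciatic specimens
#'
#' Ranges reproduce the measured spread of ex vivo rat sciatic nerves:
#' diameters 1.30-1.53 mm (mean 1.42), gauge lengths 24.7-35.2 mm (mean
#' 28.8), material parameters alpha 0.037-0.31 MPa and beta 0.78-3.40 MPa,
#' and a stretch at 50% CAP reduction centred on 1.108 with between-specimen
#' standard deviation 0.0281 (the spread implied by a 95% confidence
#' half-width of 0.026 at n = 7).
#'
#' @param d0 range of nerve diameter (mm).
#' @param L0 range of gauge length (mm).
#' @param alpha,beta ranges of the material parameters (MPa).
#' @param lambda50_mean,lambda50_sd normal parameters of the stretch at 50%
#'   CAP reduction across specimens.
#' @param width sigmoid width of the reduction curve (stretch units).
#' @param cap_amp0 unstretched CAP amplitude (mV).
#' @param noise_sd trace noise standard deviation (mV).
#' @return a named list of generator settings.
#' @export
cohort_config <- function(d0 = c(1.30, 1.53), L0 = c(24.7, 35.2),
                          alpha = c(0.037, 0.31), beta = c(0.78, 3.40),
                          lambda50_mean = 1.108, lambda50_sd = 0.0281,
                          width = 0.02, cap_amp0 = 1.0, noise_sd = 0.05) {
  rng <- list(d0 = d0, L0 = L0, alpha = alpha, beta = beta)
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (length(r) != 2 || r[1] > r[2])
      stop("invalid range for ", nm, " (low > high)")
  }
  list(d0 = d0, L0 = L0, alpha = alpha, beta = beta,
       lambda50_mean = lambda50_mean, lambda50_sd = lambda50_sd,
       width = width, cap_amp0 = cap_amp0, noise_sd = noise_sd)
}

#' Recording configuration for synthetic CAP traces
#'
#' Defaults mirror the ex vivo recording paradigm: 100 kHz sampling,
#' 0.33 Hz stimulation for 20 s, 2.0-2.2 V stimuli of 40-100 us. The
#' conduction velocity and electrode distance (half the gauge length) only
#' set the synthetic latency; 10 m/s places the CAP peak well clear of the
#' stimulus-artifact window.
#'
#' @param fs sampling rate (Hz).
#' @param stim_rate stimulation rate (Hz).
#' @param record_duration recording length (s).
#' @param stim_amplitude stimulus amplitude (V).
#' @param stim_duration stimulus duration (s).
#' @param artifact_scale stimulus artifact amplitude in the recording (mV).
#' @param conduction_velocity conduction velocity for latency synthesis (m/s).
#' @return a named list of recording settings.
#' @export
recording_config <- function(fs = 1e5, stim_rate = 0.33, record_duration = 20,
                             stim_amplitude = 2.1, stim_duration = 100e-6,
                             artifact_scale = 5, conduction_velocity = 10) {
  if (fs <= 2 * 5000) stop("sampling rate must exceed twice the 5 kHz band edge")
  if (record_duration * stim_rate < 3)
    stop("recording must span at least 3 stimulation cycles")
  list(fs = fs, stim_rate = stim_rate, record_duration = record_duration,
       stim_amplitude = stim_amplitude, stim_duration = stim_duration,
       artifact_scale = artifact_scale,
       conduction_velocity = conduction_velocity)
}

#' Draw one synthetic specimen
#'
#' Samples specimen-level ground truth (geometry, material parameters,
#' reduction-curve parameters) uniformly within the configured ranges;
#' deterministic for a fixed seed. Collapsing a range to a point fixes that
#' parameter exactly.
#'
#' @param config a [cohort_config()] list.
#' @param seed integer RNG seed.
#' @param id specimen label.
#' @param sex,side factor levels recorded in the metadata.
#' @return a `specimen_truth` list: id, sex, side, L0, d0, A0, alpha_true,
#'   beta_true, lambda50_true, width_true, cap_amp0, noise_sd, seed.
#' @export
generate_specimen <- function(config = cohort_config(), seed = 1, id = "S1",
                              sex = c("male", "female"),
                              side = c("left", "right")) {
  sex <- match.arg(sex); side <- match.arg(side)
  set.seed(seed)
  runif2 <- function(r) stats::runif(1, r[1], r[2])
  d0 <- runif2(config$d0)
  L0 <- runif2(config$L0)
  alpha <- runif2(config$alpha)
  beta <- runif2(config$beta)
  lam50 <- stats::rnorm(1, config$lambda50_mean, config$lambda50_sd)
  # reduction midpoint must exceed 1 by construction
  lam50 <- max(lam50, 1 + 10 * config$width / 10)
  structure(list(id = id, sex = sex, side = side, L0 = L0, d0 = d0,
                 A0 = circle_area(d0), alpha_true = alpha, beta_true = beta,
                 lambda50_true = lam50, width_true = config$width,
                 cap_amp0 = config$cap_amp0, noise_sd = config$noise_sd,
                 seed = seed),
            class = "specimen_truth")
}

#' @export
print.specimen_truth <- function(x, ...) {
  cat(sprintf("specimen %s (%s, %s): L0 %.1f mm, d0 %.2f mm, alpha %.3f, beta %.2f MPa, lambda50 %.3f\n",
              x$id, x$sex, x$side, x$L0, x$d0, x$alpha_true, x$beta_true,
              x$lambda50_true))
  invisible(x)
}

#' Ground-truth percent CAP reduction at a given stretch
#'
#' Logistic dose-response in stretch, anchored so that the reduction is 0 at
#' the reference state and exactly 50 at `lambda50_true`:
#' \deqn{R(\lambda) = 100 \frac{s(\lambda) - s(1)}{1 - 2 s(1)}, \quad
#'       s(\lambda) = \frac{1}{1 + e^{-(\lambda - \lambda_{50})/w}}.}
#' Monotone nondecreasing; output is capped just below 100 so the reduction
#' stays in [0, 100) even in the deep tail.
#'
#' @param spec a `specimen_truth` (or any list with `lambda50_true` and
#'   `width_true`).
#' @param lam stretch ratio(s), >= 1.
#' @return percent CAP amplitude reduction.
#' @export
true_reduction <- function(spec, lam) {
  if (any(lam < 1)) stop("stretch ratio must be >= 1")
  s <- function(x) 1 / (1 + exp(-x))
  s1 <- s((1 - spec$lambda50_true) / spec$width_true)
  r <- 100 * (s((lam - spec$lambda50_true) / spec$width_true) - s1) / (1 - 2 * s1)
  pmin(r, 100 * (1 - 1e-12))
}

#' Synthetic force-stretch table
#'
#' Forces follow the specimen's ground-truth constitutive response: the
#' axial force needed to hold stretch lam is
#' \eqn{f = T_{11}(\lambda; \alpha, \beta) A_0 / \lambda}, zero at the
#' reference state, optionally perturbed by multiplicative lognormal noise
#' (mean-one) so forces stay positive.
#'
#' @param spec a `specimen_truth`.
#' @param stretch_levels stretch ratios (>= 1).
#' @param noise_cv coefficient of variation of the lognormal noise (0 = none).
#' @param seed optional RNG seed for the noise.
#' @return data frame with columns `lam`, `force` (N).
#' @export
generate_force_table <- function(spec, stretch_levels = stretch_protocol(),
                                 noise_cv = 0, seed = NULL) {
  if (any(stretch_levels < 1)) stop("stretch ratios must be >= 1")
  f <- model_stress(spec$alpha_true, spec$beta_true, stretch_levels) *
    spec$A0 / stretch_levels
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    fac <- exp(stats::rnorm(length(f), -sdlog^2 / 2, sdlog))
    f <- f * ifelse(stretch_levels > 1, fac, 1)
  }
  data.frame(lam = stretch_levels, force = f)
}

# derive a reproducible 32-bit sub-seed from a master seed and a stream index
.subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(k)) %% 2147483629)
}

#' Standard stretch protocol
#'
#' The tested stretch increments: 1.000 to 1.200 in steps of 0.025.
#' @return numeric vector of 9 stretch ratios.
#' @export
stretch_protocol <- function() seq(1, 1.2, by = 0.025)

# biphasic CAP template on a time axis tau (s since stimulus), unit peak
.cap_template <- function(tau, latency, sigma1 = 2e-4, sigma2 = 3e-4,
                          sep = 5e-4, ratio = 0.7) {
  w <- exp(-0.5 * ((tau - latency) / sigma1)^2) -
    ratio * exp(-0.5 * ((tau - latency - sep) / sigma2)^2)
  mx <- max(w)
  if (mx <= 0) stop("degenerate CAP template")
  w / mx
}

#' Synthetic raw CAP recording at one stretch level
#'
#' Builds a stimulus-locked voltage trace: floor(duration x rate) + 1
#' stimulation epochs starting at t = 0, each holding a rectangular stimulus
#' artifact of the configured duration, a biphasic CAP template (difference
#' of two Gaussians) whose peak sits at latency = (L0/2) / conduction
#' velocity and whose amplitude is scaled by the specimen's ground-truth
#' reduction at this stretch, plus additive white Gaussian noise.
#'
#' @param spec a `specimen_truth`.
#' @param rec a [recording_config()] list.
#' @param lam stretch ratio, >= 1.
#' @param seed RNG seed for the noise.
#' @param noise_sd noise standard deviation (mV); defaults to the specimen's.
#' @return a `cap_trace` object (see [cap_trace()]): time (s), voltage (mV),
#'   sampling rate, stimulus onset times.
#' @export
generate_cap_trace <- function(spec, rec = recording_config(), lam = 1,
                               seed = 1, noise_sd = spec$noise_sd) {
  if (lam < 1) stop("stretch ratio must be >= 1")
  if (rec$stim_duration * rec$fs < 2)
    stop("sampling rate too low to resolve the stimulus duration")
  n <- round(rec$record_duration * rec$fs)
  t <- (seq_len(n) - 1) / rec$fs
  onsets <- (0:floor(rec$record_duration * rec$stim_rate)) / rec$stim_rate
  onsets <- onsets[onsets < rec$record_duration]
  latency <- (spec$L0 / 2 / 1000) / rec$conduction_velocity
  amp <- spec$cap_amp0 * (1 - true_reduction(spec, lam) / 100)
  v <- numeric(n)
  tmpl_span <- latency + 5e-3
  for (on in onsets) {
    idx <- which(t >= on & t <= on + tmpl_span)
    tau <- t[idx] - on
    v[idx] <- v[idx] + amp * .cap_template(tau, latency)
    art <- which(t >= on & t < on + rec$stim_duration)
    v[art] <- v[art] + rec$artifact_scale
  }
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(n, 0, noise_sd)
  }
  cap_trace(t, v, rec$fs, onsets)
}

#' Synthetic collagen fiber-angle sample
#'
#' Draws fiber angles (degrees) from a wrapped normal centred at zero whose
#' standard deviation is set by the target full width at half maximum,
#' \eqn{\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})}. Stretched nerves have a
#' tighter distribution (smaller FWHM) than unstretched controls.
#'
#' @param group `"stretched"` or `"control"`.
#' @param n_fibers number of fibers (>= 10).
#' @param fwhm_target population FWHM in degrees; defaults to 8 for the
#'   stretched group and 14 for controls.
#' @param seed RNG seed.
#' @return numeric vector of angles in (-90, 90].
#' @export
generate_fiber_angles <- function(group = c("control", "stretched"),
                                  n_fibers = 2000, fwhm_target = NULL,
                                  seed = 1) {
  group <- match.arg(group)
  if (n_fibers < 10) stop("need at least 10 fibers")
  if (is.null(fwhm_target))
    fwhm_target <- if (group == "stretched") 8 else 14
  if (fwhm_target <= 0) stop("fwhm_target must be positive")
  set.seed(seed)
  sd <- fwhm_target / (2 * sqrt(2 * log(2)))
  a <- stats::rnorm(n_fibers, 0, sd)
  # wrap into (-90, 90]
  a <- ((a + 90) %% 180) - 90
  a[a == -90] <- 90
  a
}

#' Generate a complete synthetic cohort on disk
#'
#' Writes, for `n` specimens, the file set the analysis pipeline consumes:
#' cohort metadata, per-specimen force-stretch tables, per-stretch raw trace
#' CSVs with stimulus-onset sidecars, and a fiber-angle table with stretched
#' and control groups (three sections per nerve). Stretch trials follow the
#' standard protocol and stop at the first level reaching 50% ground-truth
#' CAP reduction, or at 1.20, whichever comes first.
#'
#' @param n number of stretched specimens.
#' @param seed master RNG seed; per-specimen seeds are derived from it.
#' @param dir output directory (created if needed).
#' @param config a [cohort_config()].
#' @param rec a [recording_config()].
#' @param force_noise_cv multiplicative noise on forces.
#' @param n_fibers_section fibers drawn per histological section.
#' @param write_traces set FALSE to skip the (large) raw trace CSVs; the
#'   specimens and tables are still produced.
#' @return invisibly, a list with the specimen truths and file manifest.
#' @export
simulate_cohort <- function(n = 8, seed = 1, dir, config = cohort_config(),
                            rec = recording_config(), force_noise_cv = 0.02,
                            n_fibers_section = 2000, write_traces = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sexes <- rep(c("male", "female"), length.out = n)
  sides <- rep(c("left", "left", "right", "right"), length.out = n)
  specs <- list()
  meta <- NULL
  angles <- NULL
  for (i in seq_len(n)) {
    sp <- generate_specimen(config, seed = .subseed(seed, i),
                            id = sprintf("S%02d", i),
                            sex = sexes[i], side = sides[i])
    specs[[i]] <- sp
    meta <- rbind(meta, data.frame(id = sp$id, sex = sp$sex, side = sp$side,
                                   L0_mm = sp$L0, d0_mm = sp$d0))
    levels <- stretch_protocol()
    red <- true_reduction(sp, levels)
    term <- which(red >= 50)[1]
    if (!is.na(term)) levels <- levels[seq_len(term)]
    ft <- generate_force_table(sp, levels, noise_cv = force_noise_cv,
                               seed = .subseed(seed, 500 + i))
    utils::write.csv(ft, file.path(dir, sprintf("force_%s.csv", sp$id)),
                     row.names = FALSE)
    if (write_traces) {
      for (j in seq_along(levels)) {
        tr <- generate_cap_trace(sp, rec, levels[j],
                                 seed = .subseed(seed, 10000 + i * 100 + j))
        base <- sprintf("trace_%s_%05.3f", sp$id, levels[j])
        utils::write.csv(data.frame(time_s = tr$t, voltage_mV = tr$v),
                         file.path(dir, paste0(base, ".csv")),
                         row.names = FALSE)
        utils::write.csv(data.frame(onset_s = tr$stim_onsets),
                         file.path(dir, paste0(base, "_stims.csv")),
                         row.names = FALSE)
      }
    }
    for (grp in c("stretched", "control")) {
      fw_mu <- if (grp == "stretched") 8 else 14
      set.seed(.subseed(seed, 20000 + i * 7 + match(grp, c("stretched", "control"))))
      fw <- stats::rnorm(1, fw_mu, 1)  # between-specimen spread of FWHM
      for (sec in 1:3) {
        a <- generate_fiber_angles(grp, n_fibers_section, fwhm_target = fw,
                                   seed = .subseed(seed, 30000 + i * 100 +
                                     match(grp, c("stretched", "control")) * 10 + sec))
        angles <- rbind(angles, data.frame(
          specimen_id = sp$id, group = grp, section = sec, angle_deg = a))
      }
    }
  }
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(angles, file.path(dir, "fiber_angles.csv"),
                   row.names = FALSE)
  invisible(list(specimens = specs, dir = dir))
}
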