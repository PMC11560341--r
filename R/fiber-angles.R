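#' Normalize fiber angles to zero mean per section
#'
#' Subtracts each histological section's arithmetic mean angle (fibers run
#' close to the nerve axis, so angles live in (-90, 90] and no circular
#' wrapping is needed), then pools the sections.
#'
#' @param angles numeric vector of fiber angles (degrees).
#' @param sections section label per angle (default: one section).
#' @param specimen_id,group metadata carried along.
#' @return a `fiber_angle_set`: normalized pooled `angles`, `sections`,
#'   `specimen_id`, `group`.
#' @export
normalize_angles <- function(angles, sections = NULL,
                             specimen_id = NA_character_,
                             group = NA_character_) {
  if (!length(angles)) stop("no angles supplied")
  if (is.null(sections)) sections <- rep(1L, length(angles))
  if (length(sections) != length(angles))
    stop("sections must align with angles")
  if (any(tabulate(factor(sections)) == 0) || anyNA(angles))
    stop("empty section or missing angle")
  centered <- stats::ave(angles, sections, FUN = function(a) a - mean(a))
  structure(list(angles = centered, sections = sections,
                 specimen_id = specimen_id, group = group),
            class = "fiber_angle_set")
}

#' @export
print.fiber_angle_set <- function(x, ...) {
  cat(sprintf("fiber angles%s: %d fibers in %d section(s), sd %.2f deg\n",
              if (is.na(x$specimen_id)) "" else paste0(" (", x$specimen_id, ")"),
              length(x$angles), length(unique(x$sections)),
              stats::sd(x$angles)))
  invisible(x)
}

#' 1-degree fiber-angle histogram
#'
#' Bins the normalized angles into 1-degree half-open bins [a, a+1) covering
#' the data range (angles exactly on an interior edge count toward the upper
#' bin) and expresses counts as percentages of fibers.
#'
#' @param set a `fiber_angle_set` (or plain numeric vector, >= 10 angles).
#' @return an `angle_histogram`: `bin_edges`, `bin_centers`, `pct`
#'   (sums to 100).
#' @export
bin_histogram <- function(set) {
  a <- if (inherits(set, "fiber_angle_set")) set$angles else set
  if (length(a) < 10) stop("need at least 10 angles to bin")
  edges <- seq(floor(min(a)), ceiling(max(a)) + 1)
  # half-open [e, e+1): right=FALSE puts edge values in the upper bin
  cnt <- hist(a, breaks = edges, right = FALSE, plot = FALSE)$counts
  structure(list(bin_edges = edges, bin_centers = edges[-length(edges)] + 0.5,
                 pct = 100 * cnt / length(a)),
            class = "angle_histogram")
}

#' @export
print.angle_histogram <- function(x, ...) {
  cat(sprintf("angle histogram: %d one-degree bins on [%d, %d), peak %.2f%%\n",
              length(x$pct), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], max(x$pct)))
  invisible(x)
}

#' Full width at half maximum of an angle histogram
#'
#' Half-max is half the peak bin percentage. The left and right crossings
#' are located by walking outward from the peak bin to the first bin below
#' half-max on each side and linearly interpolating between bin centers;
#' ties for the peak are broken by the most central bin. The FWHM is the
#' distance between the crossings in degrees.
#'
#' @param hist an `angle_histogram`.
#' @return FWHM in degrees.
#' @export
fwhm <- function(hist) {
  p <- hist$pct
  ctr <- hist$bin_centers
  pk <- which(p == max(p))
  if (length(pk) > 1) pk <- pk[which.min(abs(ctr[pk]))]
  half <- max(p) / 2
  cross <- function(side) {
    idx <- if (side == "left") rev(seq_len(pk - 1)) else
      seq.int(pk + 1, length.out = max(length(p) - pk, 0))
    prev <- pk
    for (i in idx) {
      if (p[i] < half) {
        # linear interpolation between bin centers prev (>= half) and i (< half)
        return(ctr[prev] + (ctr[i] - ctr[prev]) * (p[prev] - half) /
                 (p[prev] - p[i]))
      }
      prev <- i
    }
    stop(sprintf("distribution never falls below half-max on the %s side",
                 side))
  }
  cross("right") - cross("left")
}

#' Tukey-fence outlier mask
#'
#' Flags values outside [Q1 - 1.5 IQR, Q3 + 1.5 IQR], with quartiles by
#' linear interpolation of order statistics (R's default type-7 quantile
#' convention; alternatives selectable).
#'
#' @param values numeric vector, n >= 4.
#' @param k fence multiplier (default 1.5).
#' @param type quantile convention passed to [stats::quantile()].
#' @return logical inclusion mask (TRUE = keep).
#' @export
iqr_outliers <- function(values, k = 1.5, type = 7) {
  if (length(values) < 4) stop("need at least 4 values for Tukey fences")
  q <- stats::quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  values >= q[1] - k * iqr & values <= q[2] + k * iqr
}

#' Compare FWHM between stretched and control groups
#'
#' Two-sided F-test on the group variances decides the t-test variant: a
#' pooled-variance Student t when the variances are compatible (F-test p >=
#' 0.05), Welch's unequal-variance t otherwise. Both groups constant with
#' zero variance is a degenerate input (F undefined).
#'
#' @param fwhm_a,fwhm_b per-specimen FWHM values (degrees), each n >= 2.
#' @param var_alpha F-test significance level switching to Welch.
#' @return list: `F_stat`, `F_p`, `t_stat`, `t_p`, `variant`
#'   (`"pooled"` or `"welch"`), `df`.
#' @export
compare_groups <- function(fwhm_a, fwhm_b, var_alpha = 0.05) {
  if (length(fwhm_a) < 2 || length(fwhm_b) < 2)
    stop("each group needs at least 2 values")
  if (stats::sd(fwhm_a) == 0 && stats::sd(fwhm_b) == 0)
    stop("both groups have zero variance: F-test undefined")
  ft <- stats::var.test(fwhm_a, fwhm_b)
  pooled <- ft$p.value >= var_alpha
  tt <- stats::t.test(fwhm_a, fwhm_b, var.equal = pooled)
  list(F_stat = unname(ft$statistic), F_p = ft$p.value,
       t_stat = unname(tt$statistic), t_p = tt$p.value,
       variant = if (pooled) "pooled" else "welch",
       df = unname(tt$parameter))
}

#' Per-specimen fiber-angle analysis of a cohort table
#'
#' Normalizes angles per section, pools sections within each specimen, bins
#' into 1-degree histograms and measures FWHM; then applies the Tukey fence
#' within each group and compares groups.
#'
#' @param angle_table data frame with columns `specimen_id`, `group`
#'   (`"stretched"`/`"control"`), `section`, `angle_deg`.
#' @return list: `per_specimen` (data frame id, group, fwhm, kept),
#'   `comparison` (see [compare_groups()], computed on the kept values).
#' @export
analyze_fiber_cohort <- function(angle_table) {
  ids <- unique(angle_table[c("specimen_id", "group")])
  res <- do.call(rbind, lapply(seq_len(nrow(ids)), function(i) {
    sel <- angle_table$specimen_id == ids$specimen_id[i] &
      angle_table$group == ids$group[i]
    fas <- normalize_angles(angle_table$angle_deg[sel],
                            angle_table$section[sel],
                            ids$specimen_id[i], ids$group[i])
    data.frame(specimen_id = ids$specimen_id[i], group = ids$group[i],
               fwhm = fwhm(bin_histogram(fas)))
  }))
  res$kept <- TRUE
  for (g in unique(res$group)) {
    sel <- res$group == g
    if (sum(sel) >= 4) res$kept[sel] <- iqr_outliers(res$fwhm[sel])
  }
  keep <- res[res$kept, ]
  cmp <- compare_groups(keep$fwhm[keep$group == "stretched"],
                        keep$fwhm[keep$group == "control"])
  list(per_specimen = res, comparison = cmp)
}
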