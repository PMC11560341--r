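#' Stimulus-locked CAP recording container
#'
#' @param t time vector (s), uniformly sampled.
#' @param v voltage vector (mV), same length as `t`.
#' @param fs sampling rate (Hz); must match the time step to 1e-9 relative.
#' @param stim_onsets stimulus onset times (s), all within the record.
#' @return a `cap_trace` object.
#' @export
cap_trace <- function(t, v, fs = NULL, stim_onsets = numeric(0)) {
  if (length(t) != length(v)) stop("time and voltage lengths differ")
  if (length(t) < 2) stop("trace needs at least 2 samples")
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("time axis must be uniform")
  if (is.null(fs)) fs <- 1 / dt[1]
  if (abs(fs - 1 / dt[1]) > 1e-9 * fs)
    stop("fs inconsistent with the time step")
  if (length(stim_onsets) &&
      (min(stim_onsets) < t[1] || max(stim_onsets) > t[length(t)]))
    stop("stimulus onsets outside the recorded interval")
  structure(list(t = t, v = v, fs = fs, stim_onsets = sort(stim_onsets)),
            class = "cap_trace")
}

#' @export
print.cap_trace <- function(x, ...) {
  cat(sprintf("CAP trace: %.3f s at %g Hz (%d samples), %d stimuli\n",
              x$t[length(x$t)] - x$t[1], x$fs, length(x$t),
              length(x$stim_onsets)))
  invisible(x)
}

#' Read a trace CSV plus its stimulus-onset sidecar
#'
#' @param trace_file CSV with columns time_s, voltage_mV (or voltage_V,
#'   converted to mV).
#' @param stim_file CSV with a column onset_s.
#' @return a [cap_trace()].
#' @export
read_cap_trace <- function(trace_file, stim_file) {
  d <- utils::read.csv(trace_file)
  v <- if ("voltage_mV" %in% names(d)) d$voltage_mV else d$voltage_V * 1000
  s <- utils::read.csv(stim_file)
  cap_trace(d$time_s, v, stim_onsets = s$onset_s)
}

#' Digital preprocessing of a raw CAP recording
#'
#' Four stages, applied in order and each optional: gating of the stimulus
#' artifact, where samples in a short window after each onset are replaced
#' by linear interpolation across the window so the large fast artifact
#' cannot ring through the subsequent filter; a zero-phase
#' (forward-backward) 4th-order Butterworth band-pass in the 100-5000 Hz
#' band; per-sweep baseline subtraction, where the mean over a window
#' immediately preceding each stimulus onset is removed from that sweep; and
#' a running median over a short sliding window (100 us by default, rounded
#' up to an odd sample count) to suppress impulsive spikes. Trace length and
#' sampling rate are preserved.
#'
#' @param trace a [cap_trace()].
#' @param band band-pass edges in Hz, `c(low, high)` with
#'   0 < low < high < fs/2, or NULL to skip filtering.
#' @param baseline_window seconds of pre-stimulus data averaged for the
#'   baseline (default 5 ms); NULL skips baseline subtraction. A stimulus too
#'   close to the start of the record gets a truncated window with a warning
#'   (baseline 0 if no samples precede it).
#' @param median_window width of the running median (s); NULL skips it.
#' @param artifact_gate seconds after each stimulus onset to bridge by
#'   linear interpolation before filtering (default 0.5 ms, matching the
#'   peak-search blanking window of [measure_cap()]); NULL skips gating.
#' @param order Butterworth order.
#' @return a filtered [cap_trace()].
#' @export
preprocess <- function(trace, band = c(100, 5000), baseline_window = 5e-3,
                       median_window = 100e-6, artifact_gate = 0.5e-3,
                       order = 4) {
  v <- trace$v
  fs <- trace$fs
  if (!is.null(artifact_gate) && length(trace$stim_onsets)) {
    for (on in trace$stim_onsets) {
      idx <- which(trace$t >= on & trace$t <= on + artifact_gate)
      if (length(idx) < 2) next
      lo <- min(idx) - 1L
      hi <- min(max(idx) + 1L, length(v))
      # anchor on clean samples outside the gate; a stimulus at the very
      # start of the record has no pre-onset sample, so bridge flat
      vlo <- if (lo >= 1L) v[lo] else v[hi]
      v[idx] <- vlo + (v[hi] - vlo) * (idx - lo) / (hi - lo)
    }
  }
  if (!is.null(band)) {
    if (band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2)
      stop("band edges must satisfy 0 < low < high < fs/2")
    bf <- signal::butter(order, band / (fs / 2), type = "pass")
    v <- signal::filtfilt(bf, v)
  }
  if (!is.null(baseline_window) && length(trace$stim_onsets)) {
    ons <- trace$stim_onsets
    nb <- round(baseline_window * fs)
    if (nb < 1) stop("baseline window shorter than one sample")
    i_on <- vapply(ons, function(on) which.min(abs(trace$t - on)), integer(1))
    # partition the record at the start of each baseline window, so every
    # sample belongs to exactly one sweep and gets that sweep's baseline
    seg0 <- pmax(i_on - nb, 1L)
    if (any(i_on - nb < 1))
      warning("stimulus too close to trace start; baseline window truncated")
    seg0[1] <- 1L
    seg_end <- c(seg0[-1] - 1L, length(v))
    for (k in seq_along(ons)) {
      pre <- if (i_on[k] > 1L) seq.int(max(i_on[k] - nb, 1L), i_on[k] - 1L)
             else integer(0)
      bl <- if (length(pre)) mean(v[pre]) else 0
      v[seg0[k]:seg_end[k]] <- v[seg0[k]:seg_end[k]] - bl
    }
  }
  if (!is.null(median_window)) {
    k <- round(median_window * fs)
    if (k < 1) stop("median window shorter than one sample")
    if (k %% 2 == 0) k <- k + 1
    if (k > 1) v <- stats::runmed(v, k, endrule = "keep")
  }
  cap_trace(trace$t, as.numeric(v), fs, trace$stim_onsets)
}

#' Stimulus-locked epoch extraction and averaging
#'
#' Cuts the trace into epochs aligned on each stimulus onset, truncates them
#' to a common length, and averages pointwise.
#'
#' @param trace a [cap_trace()] with at least one stimulus onset.
#' @param epoch_window epoch length (s); defaults to the shortest
#'   inter-stimulus interval (or the remaining record for a single stimulus).
#' @return a data frame with columns `tau` (s since stimulus) and `v` (mV),
#'   plus attribute `n_sweeps`.
#' @export
extract_and_average <- function(trace, epoch_window = NULL) {
  ons <- trace$stim_onsets
  if (!length(ons)) stop("no stimulus onsets: nothing to average")
  t_end <- trace$t[length(trace$t)]
  if (is.null(epoch_window)) {
    gaps <- diff(c(ons, t_end + 1 / trace$fs))
    epoch_window <- min(gaps)
  }
  n_ep <- round(epoch_window * trace$fs)
  idx0 <- vapply(ons, function(on) which.min(abs(trace$t - on)), integer(1))
  keep <- idx0 + n_ep - 1 <= length(trace$t)
  if (!any(keep)) stop("no complete epoch fits in the record")
  idx0 <- idx0[keep]
  m <- vapply(idx0, function(i) trace$v[i:(i + n_ep - 1)], numeric(n_ep))
  avg <- rowMeans(m)
  out <- data.frame(tau = (seq_len(n_ep) - 1) / trace$fs, v = avg)
  attr(out, "n_sweeps") <- length(idx0)
  out
}

#' Measure amplitude and latency of an averaged CAP waveform
#'
#' The CAP peak is the largest (signed) deflection after an artifact
#' blanking window that excludes the stimulus artifact from the search.
#' Amplitude is peak minus baseline; the baseline is re-estimated from any
#' pre-stimulus samples (tau < 0) and taken as 0 for waveforms that start at
#' the stimulus, as produced by [extract_and_average()] on
#' baseline-subtracted traces. Latency is the stimulus-to-peak delay.
#'
#' @param avg_waveform data frame with columns `tau` (s) and `v` (mV).
#' @param artifact_blank blanking window after the stimulus (s) excluded
#'   from the peak search; default 0.5 ms.
#' @param polarity +1 to pick the positive peak (default), -1 for inverted
#'   montages.
#' @return a `cap_measurement` list: `amplitude` (mV, >= 0 clipped at the
#'   baseline), `latency` (ms), `baseline` (mV), `peak_time` (s),
#'   `n_sweeps`.
#' @export
measure_cap <- function(avg_waveform, artifact_blank = 0.5e-3, polarity = 1) {
  tau <- avg_waveform$tau
  v <- avg_waveform$v * polarity
  if (max(tau) < artifact_blank + 1e-3)
    stop("waveform must extend at least 1 ms beyond the blanking window")
  search <- which(tau > artifact_blank)
  vs <- v[search]
  if (!length(vs) || all(is.na(vs))) stop("empty or all-NA peak search window")
  pre <- which(tau < 0)
  baseline <- if (length(pre)) mean(v[pre]) else 0
  ipk <- search[which.max(vs)]
  amp <- max(v[ipk] - baseline, 0)
  structure(list(amplitude = amp, latency = tau[ipk] * 1000,
                 baseline = baseline, peak_time = tau[ipk],
                 n_sweeps = attr(avg_waveform, "n_sweeps") %||% 1L),
            class = "cap_measurement")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cap_measurement <- function(x, ...) {
  cat(sprintf("CAP: amplitude %.4g mV, latency %.3f ms (%d sweeps)\n",
              x$amplitude, x$latency, x$n_sweeps))
  invisible(x)
}

#' Percent CAP amplitude reduction relative to the unstretched recording
#'
#' \deqn{R_n = \frac{C_{1.00} - C_n}{C_{1.00}} \times 100\%.}
#' A value above the reference (amplitude increase) yields a negative
#' reduction and is passed through unclamped.
#'
#' @param c_ref unstretched CAP amplitude (mV), > 0.
#' @param c_n CAP amplitude at stretch n (mV), >= 0.
#' @return percent reduction.
#' @examples
#' cap_reduction(2, 1)   # 50
#' @export
cap_reduction <- function(c_ref, c_n) {
  if (any(c_ref <= 0)) stop("reference amplitude must be positive")
  if (any(c_n < 0)) stop("amplitudes must be non-negative")
  (c_ref - c_n) / c_ref * 100
}

#' Compare CAP latencies between unstretched and terminal trials
#'
#' Two-sample pooled-variance (Student) t-test, two-sided. Identical
#' constant groups (zero variance, equal means) return t = 0, p = 1 by
#' convention.
#'
#' @param lat_unstretched,lat_final latency samples (ms), each length >= 2.
#' @return list with `t`, `p`, `df`.
#' @export
compare_latencies <- function(lat_unstretched, lat_final) {
  if (length(lat_unstretched) < 2 || length(lat_final) < 2)
    stop("each latency group needs at least 2 values")
  if (stats::sd(lat_unstretched) == 0 && stats::sd(lat_final) == 0) {
    if (mean(lat_unstretched) == mean(lat_final))
      return(list(t = 0, p = 1,
                  df = length(lat_unstretched) + length(lat_final) - 2))
    return(list(t = Inf * sign(mean(lat_unstretched) - mean(lat_final)),
                p = 0, df = length(lat_unstretched) + length(lat_final) - 2))
  }
  tt <- stats::t.test(lat_unstretched, lat_final, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Full per-recording measurement: preprocess, average, measure
#'
#' Convenience wrapper running the standard signal chain on one raw trace.
#'
#' @param trace a [cap_trace()].
#' @param band,baseline_window,median_window see [preprocess()].
#' @param artifact_blank,polarity see [measure_cap()].
#' @return a `cap_measurement`.
#' @export
process_recording <- function(trace, band = c(100, 5000),
                              baseline_window = 5e-3, median_window = 100e-6,
                              artifact_blank = 0.5e-3, polarity = 1) {
  pp <- preprocess(trace, band, baseline_window, median_window,
                   artifact_gate = artifact_blank)
  avg <- extract_and_average(pp)
  measure_cap(avg, artifact_blank, polarity)
}
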