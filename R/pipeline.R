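#' Analysis window configuration
#'
#' @param baseline_window_s Absolute interval used for the pre-exposure
#'   baseline (s); default the first 20 s of the run.
#' @param analysis_window_s Interval relative to sample application over
#'   which the windowed slope is fit (s); default 60-450 s, chosen to skip
#'   the droplet-spreading transient and capture the steady penetration
#'   phase.
#' @param plateau_slope_tol_fF_per_s Moving-slope threshold below which the
#'   response counts as quasi-equilibrated (fF/s).
#' @param plateau_min_span_s Minimum span the slope must stay below the
#'   threshold (s).
#' @return A list of class `analysis_windows`.
#' @export
analysis_windows <- function(baseline_window_s = c(0, 20),
                             analysis_window_s = c(60, 450),
                             plateau_slope_tol_fF_per_s = 0.05,
                             plateau_min_span_s = 60) {
  stopifnot(length(baseline_window_s) == 2, diff(baseline_window_s) > 0,
            length(analysis_window_s) == 2, diff(analysis_window_s) > 0,
            plateau_slope_tol_fF_per_s > 0, plateau_min_span_s > 0)
  structure(
    list(baseline_window_s = baseline_window_s,
         analysis_window_s = analysis_window_s,
         plateau_slope_tol_fF_per_s = plateau_slope_tol_fF_per_s,
         plateau_min_span_s = plateau_min_span_s),
    class = "analysis_windows"
  )
}

trace_dt <- function(trace) {
  if (nrow(trace) < 2) {
    abort("Trace needs at least two samples.", class = "irritrace_window_error")
  }
  trace$time_s[2] - trace$time_s[1]
}

window_idx <- function(trace, window, min_n, what) {
  idx <- which(trace$time_s >= window[1] & trace$time_s <= window[2])
  if (length(idx) < min_n) {
    abort(sprintf("%s window [%g, %g] s holds %d samples; need at least %d.",
                  what, window[1], window[2], length(idx), min_n),
          class = "irritrace_window_error")
  }
  idx
}

#' Pre-exposure baseline level
#'
#' Mean capacitance over the baseline window, with its standard deviation.
#'
#' @param trace A trace tibble.
#' @param windows An [analysis_windows()].
#' @return One-row tibble: `baseline_fF`, `sd_fF`, `n`.
#' @export
estimate_baseline <- function(trace, windows = analysis_windows()) {
  idx <- window_idx(trace, windows$baseline_window_s, 10, "Baseline")
  y <- trace$capacitance_fF[idx]
  tibble::tibble(baseline_fF = mean(y), sd_fF = sd(y), n = length(y))
}

#' Subtract an air-exposure reference from a trace
#'
#' Pointwise difference against a matched reference trace on the common time
#' grid, or subtraction of a scalar baseline.
#'
#' @param trace A trace tibble.
#' @param reference A reference trace covering the same time span, or a
#'   single number.
#' @return Tibble with `time_s` and `delta_C_fF`.
#' @export
subtract_reference <- function(trace, reference) {
  if (is.numeric(reference) && length(reference) == 1) {
    return(tibble::tibble(time_s = trace$time_s,
                          delta_C_fF = trace$capacitance_fF - reference))
  }
  stopifnot(is.data.frame(reference))
  n <- min(nrow(trace), nrow(reference))
  if (abs(nrow(trace) - nrow(reference)) > 1 ||
      max(abs(trace$time_s[seq_len(n)] - reference$time_s[seq_len(n)])) >
        0.5 * trace_dt(trace)) {
    abort("Reference grid does not align with the trace (offset beyond one sample).",
          class = "irritrace_alignment_error")
  }
  tibble::tibble(
    time_s = trace$time_s[seq_len(n)],
    delta_C_fF = trace$capacitance_fF[seq_len(n)] - reference$capacitance_fF[seq_len(n)]
  )
}

# Rolling OLS slope over windows of w samples; returns one slope per window
# start position (length n - w + 1). Uniform grid assumed.
rolling_slope <- function(y, dt, w) {
  n <- length(y)
  stopifnot(w >= 2, w <= n)
  cc <- (seq_len(w) - 1) - (w - 1) / 2
  denom <- dt * sum(cc^2)
  num <- stats::filter(y, rev(cc), method = "convolution", sides = 1)
  as.numeric(num[w:n]) / denom
}

#' Windowed least-squares slope (the canonical dC/dt estimator)
#'
#' Ordinary-least-squares slope of capacitance against time over the
#' analysis window shifted to the application time, reported with its
#' standard error.
#'
#' @param trace A trace tibble.
#' @param windows An [analysis_windows()].
#' @param t_apply_s Application time of the test substance (s).
#' @return One-row tibble: `rate_fF_per_s`, `se_fF_per_s`, `n`.
#' @export
rate_windowed <- function(trace, windows = analysis_windows(), t_apply_s = 0) {
  win <- windows$analysis_window_s + t_apply_s
  if (win[2] > max(trace$time_s) + 1e-9) {
    abort(sprintf("Analysis window [%g, %g] s extends beyond the trace (ends %g s).",
                  win[1], win[2], max(trace$time_s)),
          class = "irritrace_window_error")
  }
  idx <- window_idx(trace, win, 50, "Analysis")
  t <- trace$time_s[idx]
  y <- trace$capacitance_fF[idx]
  tc <- t - mean(t)
  sxx <- sum(tc^2)
  slope <- sum(tc * y) / sxx
  res <- y - mean(y) - slope * tc
  se <- sqrt(sum(res^2) / (length(y) - 2) / sxx)
  tibble::tibble(rate_fF_per_s = slope, se_fF_per_s = se, n = length(y))
}

#' Maximum smoothed rate of change
#'
#' Maximum over time of the moving-window least-squares slope (window length
#' `smooth_span_s`) evaluated on windows that open at or after the
#' application time.
#'
#' @param trace A trace tibble.
#' @param t_apply_s Application time (s).
#' @param smooth_span_s Length of the moving slope window (s); must be at
#'   least 10 sampling intervals.
#' @return One-row tibble: `rate_max_fF_per_s`, `t_at_max_s`.
#' @export
rate_max <- function(trace, t_apply_s = 0, smooth_span_s = 30) {
  dt <- trace_dt(trace)
  if (smooth_span_s < 10 * dt) {
    abort("`smooth_span_s` must be at least 10 sampling intervals.",
          class = "irritrace_window_error")
  }
  w <- round(smooth_span_s / dt) + 1
  post <- which(trace$time_s >= t_apply_s)
  if (length(post) < w) {
    abort("Post-application segment is shorter than the smoothing span.",
          class = "irritrace_window_error")
  }
  y <- trace$capacitance_fF[post]
  s <- rolling_slope(y, dt, w)
  i <- which.max(s)
  tibble::tibble(rate_max_fF_per_s = s[i],
                 t_at_max_s = trace$time_s[post[1]] + (i - 1) * dt)
}

#' Detect the stable capacitance plateau
#'
#' Earliest time at or after application where the moving-window slope
#' (window length `plateau_min_span_s`) drops below the tolerance; the
#' plateau value is the mean over that span. Absence (a monotone ramp that
#' never settles) is reported as `NA`, not an error.
#'
#' @param trace A trace tibble.
#' @param windows An [analysis_windows()].
#' @param t_apply_s Application time (s).
#' @return One-row tibble: `plateau_fF`, `plateau_t_s` (both `NA` if no
#'   quasi-equilibrium is reached).
#' @export
detect_plateau <- function(trace, windows = analysis_windows(), t_apply_s = 0) {
  dt <- trace_dt(trace)
  w <- round(windows$plateau_min_span_s / dt) + 1
  post <- which(trace$time_s >= t_apply_s)
  absent <- tibble::tibble(plateau_fF = NA_real_, plateau_t_s = NA_real_)
  if (length(post) < w) return(absent)
  y <- trace$capacitance_fF[post]
  s <- rolling_slope(y, dt, w)
  ok <- which(abs(s) < windows$plateau_slope_tol_fF_per_s)
  if (!length(ok)) return(absent)
  j <- ok[1]
  tibble::tibble(plateau_fF = mean(y[j:(j + w - 1)]),
                 plateau_t_s = trace$time_s[post[1]] + (j - 1) * dt)
}

#' Baseline RMS noise
#'
#' Root-mean-square of the residuals over a stimulus-free window after mean
#' removal (default) or linear detrending.
#'
#' @param trace A trace tibble.
#' @param window Absolute interval (s).
#' @param detrend `"mean"` (default) or `"linear"`.
#' @return RMS noise in fF.
#' @export
rms_noise <- function(trace, window = c(0, 600), detrend = c("mean", "linear")) {
  detrend <- match.arg(detrend)
  idx <- window_idx(trace, window, 100, "Noise")
  y <- trace$capacitance_fF[idx]
  res <- if (detrend == "mean") {
    y - mean(y)
  } else {
    stats::residuals(lm(y ~ trace$time_s[idx]))
  }
  sqrt(mean(res^2))
}

#' Temperature-drift coefficient
#'
#' Least-squares slope of capacitance against temperature over a
#' stimulus-free segment.
#'
#' @param trace A trace tibble with a `temperature_C` column.
#' @param window Optional absolute interval (s); default the whole trace.
#' @return Drift in fF/degC.
#' @export
drift_coefficient <- function(trace, window = NULL) {
  if (!"temperature_C" %in% names(trace)) {
    abort("Trace carries no temperature series.", class = "irritrace_undefined_drift")
  }
  idx <- if (is.null(window)) seq_len(nrow(trace)) else {
    window_idx(trace, window, 10, "Drift")
  }
  temp <- trace$temperature_C[idx]
  if (sd(temp) == 0) {
    abort("Temperature is constant; the drift coefficient is undefined.",
          class = "irritrace_undefined_drift")
  }
  unname(coef(lm(trace$capacitance_fF[idx] ~ temp))[2])
}

# Resolve the sample application time: the trace's own annotation first,
# then the protocol's final apply event (the assay sequence is blank then
# sample), then a change-point fallback (start of the steepest moving-window
# slope), flagged in the output.
resolve_t_apply <- function(trace, protocol = NULL) {
  t_meta <- trace_meta(trace)$t_apply_s
  if (!is.null(t_meta) && is.finite(t_meta)) {
    return(list(t_apply_s = t_meta, source = "metadata"))
  }
  if (!is.null(protocol)) {
    ev <- protocol$events
    hit <- which(ev$kind == "apply")
    if (length(hit)) {
      return(list(t_apply_s = ev$t_s[utils::tail(hit, 1)], source = "protocol"))
    }
  }
  dt <- trace_dt(trace)
  w <- max(round(10 / dt) + 1, 11)
  s <- rolling_slope(trace$capacitance_fF, dt, w)
  list(t_apply_s = trace$time_s[which.max(s)], source = "changepoint")
}

#' Full per-trace response metrics
#'
#' Composes the pipeline: baseline, end-of-window capacitance change,
#' windowed and maximum-rate slopes, plateau, baseline RMS noise and (when a
#' temperature series is present and non-constant) the drift coefficient.
#'
#' @param trace A trace tibble.
#' @param windows An [analysis_windows()].
#' @param protocol Optional [exposure_protocol()] identifying the sample
#'   application; otherwise trace metadata or a change-point fallback is
#'   used (flagged in `t_apply_source`).
#' @param smooth_span_s Smoothing span for the maximum-rate estimator (s).
#' @return One-row tibble of response metrics.
#' @export
analyze_trace <- function(trace, windows = analysis_windows(), protocol = NULL,
                          smooth_span_s = 30) {
  ta <- resolve_t_apply(trace, protocol)
  base <- estimate_baseline(trace, windows)
  rate <- rate_windowed(trace, windows, ta$t_apply_s)
  rmax <- rate_max(trace, ta$t_apply_s, smooth_span_s)
  plat <- detect_plateau(trace, windows, ta$t_apply_s)
  win_end <- ta$t_apply_s + windows$analysis_window_s[2]
  tail_idx <- which(trace$time_s > win_end - 1 & trace$time_s <= win_end)
  delta_C <- mean(trace$capacitance_fF[tail_idx]) - base$baseline_fF
  noise <- rms_noise(trace, windows$baseline_window_s)
  has_temp <- "temperature_C" %in% names(trace)
  drift <- if (has_temp && sd(trace$temperature_C) > 0) {
    drift_coefficient(trace)
  } else NA_real_
  tibble::tibble(
    baseline_fF = base$baseline_fF,
    baseline_sd_fF = base$sd_fF,
    delta_C_fF = delta_C,
    rate_window_fF_per_s = rate$rate_fF_per_s,
    rate_window_se = rate$se_fF_per_s,
    rate_max_fF_per_s = rmax$rate_max_fF_per_s,
    plateau_fF = plat$plateau_fF,
    plateau_t_s = plat$plateau_t_s,
    rms_noise_fF = noise,
    drift_fF_per_degC = drift,
    t_apply_s = ta$t_apply_s,
    t_apply_source = ta$source
  )
}

#' Analyze every trace of a batch
#'
#' @param batch Nested tibble with a `trace` list column (see
#'   [generate_batch()]).
#' @inheritParams analyze_trace
#' @return The batch tibble with the per-trace metrics columns appended.
#' @export
analyze_batch <- function(batch, windows = analysis_windows(), protocol = NULL,
                          smooth_span_s = 30) {
  metrics <- purrr::map(batch$trace, analyze_trace, windows = windows,
                        protocol = protocol, smooth_span_s = smooth_span_s)
  dplyr::bind_cols(batch, dplyr::bind_rows(metrics))
}
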