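#' Run the full irritation assay on a set of traces
#'
#' For each trace: blank QC on the PBS segment, then the response metrics;
#' per substance: replicate rates (QC-passing traces only), the mean-rate
#' classification against the cutoff, and the group comparison against the
#' negative control; reproducibility CVs when device/day metadata allow.
#' Traces failing blank QC are flagged and excluded from group statistics; a
#' substance whose replicates all fail QC is reported unevaluable, never
#' silently dropped.
#'
#' @param traces Nested tibble with columns `substance` and `trace` (list of
#'   trace tibbles), e.g. from [generate_panel()] or [generate_batch()];
#'   optional `device_id`, `day_id`, `rep_id` columns enable the
#'   reproducibility section.
#' @param protocol The [exposure_protocol()] the traces follow.
#' @param config A [classification_config()].
#' @param windows An [analysis_windows()].
#' @return An object of class `irritation_report`: list with `per_trace`,
#'   `results`, `comparisons`, `reproducibility`, `config`.
#' @export
assay_run <- function(traces, protocol, config = classification_config(),
                      windows = analysis_windows()) {
  stopifnot(is.data.frame(traces), all(c("substance", "trace") %in% names(traces)))
  col_or <- function(nm, i, default) {
    if (nm %in% names(traces)) traces[[nm]][i] else default
  }
  per_trace <- purrr::map(seq_len(nrow(traces)), function(i) {
    tr <- traces$trace[[i]]
    qc <- blank_qc(tr, protocol, config)
    met <- analyze_trace(tr, windows, protocol)
    dplyr::bind_cols(
      tibble::tibble(substance = traces$substance[i],
                     device_id = col_or("device_id", i, 1L),
                     day_id = col_or("day_id", i, 1L),
                     rep_id = col_or("rep_id", i, i),
                     qc_pass = qc$pass,
                     qc_slope_fF_per_s = qc$slope_fF_per_s),
      met
    )
  })
  per_trace <- dplyr::bind_rows(per_trace)
  per_trace$rate_fF_per_s <- if (config$estimator == "windowed") {
    per_trace$rate_window_fF_per_s
  } else {
    per_trace$rate_max_fF_per_s
  }
  per_trace$status <- ifelse(per_trace$qc_pass, "included", "flagged")

  results <- dplyr::summarise(
    dplyr::group_by(per_trace, .data$substance),
    n_total = dplyr::n(),
    n_included = sum(.data$qc_pass),
    n_flagged = sum(!.data$qc_pass),
    mean_rate_fF_per_s = if (any(.data$qc_pass)) {
      mean(.data$rate_fF_per_s[.data$qc_pass])
    } else NA_real_,
    sd_rate_fF_per_s = if (sum(.data$qc_pass) >= 2) {
      sd(.data$rate_fF_per_s[.data$qc_pass])
    } else NA_real_,
    .groups = "drop"
  )
  results$unevaluable <- results$n_included == 0
  results$label <- factor(NA, levels = c("no_classification", "category2"))
  ok <- !results$unevaluable
  results$label[ok] <- classify(results$mean_rate_fF_per_s[ok], config)

  included <- per_trace[per_trace$qc_pass, c("substance", "rate_fF_per_s",
                                             "device_id", "day_id")]
  comparisons <- NULL
  sizes <- table(included$substance)
  if (config$control_substance %in% names(sizes) &&
      all(sizes >= 2) && length(sizes) >= 2) {
    comparisons <- compare_to_control(included, config)
  }
  repro <- tryCatch(
    reproducibility(included),
    error = function(e) NULL
  )
  structure(
    list(per_trace = per_trace, results = results, comparisons = comparisons,
         reproducibility = repro, config = config),
    class = "irritation_report"
  )
}

#' Generate a synthetic substance panel
#'
#' One batch of blank-then-sample assay traces per panel substance, with
#' replicate-level rate variability and instrument noise, ready for
#' [assay_run()].
#'
#' @param panel Tibble with `substance`, `ghs_label`,
#'   `target_rate_fF_per_s` (default [reference_panel()]).
#' @param n_reps Replicates per substance.
#' @param rate_cv_pct Replicate-level CV of the disruption rate (%).
#' @param noise A [noise_model()].
#' @param state Intact-sensor [circuit_state()].
#' @param duration_s,sampling_dt_s Passed to [standard_protocol()].
#' @param seed Root seed.
#' @return List with `traces` (nested tibble) and `protocol`; protocols are
#'   identical across substances apart from the sample name.
#' @export
generate_panel <- function(panel = reference_panel(), n_reps = 3,
                           rate_cv_pct = 3, noise = noise_model(),
                           state = default_circuit_state(),
                           duration_s = 900, sampling_dt_s = 0.1, seed = 1) {
  rows <- purrr::map(seq_len(nrow(panel)), function(i) {
    prof <- substance_profile(panel$substance[i], panel$ghs_label[i],
                              target_rate_fF_per_s = panel$target_rate_fF_per_s[i])
    prot <- standard_protocol(prof$name, duration_s, sampling_dt_s)
    b <- generate_batch(prof, prot, n_devices = 1, n_days = 1, n_reps = n_reps,
                        baseline_cv_pct = 0, rate_cv_pct = 0,
                        rate_cv_rep_pct = rate_cv_pct,
                        noise = noise, state = state,
                        seed = child_seed(seed, i))
    b$ghs_label <- panel$ghs_label[i]
    b
  })
  list(
    traces = dplyr::bind_rows(rows),
    protocol = standard_protocol("sample", duration_s, sampling_dt_s)
  )
}

#' @export
print.irritation_report <- function(x, ...) {
  cat("Capacitive irritation assay report\n")
  cat(sprintf("  estimator: %s slope; cutoff %.2f fF/s; alpha %.3g (Bonferroni)\n",
              x$config$estimator, x$config$cutoff_fF_per_s, x$config$alpha))
  cat(sprintf("  traces: %d (%d flagged by blank QC)\n",
              nrow(x$per_trace), sum(!x$per_trace$qc_pass)))
  print(x$results)
  if (!is.null(x$comparisons)) {
    cat(sprintf("Group comparisons vs %s:\n", x$config$control_substance))
    print(x$comparisons)
  }
  if (!is.null(x$reproducibility)) {
    cat("Reproducibility (CV %):\n")
    print(x$reproducibility)
  }
  invisible(x)
}

#' @method tidy irritation_report
#' @export
tidy.irritation_report <- function(x, ...) {
  x$results
}

#' @method glance irritation_report
#' @export
glance.irritation_report <- function(x, ...) {
  tibble::tibble(
    n_traces = nrow(x$per_trace),
    n_substances = nrow(x$results),
    n_category2 = sum(x$results$label == "category2", na.rm = TRUE),
    n_flagged = sum(!x$per_trace$qc_pass),
    n_unevaluable = sum(x$results$unevaluable),
    n_significant = if (is.null(x$comparisons)) NA_integer_ else {
      sum(x$comparisons$significant)
    }
  )
}

#' Plot per-substance disruption rates against the cutoff
#'
#' @param object An `irritation_report`.
#' @param ... Unused.
#' @return A ggplot: replicate and mean rates per substance on a log axis,
#'   with the classification cutoff.
#' @method autoplot irritation_report
#' @export
autoplot.irritation_report <- function(object, ...) {
  inc <- object$per_trace[object$per_trace$qc_pass, ]
  ggplot2::ggplot(inc, ggplot2::aes(x = .data$substance, y = .data$rate_fF_per_s)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 95, size = 8,
                          colour = "red") +
    ggplot2::geom_hline(yintercept = object$config$cutoff_fF_per_s,
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = expression(Delta * C / Delta * t ~ "(fF/s)"),
                  title = "Disruption rates vs classification cutoff")
}

#' Plot a capacitance-time trace
#'
#' @param trace A trace tibble.
#' @param t_apply_s Optional application time to mark.
#' @return A ggplot of the transient.
#' @export
plot_trace <- function(trace, t_apply_s = trace_meta(trace)$t_apply_s) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_s, y = .data$capacitance_fF)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Capacitance (fF)")
  if (!is.null(t_apply_s) && is.finite(t_apply_s)) {
    p <- p + ggplot2::geom_vline(xintercept = t_apply_s, colour = "red",
                                 linetype = "dotted")
  }
  p
}
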