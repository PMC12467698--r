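#' Classification configuration
#'
#' @param cutoff_fF_per_s Decision threshold on dC/dt (fF/s); default 3.5.
#' @param estimator Which slope feeds classification: `"windowed"` (60-450 s
#'   OLS slope, the canonical definition) or `"max_rate"`.
#' @param alpha Significance level for group comparisons; default 0.01.
#' @param n_comparisons Bonferroni divisor; `NULL` means the number of
#'   non-control substances in the run.
#' @param var_equal Use the pooled-variance Student t-test instead of Welch.
#' @param control_substance Negative-control group name.
#' @param blank_substance Substance of the blank-QC segment.
#' @param min_blank_s Minimum blank-segment length (s).
#' @return A list of class `classification_config`.
#' @export
classification_config <- function(cutoff_fF_per_s = 3.5,
                                  estimator = c("windowed", "max_rate"),
                                  alpha = 0.01, n_comparisons = NULL,
                                  var_equal = FALSE,
                                  control_substance = "PBS",
                                  blank_substance = "PBS",
                                  min_blank_s = 400) {
  estimator <- match.arg(estimator)
  stopifnot(cutoff_fF_per_s > 0, alpha > 0, alpha < 1,
            is.null(n_comparisons) || n_comparisons >= 1)
  structure(
    list(cutoff_fF_per_s = cutoff_fF_per_s, estimator = estimator,
         alpha = alpha, n_comparisons = n_comparisons, var_equal = var_equal,
         control_substance = control_substance,
         blank_substance = blank_substance, min_blank_s = min_blank_s),
    class = "classification_config"
  )
}

#' Classify a disruption rate
#'
#' Category 2 iff the rate strictly exceeds the cutoff; ties and anything
#' below (including negative rates) map to No Classification.
#'
#' @param rate_fF_per_s dC/dt values (fF/s); vectorised.
#' @param config A [classification_config()].
#' @return Factor with levels `no_classification`, `category2`.
#' @export
classify <- function(rate_fF_per_s, config = classification_config()) {
  if (any(is.na(rate_fF_per_s))) {
    abort("Rates must be finite to classify.", class = "irritrace_invalid_metric")
  }
  factor(ifelse(rate_fF_per_s > config$cutoff_fF_per_s, "category2", "no_classification"),
         levels = c("no_classification", "category2"))
}

#' Blank quality control
#'
#' Fits the OLS slope over the PBS blank segment; the barrier passes when
#' the slope is both below the classification cutoff in magnitude and
#' statistically indistinguishable from zero (|slope| <= 3 SE).
#'
#' @param trace A trace tibble.
#' @param protocol An [exposure_protocol()] whose events delimit the blank
#'   segment (apply then remove of the blank substance).
#' @param config A [classification_config()].
#' @return One-row tibble: `pass`, `slope_fF_per_s`, `se_fF_per_s`.
#' @export
blank_qc <- function(trace, protocol, config = classification_config()) {
  ev <- protocol$events
  i_on <- which(ev$kind == "apply" & ev$substance == config$blank_substance)
  if (!length(i_on)) {
    abort("Protocol has no blank application event.", class = "irritrace_protocol_error")
  }
  i_on <- i_on[1]
  later <- which(ev$kind == "remove" & seq_len(nrow(ev)) > i_on)
  t_off <- if (length(later)) ev$t_s[later[1]] else protocol$duration_s
  if (t_off - ev$t_s[i_on] < config$min_blank_s) {
    abort(sprintf("Blank segment is %.0f s; at least %.0f s required.",
                  t_off - ev$t_s[i_on], config$min_blank_s),
          class = "irritrace_protocol_error")
  }
  idx <- window_idx(trace, c(ev$t_s[i_on], t_off), 50, "Blank")
  t <- trace$time_s[idx]
  y <- trace$capacitance_fF[idx]
  tc <- t - mean(t)
  sxx <- sum(tc^2)
  slope <- sum(tc * y) / sxx
  res <- y - mean(y) - slope * tc
  se <- sqrt(sum(res^2) / (length(y) - 2) / sxx)
  tibble::tibble(
    # epsilon guards the noiseless degenerate case where slope and SE are
    # both at floating-point zero
    pass = abs(slope) < config$cutoff_fF_per_s & abs(slope) <= 3 * se + 1e-9,
    slope_fF_per_s = slope,
    se_fF_per_s = se
  )
}

#' Coefficient of variation in percent
#'
#' @param values Numeric vector (n >= 2, non-zero mean).
#' @return 100 * sample SD / |mean|.
#' @examples
#' cv_percent(c(9, 10, 11)) # 10
#' @export
cv_percent <- function(values) {
  if (length(values) < 2) {
    abort("CV needs at least two values.", class = "irritrace_insufficient_replicates")
  }
  m <- mean(values)
  if (m == 0) {
    abort("CV is undefined for zero mean.", class = "irritrace_undefined_cv")
  }
  100 * sd(values) / abs(m)
}

#' Compare substance groups against the negative control
#'
#' Two-sample t-test (Welch by default, pooled-variance via the config
#' switch) of each non-control group against the control, Bonferroni
#' correction over the number of non-control groups, and a significance
#' flag at the configured alpha.
#'
#' @param rates Data frame with columns `substance` and `rate_fF_per_s`
#'   (one row per replicate).
#' @param config A [classification_config()].
#' @return Tibble with one row per non-control substance: `t_statistic`,
#'   `p_value`, `p_adjusted`, `significant`, `n_group`, `n_control`.
#' @export
compare_to_control <- function(rates, config = classification_config()) {
  stopifnot(is.data.frame(rates), all(c("substance", "rate_fF_per_s") %in% names(rates)))
  control <- config$control_substance
  if (!control %in% rates$substance) {
    abort(sprintf("Control group '%s' not present.", control),
          class = "irritrace_protocol_error")
  }
  ctrl <- rates$rate_fF_per_s[rates$substance == control]
  others <- setdiff(unique(rates$substance), control)
  sizes <- table(rates$substance)
  if (any(sizes < 2)) {
    abort(sprintf("Groups with fewer than 2 replicates: %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")),
          class = "irritrace_insufficient_replicates")
  }
  m <- config$n_comparisons %||% length(others)
  out <- purrr::map(others, function(s) {
    x <- rates$rate_fF_per_s[rates$substance == s]
    tt <- t.test(x, ctrl, var.equal = config$var_equal)
    tibble::tibble(substance = s,
                   t_statistic = unname(tt$statistic),
                   p_value = tt$p.value,
                   n_group = length(x), n_control = length(ctrl))
  })
  out <- dplyr::bind_rows(out)
  out$p_adjusted <- pmin(1, out$p_value * m)
  out$significant <- out$p_adjusted < config$alpha
  out[, c("substance", "t_statistic", "p_value", "p_adjusted",
          "significant", "n_group", "n_control")]
}

#' Reproducibility coefficients of variation
#'
#' Per substance: the mean CV of rates across replicates within each
#' device-day cell (intra-day), the mean CV of day means within each device
#' (inter-day), and the CV of device means (inter-device).
#'
#' @param metrics Data frame with columns `substance`, `device_id`,
#'   `day_id`, `rate_fF_per_s`.
#' @return Tibble with one row per substance: `cv_intra_day_pct`,
#'   `cv_inter_day_pct`, `cv_inter_device_pct`.
#' @export
reproducibility <- function(metrics) {
  stopifnot(all(c("substance", "device_id", "day_id", "rate_fF_per_s") %in% names(metrics)))
  if (!nrow(metrics)) {
    abort("No replicates to summarise.", class = "irritrace_insufficient_replicates")
  }
  per_sub <- function(df) {
    cells <- dplyr::summarise(
      dplyr::group_by(df, .data$device_id, .data$day_id),
      n = dplyr::n(), cv = if (dplyr::n() >= 2) cv_percent(.data$rate_fF_per_s) else NA_real_,
      mean_rate = mean(.data$rate_fF_per_s), .groups = "drop")
    if (any(cells$n < 2)) {
      abort("Each device-day cell needs at least 2 replicates.",
            class = "irritrace_insufficient_replicates")
    }
    day_means <- dplyr::summarise(
      dplyr::group_by(cells, .data$device_id),
      n_days = dplyr::n(),
      cv_day = if (dplyr::n() >= 2) cv_percent(.data$mean_rate) else NA_real_,
      device_mean = mean(.data$mean_rate), .groups = "drop")
    tibble::tibble(
      cv_intra_day_pct = mean(cells$cv),
      # levels that the design cannot resolve (single day, single device)
      # are reported NA rather than invented
      cv_inter_day_pct = if (any(day_means$n_days >= 2)) {
        mean(day_means$cv_day, na.rm = TRUE)
      } else NA_real_,
      cv_inter_device_pct = if (nrow(day_means) >= 2) {
        cv_percent(day_means$device_mean)
      } else NA_real_
    )
  }
  dplyr::reframe(dplyr::group_by(metrics, .data$substance), per_sub(dplyr::pick(dplyr::everything())))
}
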