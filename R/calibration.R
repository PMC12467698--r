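#' Fit the logarithmic spacer-thickness calibration
#'
#' Least-squares fit of C = a ln(x) + b to (thickness, capacitance) pairs.
#' The empirical relation between spacer thickness and the capacitance
#' reading is logarithmic over the working range (the ideal-plate 1/d law
#' does not hold for the layered coplanar geometry), so the calibration is
#' fit on ln(thickness). The 0 um blank cannot enter this fit and is
#' reported separately.
#'
#' @param data Data frame with columns `thickness_um` (> 0) and
#'   `capacitance_fF`.
#' @return An object of class `cap_calibration` with coefficients,
#'   R-squared, and residuals.
#' @examples
#' pts <- generate_calibration_set(calibration_design(c(30, 130, 330)))
#' fit <- fit_log_model(pts)
#' predict(fit, thickness_um = 170)
#' @export
fit_log_model <- function(data) {
  stopifnot(is.data.frame(data), all(c("thickness_um", "capacitance_fF") %in% names(data)))
  x <- data$thickness_um
  if (any(x <= 0)) {
    abort("Thicknesses must be positive: ln(x) is undefined at or below 0.",
          class = "irritrace_domain_error")
  }
  if (length(unique(x)) < 2) {
    abort("Need at least two distinct thicknesses to fit the log model.",
          class = "irritrace_rank_deficiency")
  }
  fit <- lm(capacitance_fF ~ log(thickness_um), data = data)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((data$capacitance_fF - mean(data$capacitance_fF))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  new_cap_calibration(
    coeff_a_fF = unname(coef(fit)[2]),
    coeff_b_fF = unname(coef(fit)[1]),
    r_squared = r2,
    n_points = nrow(data),
    residuals_fF = unname(stats::residuals(fit)),
    data = tibble::as_tibble(data)
  )
}

new_cap_calibration <- function(coeff_a_fF, coeff_b_fF, r_squared = NA_real_,
                                n_points = NA_integer_, residuals_fF = numeric(),
                                data = NULL) {
  structure(
    list(coeff_a_fF = coeff_a_fF, coeff_b_fF = coeff_b_fF,
         r_squared = r_squared, n_points = n_points,
         residuals_fF = residuals_fF, data = data),
    class = "cap_calibration"
  )
}

#' Build a calibration model from known coefficients
#'
#' Instantiates the calibration directly from published coefficients, e.g.
#' the study model a = -144.5 fF per ln-um, b = 1007.5 fF.
#'
#' @param coeff_a_fF Log coefficient (fF per ln-um).
#' @param coeff_b_fF Intercept (fF).
#' @return A `cap_calibration` object without fit diagnostics.
#' @export
calibration_model <- function(coeff_a_fF, coeff_b_fF) {
  new_cap_calibration(coeff_a_fF, coeff_b_fF)
}

#' @export
print.cap_calibration <- function(x, ...) {
  cat(sprintf("Spacer calibration: C = %.4g ln(x) + %.4g  [fF; x in um]\n",
              x$coeff_a_fF, x$coeff_b_fF))
  if (is.finite(x$r_squared)) {
    cat(sprintf("  R-squared %.4f on %d points\n", x$r_squared, x$n_points))
  }
  invisible(x)
}

#' Predict capacitance at a spacer thickness
#'
#' @param object A `cap_calibration`.
#' @param thickness_um Thickness in um (> 0); vectorised.
#' @param ... Unused.
#' @return Capacitance in fF.
#' @export
predict.cap_calibration <- function(object, thickness_um, ...) {
  if (any(thickness_um <= 0)) {
    abort("Thickness must be positive.", class = "irritrace_domain_error")
  }
  object$coeff_a_fF * log(thickness_um) + object$coeff_b_fF
}

#' Inverse prediction: thickness giving a target capacitance
#'
#' Solves C = a ln(x) + b for x = exp((C - b)/a); the exact inverse of
#' [predict.cap_calibration()].
#'
#' @param model A `cap_calibration`.
#' @param C_fF Capacitance in fF; vectorised.
#' @return Thickness in um.
#' @export
invert_thickness <- function(model, C_fF) {
  if (model$coeff_a_fF == 0) {
    abort("Model with zero log coefficient cannot be inverted.",
          class = "irritrace_non_invertible")
  }
  exp((C_fF - model$coeff_b_fF) / model$coeff_a_fF)
}

#' Working-point report
#'
#' Inverse-predicts the spacer thickness for a design capacitance and
#' reports the detection margin (distance from the working point down to the
#' C = 0 floor). When a measured capacitance at that thickness is supplied,
#' the absolute and relative prediction error are reported alongside.
#'
#' @param model A `cap_calibration`.
#' @param target_C_fF Design capacitance (fF).
#' @param measured_C_fF Optional measured capacitance (fF) at
#'   `at_thickness_um`, to quantify the model-vs-material discrepancy.
#' @param at_thickness_um Thickness at which `measured_C_fF` was taken (um);
#'   defaults to the inverse-predicted working-point thickness.
#' @return One-row tibble: `target_C_fF`, `thickness_um`, `margin_fF`, and
#'   when measured data are given `measured_C_fF`, `predicted_C_fF`,
#'   `abs_error_fF`, `rel_error_pct`.
#' @export
working_point_report <- function(model, target_C_fF, measured_C_fF = NULL,
                                 at_thickness_um = NULL) {
  out <- tibble::tibble(
    target_C_fF = target_C_fF,
    thickness_um = invert_thickness(model, target_C_fF),
    margin_fF = target_C_fF
  )
  if (!is.null(measured_C_fF)) {
    at <- at_thickness_um %||% out$thickness_um
    predicted <- predict(model, at)
    out$measured_C_fF <- measured_C_fF
    out$predicted_C_fF <- predicted
    out$abs_error_fF <- abs(predicted - measured_C_fF)
    out$rel_error_pct <- 100 * out$abs_error_fF / predicted
  }
  out
}

#' @method tidy cap_calibration
#' @export
tidy.cap_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("ln(thickness_um)", "(Intercept)"),
    estimate = c(x$coeff_a_fF, x$coeff_b_fF)
  )
}

#' @method glance cap_calibration
#' @export
glance.cap_calibration <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n_points)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Calibration curve plot
#'
#' @param object A `cap_calibration` fitted with [fit_log_model()].
#' @param ... Unused.
#' @return A ggplot: points and the fitted log curve on a linear thickness
#'   axis.
#' @method autoplot cap_calibration
#' @export
autoplot.cap_calibration <- function(object, ...) {
  stopifnot(!is.null(object$data))
  grid <- tibble::tibble(
    thickness_um = seq(min(object$data$thickness_um),
                       max(object$data$thickness_um), length.out = 200)
  )
  grid$capacitance_fF <- predict(object, grid$thickness_um)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$thickness_um, y = .data$capacitance_fF)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "Spacer thickness (µm)", y = "Capacitance (fF)",
                  title = "Spacer-thickness calibration")
}
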