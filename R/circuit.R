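#' Dielectric layer of the sensor stack
#'
#' One layer of the artificial stratum corneum build-up: the insulating
#' polyacetate tape over the electrodes, the double-sided adhesive spacer,
#' the absorbent cellulose-ester filter, or the lanolin barrier coating.
#'
#' @param name Layer label.
#' @param thickness_um Layer thickness in micrometres (> 0).
#' @param rel_permittivity Relative permittivity (>= 1).
#' @param role One of `"insulation"`, `"adhesive"`, `"absorbent"`, `"barrier"`.
#' @return A one-row tibble of class `dielectric_layer`.
#' @examples
#' dielectric_layer("DS tape", 170, 3.2, "adhesive")
#' @export
dielectric_layer <- function(name, thickness_um, rel_permittivity,
                             role = c("insulation", "adhesive", "absorbent", "barrier")) {
  role <- match.arg(role)
  if (!is.numeric(thickness_um) || length(thickness_um) != 1 || !is.finite(thickness_um) ||
      thickness_um <= 0) {
    abort("`thickness_um` must be a single positive number.", class = "irritrace_invalid_geometry")
  }
  if (!is.numeric(rel_permittivity) || length(rel_permittivity) != 1 ||
      !is.finite(rel_permittivity) || rel_permittivity < 1) {
    abort("`rel_permittivity` must be a single number >= 1.", class = "irritrace_invalid_geometry")
  }
  out <- tibble::tibble(
    name = as.character(name),
    thickness_um = thickness_um,
    rel_permittivity = rel_permittivity,
    role = role
  )
  class(out) <- c("dielectric_layer", class(out))
  out
}

#' Sensor stack: ordered dielectric layers over one electrode
#'
#' @param layers A list of [dielectric_layer()] rows, or a tibble binding them.
#' @param electrode_area_um2 Electrode area in square micrometres (> 0).
#' @return A list of class `sensor_stack` with elements `layers` (tibble) and
#'   `electrode_area_um2`.
#' @examples
#' sensor_stack(
#'   list(
#'     dielectric_layer("PA tape", 60, 3.5, "insulation"),
#'     dielectric_layer("DS tape", 170, 3.2, "adhesive")
#'   ),
#'   electrode_area_um2 = 1e8
#' )
#' @export
sensor_stack <- function(layers, electrode_area_um2) {
  if (is.data.frame(layers)) layers <- list(layers)
  if (!length(layers)) {
    abort("A sensor stack needs at least one layer.", class = "irritrace_invalid_input")
  }
  layers <- dplyr::bind_rows(layers)
  if (nrow(layers) < 1) {
    abort("A sensor stack needs at least one layer.", class = "irritrace_invalid_input")
  }
  if (!is.numeric(electrode_area_um2) || length(electrode_area_um2) != 1 ||
      !is.finite(electrode_area_um2) || electrode_area_um2 <= 0) {
    abort("`electrode_area_um2` must be a single positive number.",
          class = "irritrace_invalid_geometry")
  }
  structure(
    list(layers = layers, electrode_area_um2 = electrode_area_um2),
    class = "sensor_stack"
  )
}

#' Parallel-plate capacitance of a single layer
#'
#' Applies C = eps0 * eps_r * A / d with eps0 expressed in fF/um, so the
#' result is in femtofarads.
#'
#' @param layer A [dielectric_layer()].
#' @param area_um2 Plate area in square micrometres (> 0).
#' @return Capacitance in fF.
#' @examples
#' # vacuum-gap 1 cm^2 plate pair, 170 um apart: ~5208 fF
#' layer_capacitance(dielectric_layer("gap", 170, 1, "insulation"), 1e8)
#' @export
layer_capacitance <- function(layer, area_um2) {
  if (!is.numeric(area_um2) || length(area_um2) != 1 || is.na(area_um2) || area_um2 < 0) {
    abort("`area_um2` must be a single non-negative number.",
          class = "irritrace_invalid_geometry")
  }
  if (layer$thickness_um <= 0) {
    abort("Layer thickness must be positive.", class = "irritrace_invalid_geometry")
  }
  EPS0_FF_PER_UM * layer$rel_permittivity * area_um2 / layer$thickness_um
}

#' Series capacitance of the whole dielectric stack
#'
#' Layers between electrode and sensing surface act as capacitors in series:
#' 1/C_s = sum(1/C_i). Order of the layers does not matter.
#'
#' @param stack A [sensor_stack()].
#' @return Stack capacitance C_s in fF.
#' @export
stack_capacitance <- function(stack) {
  stopifnot(inherits(stack, "sensor_stack"))
  ci <- EPS0_FF_PER_UM * stack$layers$rel_permittivity *
    stack$electrode_area_um2 / stack$layers$thickness_um
  1 / sum(1 / ci)
}

#' Lumped circuit state of the sensor
#'
#' Captures the quantities of the two-path equivalent circuit: the dielectric
#' stack capacitance `C_s` under each electrode, the inter-electrode contact
#' path in air (`C_a`, `R_e`) and under electrolyte (`C_a'`, `R_e'`), and a
#' leakage resistance through the barrier. `Inf` encodes an open circuit.
#'
#' @param C_s_fF Stack capacitance per electrode (fF, >= 0).
#' @param C_a_fF Air-path contact capacitance (fF, >= 0).
#' @param C_a_prime_fF Electrolyte-path contact capacitance (fF, >= 0);
#'   defaults to `C_a_fF` so that application of a droplet is continuous.
#' @param R_e_Gohm,R_e_prime_Gohm Contact-path resistances (GOhm, > 0 or Inf).
#' @param R_leak_Gohm Leakage resistance through the barrier (GOhm, > 0 or Inf).
#' @return A list of class `circuit_state`.
#' @export
circuit_state <- function(C_s_fF, C_a_fF, C_a_prime_fF = C_a_fF,
                          R_e_Gohm = Inf, R_e_prime_Gohm = Inf,
                          R_leak_Gohm = 1e4) {
  caps <- c(C_s_fF = C_s_fF, C_a_fF = C_a_fF, C_a_prime_fF = C_a_prime_fF)
  if (any(is.na(caps)) || any(caps < 0)) {
    abort("Capacitances must be non-negative.", class = "irritrace_invalid_input")
  }
  res <- c(R_e_Gohm = R_e_Gohm, R_e_prime_Gohm = R_e_prime_Gohm, R_leak_Gohm = R_leak_Gohm)
  if (any(is.na(res)) || any(res <= 0)) {
    abort("Resistances must be positive (use Inf for an open circuit).",
          class = "irritrace_invalid_input")
  }
  structure(
    list(C_s_fF = C_s_fF, C_a_fF = C_a_fF, C_a_prime_fF = C_a_prime_fF,
         R_e_Gohm = R_e_Gohm, R_e_prime_Gohm = R_e_prime_Gohm,
         R_leak_Gohm = R_leak_Gohm),
    class = "circuit_state"
  )
}

# Series combination of the two electrode stacks with a contact-path
# capacitance: C_total = [2/C_s + 1/C_contact]^-1. Vectorised over C_contact.
series_total <- function(C_s, C_contact) {
  out <- 1 / (2 / C_s + 1 / C_contact)
  out[C_contact == 0] <- 0
  out[is.infinite(C_contact)] <- C_s / 2
  out
}

#' Total measured capacitance of the sensor
#'
#' Two identical electrode stacks (C_s each) in series with the contact path
#' between them: C_total = \[2/C_s + 1/C_contact\]^-1, where the contact
#' capacitance is the air path (`mode = "air"`) or the electrolyte path
#' (`mode = "electrolyte"`). Bounded above by the conductive limit C_s/2.
#'
#' @param state A [circuit_state()].
#' @param mode `"air"` or `"electrolyte"`.
#' @return Total capacitance in fF.
#' @export
total_capacitance <- function(state, mode = c("air", "electrolyte")) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "circuit_state"))
  if (state$C_s_fF == 0) {
    abort("Degenerate sensor: C_s is zero.", class = "irritrace_degenerate_sensor")
  }
  contact <- if (mode == "air") state$C_a_fF else state$C_a_prime_fF
  series_total(state$C_s_fF, contact)
}

#' Conductive-path limit of the total capacitance
#'
#' When the electrolyte path becomes fully conductive the two electrode
#' stacks remain as the only series capacitances and the reading saturates
#' at C_s/2.
#'
#' @param state A [circuit_state()].
#' @return C_s / 2 in fF.
#' @export
conductive_limit <- function(state) {
  stopifnot(inherits(state, "circuit_state"))
  state$C_s_fF / 2
}

# Equivalent series-path capacitance of the leakage conductance at the
# measurement frequency: C = 1/(omega * R). R in GOhm -> fF conversion:
# 1/(omega * R * 1e9) F = 1e6/(omega * R) fF (~159 fF per 1/GOhm at 1 kHz).
leak_capacitance_fF <- function(R_leak_Gohm) {
  1e6 / (OMEGA_MEAS * R_leak_Gohm)
}
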