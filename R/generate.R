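#' Default sensor stack and circuit state of the simulator
#'
#' `default_sensor_stack()` mirrors the physical build: insulating PA tape
#' over the electrodes, a 170 um double-sided adhesive spacer, an absorbent
#' mixed-cellulose-ester filter and the lanolin barrier coating.
#' `default_circuit_state()` is the simulator's working state: a
#' high-headroom stack capacitance (C_s = 2e5 fF) with the air-path contact
#' capacitance set so the intact sensor reads close to the 220 fF working
#' point. The generous C_s/2 ceiling lets the rate-matching routine reach
#' the full span of reported disruption rates (up to 40 fF/s windowed slope).
#'
#' @return A [sensor_stack()] or [circuit_state()].
#' @export
default_sensor_stack <- function() {
  sensor_stack(
    list(
      dielectric_layer("PA tape", 60, 3.5, "insulation"),
      dielectric_layer("DS tape", 170, 3.2, "adhesive"),
      dielectric_layer("MCE filter", 180, 2.0, "absorbent"),
      dielectric_layer("lanolin", 50, 2.7, "barrier")
    ),
    electrode_area_um2 = 1e8
  )
}

#' @rdname default_sensor_stack
#' @param baseline_fF Air-mode reading the state is tuned to (fF).
#' @param C_s_fF Stack capacitance per electrode (fF).
#' @export
default_circuit_state <- function(baseline_fF = 220, C_s_fF = 2e5) {
  # invert the series formula so the air-mode total equals baseline_fF
  C_a <- 1 / (1 / baseline_fF - 2 / C_s_fF) - leak_capacitance_fF(1e4)
  circuit_state(C_s_fF = C_s_fF, C_a_fF = C_a, R_leak_Gohm = 1e4)
}

#' Instrument noise model
#'
#' Additive white noise plus a linear temperature sensitivity, matching the
#' capacitance readout's validated behaviour: RMS baseline noise below 2 fF
#' (measured 1.8 +/- 0.3 fF over 600 s) and a 0.012 +/- 0.004 fF/degC drift.
#'
#' @param white_rms_fF Standard deviation of the additive white noise (fF).
#' @param drift_per_degC_fF Linear temperature coefficient (fF/degC).
#' @param temperature_series Optional temperature trajectory on the trace
#'   grid (degC); defaults to a constant 25 degC.
#' @param reference_temp_C Temperature at which the drift term vanishes.
#' @param seed Integer RNG seed; `NULL` leaves the global RNG untouched.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(white_rms_fF = 1.8, drift_per_degC_fF = 0.012,
                        temperature_series = NULL, reference_temp_C = 25,
                        seed = NULL) {
  if (white_rms_fF < 0) {
    abort("`white_rms_fF` must be non-negative.", class = "irritrace_invalid_input")
  }
  structure(
    list(white_rms_fF = white_rms_fF, drift_per_degC_fF = drift_per_degC_fF,
         temperature_series = temperature_series,
         reference_temp_C = reference_temp_C, seed = seed),
    class = "noise_model"
  )
}

#' Exposure protocol
#'
#' Ordered apply/remove events on the sensing surface. The standard assay
#' confirms baseline stability for 20 s, applies a 50 uL PBS blank for
#' 400 s, removes it, then applies the test substance for the remainder of
#' the run.
#'
#' @param events Tibble or data frame with columns `kind` ("apply"/"remove"),
#'   `substance`, `t_s` (strictly increasing, within the duration).
#' @param sampling_dt_s Sampling interval (s), default 0.1.
#' @param duration_s Total trace length (s).
#' @param droplet_volume_uL Droplet volume, metadata only.
#' @return A list of class `exposure_protocol`.
#' @export
exposure_protocol <- function(events, sampling_dt_s = 0.1, duration_s,
                              droplet_volume_uL = 50) {
  events <- tibble::as_tibble(events)
  stopifnot(all(c("kind", "substance", "t_s") %in% names(events)))
  if (!all(events$kind %in% c("apply", "remove"))) {
    abort("Event kind must be 'apply' or 'remove'.", class = "irritrace_protocol_error")
  }
  if (sampling_dt_s <= 0) {
    abort("`sampling_dt_s` must be positive.", class = "irritrace_protocol_error")
  }
  if (nrow(events) && (any(diff(events$t_s) <= 0) ||
                       any(events$t_s < 0) || any(events$t_s >= duration_s))) {
    abort("Event times must be strictly increasing and inside the trace duration.",
          class = "irritrace_protocol_error")
  }
  structure(
    list(events = events, sampling_dt_s = sampling_dt_s,
         duration_s = duration_s, droplet_volume_uL = droplet_volume_uL),
    class = "exposure_protocol"
  )
}

#' Standard blank-then-sample assay protocol
#'
#' Baseline 20 s, PBS blank 400 s, blank removal, then the test substance
#' applied at 430 s and held for the rest of the run.
#'
#' @param substance Name of the test substance.
#' @param duration_s Total length (s); the default leaves a full 60-450 s
#'   analysis window after sample application.
#' @param sampling_dt_s Sampling interval (s).
#' @return An [exposure_protocol()].
#' @export
standard_protocol <- function(substance, duration_s = 900, sampling_dt_s = 0.1) {
  exposure_protocol(
    tibble::tibble(
      kind = c("apply", "remove", "apply"),
      substance = c("PBS", "PBS", substance),
      t_s = c(20, 420, 430)
    ),
    sampling_dt_s = sampling_dt_s, duration_s = duration_s
  )
}

#' Substance profile for the simulator
#'
#' @param name Substance label.
#' @param ghs_label One of `"category2"`, `"no_classification"`,
#'   `"control_negative"`, `"control_positive"`.
#' @param target_rate_fF_per_s Nominal windowed dC/dt the kinetics are tuned
#'   to produce (fF/s, >= 0).
#' @param kinetics Optional pre-tuned [disruption_kinetics()]; when `NULL`
#'   the generator tunes kinetics to the target rate on demand.
#' @return A list of class `substance_profile`.
#' @export
substance_profile <- function(name, ghs_label = c("no_classification", "category2",
                                                  "control_negative", "control_positive"),
                              target_rate_fF_per_s = 0, kinetics = NULL) {
  ghs_label <- match.arg(ghs_label)
  if (target_rate_fF_per_s < 0) {
    abort("`target_rate_fF_per_s` must be non-negative.", class = "irritrace_invalid_input")
  }
  structure(
    list(name = name, ghs_label = ghs_label,
         target_rate_fF_per_s = target_rate_fF_per_s, kinetics = kinetics),
    class = "substance_profile"
  )
}

#' Reference substance panel
#'
#' Six OECD reference substances: the non-classified group (PBS 0.4,
#' PEG 400 0.7, 50% isopropanol 1.3 fF/s) and the Category 2 group
#' (5% glutaraldehyde 8, 5% KOH 20, 5% SDS 40 fF/s), spanning the reported
#' group ranges of 0.4-1.3 and 8-40 fF/s.
#'
#' @return Tibble with columns `substance`, `ghs_label`,
#'   `target_rate_fF_per_s`.
#' @export
reference_panel <- function() {
  tibble::tibble(
    substance = c("PBS", "PEG400", "isopropanol", "GA", "KOH", "SDS"),
    ghs_label = c("no_classification", "no_classification", "no_classification",
                  "category2", "category2", "category2"),
    target_rate_fF_per_s = c(0.4, 0.7, 1.3, 8, 20, 40)
  )
}

# Deterministic child seed per trace so any subset of a batch is
# reproducible from the root seed alone (affine counter scheme mod a prime
# below 2^31).
child_seed <- function(root, index) {
  ((as.numeric(root) %% 59999) * 31013 + as.numeric(index) * 7919) %% 2147483629 + 1
}

# Evaluate thunk with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

new_trace <- function(time_s, capacitance_fF, temperature_C = NULL, meta = list()) {
  tr <- tibble::tibble(time_s = time_s, capacitance_fF = capacitance_fF)
  if (!is.null(temperature_C)) tr$temperature_C <- temperature_C
  attr(tr, "meta") <- meta
  tr
}

#' Metadata of a trace
#'
#' @param trace A trace tibble produced by [generate_trace()] or
#'   [read_trace_csv()].
#' @return Named list of metadata fields.
#' @export
trace_meta <- function(trace) {
  attr(trace, "meta") %||% list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic capacitance-time trace
#'
#' Runs the circuit model piecewise over the protocol events. Apply events
#' matching the substance profile start the tuned disruption kinetics; apply
#' events of other substances (the PBS blank) leave the contact path frozen;
#' remove events relax the contact path back toward its air value at
#' `recovery_rate_per_s`. White noise and the temperature-drift term are then
#' added. Deterministic given the noise model's seed.
#'
#' @param substance A [substance_profile()].
#' @param protocol An [exposure_protocol()].
#' @param noise A [noise_model()].
#' @param state Intact-sensor [circuit_state()].
#' @param window Analysis window (s, relative to application) used when
#'   kinetics must be tuned to the profile's target rate.
#' @param recovery_rate_per_s Relaxation rate back to baseline after a
#'   removal event (1/s).
#' @param meta Extra metadata fields (device_id, batch_id, day_id, ...).
#' @return A trace tibble (`time_s`, `capacitance_fF`, optionally
#'   `temperature_C`) with a `meta` attribute.
#' @export
generate_trace <- function(substance, protocol, noise = noise_model(),
                           state = default_circuit_state(),
                           window = c(60, 450),
                           recovery_rate_per_s = 0.01,
                           meta = list()) {
  stopifnot(inherits(substance, "substance_profile"),
            inherits(protocol, "exposure_protocol"),
            inherits(noise, "noise_model"))
  kin <- substance$kinetics
  if (is.null(kin)) {
    kin <- match_kinetics_to_rate(substance$target_rate_fF_per_s, window = window,
                                  state0 = state, dt_s = protocol$sampling_dt_s)
  }
  dt <- protocol$sampling_dt_s
  n <- round(protocol$duration_s / dt)
  t_grid <- seq(0, by = dt, length.out = n)

  # piecewise-exponential contact capacitance and leakage resistance
  C_c <- rep(state$C_a_fF, n)
  R_l <- rep(state$R_leak_Gohm, n)
  ev <- protocol$events
  bounds <- c(ev$t_s, Inf)
  cur_C <- state$C_a_fF
  cur_R <- state$R_leak_Gohm
  t_apply_s <- NA_real_
  # the test application is the LAST apply event naming the profile's
  # substance; earlier matching applies (e.g. a PBS blank when PBS is also
  # the test substance) are inert blank contacts
  test_ev <- utils::tail(which(ev$kind == "apply" & ev$substance == substance$name), 1)
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      idx <- t_grid >= ev$t_s[i] & t_grid < bounds[i + 1]
      if (length(test_ev) && i == test_ev) {
        tgt_C <- kin$C_a_prime_final_fF; k_C <- kin$rate_perm_per_s
        tgt_R <- kin$R_leak_final_Gohm;  k_R <- kin$rate_leak_per_s
        t_apply_s <- ev$t_s[i]
      } else if (ev$kind[i] == "apply") {
        tgt_C <- cur_C; k_C <- 0
        tgt_R <- cur_R; k_R <- 0
      } else {
        tgt_C <- state$C_a_fF;      k_C <- recovery_rate_per_s
        tgt_R <- state$R_leak_Gohm; k_R <- recovery_rate_per_s
      }
      C_c[idx] <- relax_exp(t_grid[idx], ev$t_s[i], cur_C, tgt_C, k_C)
      R_l[idx] <- relax_exp(t_grid[idx], ev$t_s[i], cur_R, tgt_R, k_R)
      t_end <- min(bounds[i + 1], t_grid[n])
      cur_C <- relax_exp(t_end, ev$t_s[i], cur_C, tgt_C, k_C)
      cur_R <- relax_exp(t_end, ev$t_s[i], cur_R, tgt_R, k_R)
    }
  }
  C <- series_total(state$C_s_fF, C_c + leak_capacitance_fF(R_l))

  temp <- noise$temperature_series %||% rep(25, n)
  if (length(temp) != n) {
    abort("Temperature series must match the trace grid length.",
          class = "irritrace_invalid_input")
  }
  C <- C + noise$drift_per_degC_fF * (temp - noise$reference_temp_C)
  if (noise$white_rms_fF > 0) {
    C <- C + with_seed(noise$seed, rnorm(n, 0, noise$white_rms_fF))
  }
  new_trace(t_grid, C,
            temperature_C = if (is.null(noise$temperature_series)) NULL else temp,
            meta = c(list(substance = substance$name,
                          ghs_label = substance$ghs_label,
                          t_apply_s = t_apply_s,
                          sampling_dt_s = dt), meta))
}

#' Generate a device x day x replicate batch of traces
#'
#' Multiplicative Normal(1, cv) perturbations are applied to the baseline
#' (device level) and to the target disruption rate (device, day and
#' replicate levels), emulating fabrication and run-to-run variability;
#' kinetics are re-tuned to each perturbed rate.
#'
#' @param substance A [substance_profile()].
#' @param protocol An [exposure_protocol()].
#' @param n_devices,n_days,n_reps Grouping sizes.
#' @param baseline_cv_pct Device-level CV of the baseline capacitance (%).
#' @param rate_cv_pct Default CV applied at each rate level (%).
#' @param rate_cv_device_pct,rate_cv_day_pct,rate_cv_rep_pct Per-level rate
#'   CVs (%), defaulting to `rate_cv_pct`.
#' @param noise A [noise_model()]; its seed is ignored in favour of
#'   per-trace child seeds.
#' @param state Intact-sensor [circuit_state()].
#' @param seed Root seed; child streams per trace follow a counter scheme so
#'   subsets are reproducible.
#' @return Nested tibble with one row per trace: `device_id`, `day_id`,
#'   `rep_id`, `substance`, `trace` (list column).
#' @export
generate_batch <- function(substance, protocol,
                           n_devices = 3, n_days = 1, n_reps = 5,
                           baseline_cv_pct = 0.7, rate_cv_pct = 3,
                           rate_cv_device_pct = rate_cv_pct,
                           rate_cv_day_pct = rate_cv_pct,
                           rate_cv_rep_pct = rate_cv_pct,
                           noise = noise_model(),
                           state = default_circuit_state(),
                           seed = 1) {
  stopifnot(baseline_cv_pct >= 0, rate_cv_device_pct >= 0,
            rate_cv_day_pct >= 0, rate_cv_rep_pct >= 0)
  grid <- tidyr::expand_grid(device_id = seq_len(n_devices),
                             day_id = seq_len(n_days),
                             rep_id = seq_len(n_reps))
  fac <- with_seed(child_seed(seed, 0), {
    dev_base <- rnorm(n_devices, 1, baseline_cv_pct / 100)
    dev_rate <- rnorm(n_devices, 1, rate_cv_device_pct / 100)
    day_rate <- matrix(rnorm(n_devices * n_days, 1, rate_cv_day_pct / 100),
                       n_devices, n_days)
    rep_rate <- rnorm(nrow(grid), 1, rate_cv_rep_pct / 100)
    list(dev_base = dev_base, dev_rate = dev_rate, day_rate = day_rate,
         rep_rate = rep_rate)
  })
  base0 <- total_capacitance(state, "air")
  traces <- purrr::map(seq_len(nrow(grid)), function(i) {
    d <- grid$device_id[i]; y <- grid$day_id[i]
    rate_i <- substance$target_rate_fF_per_s *
      fac$dev_rate[d] * fac$day_rate[d, y] * fac$rep_rate[i]
    state_i <- default_circuit_state(baseline_fF = base0 * fac$dev_base[d],
                                     C_s_fF = state$C_s_fF)
    prof_i <- substance_profile(substance$name, substance$ghs_label,
                                target_rate_fF_per_s = max(rate_i, 0))
    noise_i <- noise_model(noise$white_rms_fF, noise$drift_per_degC_fF,
                           noise$temperature_series, noise$reference_temp_C,
                           seed = child_seed(seed, i))
    generate_trace(prof_i, protocol, noise_i, state = state_i,
                   meta = list(device_id = d, day_id = y, rep_id = grid$rep_id[i],
                               batch_id = d))
  })
  grid$substance <- substance$name
  grid$trace <- traces
  grid
}

#' Calibration design and dataset generator
#'
#' Generates (thickness, capacitance) pairs from the logarithmic spacer
#' model C = a ln(x) + b plus additive Gaussian noise. The 0 um blank is not
#' part of the design (ln(0) is undefined); it is reported separately as a
#' constant blank response.
#'
#' @param thicknesses_um Spacer thicknesses (um, all > 0).
#' @param reps Replicates per thickness.
#' @param noise_rms_fF Additive noise SD on the capacitance (fF).
#' @param coeff_a_fF,coeff_b_fF Generating model coefficients (fF).
#' @param seed Integer seed.
#' @return `calibration_design()`: a list of class `calibration_design`.
#' @export
calibration_design <- function(thicknesses_um = c(30, 130, 170, 330), reps = 1,
                               noise_rms_fF = 0, coeff_a_fF = -144.5,
                               coeff_b_fF = 1007.5, seed = 1) {
  if (any(thicknesses_um <= 0)) {
    abort("Spacer thicknesses must be positive (ln(0) is undefined; the 0 um blank is handled separately).",
          class = "irritrace_domain_error")
  }
  structure(
    list(thicknesses_um = thicknesses_um, reps = reps,
         noise_rms_fF = noise_rms_fF, coeff_a_fF = coeff_a_fF,
         coeff_b_fF = coeff_b_fF, seed = seed),
    class = "calibration_design"
  )
}

#' @rdname calibration_design
#' @param design A `calibration_design()`.
#' @return `generate_calibration_set()`: tibble with `thickness_um`,
#'   `capacitance_fF`.
#' @export
generate_calibration_set <- function(design) {
  stopifnot(inherits(design, "calibration_design"))
  x <- rep(design$thicknesses_um, each = design$reps)
  mu <- design$coeff_a_fF * log(x) + design$coeff_b_fF
  eps <- if (design$noise_rms_fF > 0) {
    with_seed(design$seed, rnorm(length(x), 0, design$noise_rms_fF))
  } else 0
  tibble::tibble(thickness_um = x, capacitance_fF = mu + eps)
}
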