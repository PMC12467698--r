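# fixtures are built in code; no stored data

EPS0 <- 8.854e-3 # fF/um, duplicated here as the tests' independent constant

make_trace <- function(C, dt = 0.1, temperature_C = NULL, meta = list()) {
  tr <- tibble::tibble(time_s = seq(0, by = dt, length.out = length(C)),
                       capacitance_fF = C)
  if (!is.null(temperature_C)) tr$temperature_C <- temperature_C
  attr(tr, "meta") <- meta
  tr
}

quiet_noise <- function(seed = NULL) noise_model(white_rms_fF = 0, seed = seed)

no_event_protocol <- function(duration_s = 600, dt = 0.1) {
  exposure_protocol(
    tibble::tibble(kind = character(), substance = character(), t_s = numeric()),
    sampling_dt_s = dt, duration_s = duration_s
  )
}

# series formula evaluated longhand, independent of the package internals
series_oracle <- function(C_s, C_contact) 1 / (2 / C_s + 1 / C_contact)
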