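#' Specify a bath-temperature simulation
#'
#' Models the heated imaging chamber as a first-order thermal plant,
#' dT/dt = -(T - ambient)/tau + heater_rate * u, driven by a bang-bang
#' controller: the heater switches on when the measured (noisy) temperature is
#' below the setpoint and off when it is at or above it.
#'
#' @param setpoint_C Desired bath temperature, deg C (physiological default 37).
#' @param ambient_C Ambient temperature, deg C.
#' @param start_C Initial bath temperature (default: ambient).
#' @param thermal_time_constant_s Plant time constant tau, s.
#' @param heater_rate_C_per_s Heating rate with the heater on, deg C / s.
#'   Must exceed `(setpoint_C - ambient_C) / thermal_time_constant_s` for the
#'   bath to reach the setpoint; the default 0.5 holds a 37 deg C bath from
#'   21 deg C ambient within a fraction of a degree.
#' @param sensor_noise_C Gaussian sd of the thermistor reading, deg C.
#' @param dt_s Euler integration step, s; must be < tau / 10.
#' @param duration_s Simulated duration, s.
#' @param seed Integer seed for the sensor noise.
#' @return An object of class `bath_sim_spec`.
#' @export
bath_sim_spec <- function(setpoint_C = 37, ambient_C = 21,
                          start_C = ambient_C,
                          thermal_time_constant_s = 120,
                          heater_rate_C_per_s = 0.5,
                          sensor_noise_C = 0.05,
                          dt_s = 1, duration_s = 600, seed = 1L) {
  check_number(setpoint_C, "setpoint_C")
  check_number(ambient_C, "ambient_C")
  check_number(start_C, "start_C")
  check_number(thermal_time_constant_s, "thermal_time_constant_s", min = 1e-9)
  check_number(heater_rate_C_per_s, "heater_rate_C_per_s", min = 0)
  check_number(sensor_noise_C, "sensor_noise_C", min = 0)
  check_number(dt_s, "dt_s", min = 1e-12)
  check_number(duration_s, "duration_s", min = 0)
  seed <- check_count(seed, "seed")
  if (dt_s >= thermal_time_constant_s / 10) {
    stop_validation("`dt_s` must be smaller than thermal_time_constant_s / 10")
  }
  structure(
    list(setpoint_C = setpoint_C, ambient_C = ambient_C, start_C = start_C,
         thermal_time_constant_s = thermal_time_constant_s,
         heater_rate_C_per_s = heater_rate_C_per_s,
         sensor_noise_C = sensor_noise_C, dt_s = dt_s,
         duration_s = duration_s, seed = seed),
    class = "bath_sim_spec")
}

#' Simulate the bang-bang heated bath
#'
#' Euler-integrates the first-order plant under on/off control. At each step
#' the controller reads the noisy sensor, sets the heater for that step, and
#' the plant integrates forward. `heater_on` is TRUE exactly on steps where
#' the measured temperature was below the setpoint.
#'
#' @param spec A [bath_sim_spec()].
#' @return Tibble with `time_s`, `temperature_C` (measured),
#'   `temperature_true_C` (plant state) and `heater_on`.
#' @export
simulate_bath_temperature <- function(spec) {
  stopifnot(inherits(spec, "bath_sim_spec"))
  n <- floor(spec$duration_s / spec$dt_s) + 1L
  withr::with_seed(spec$seed, {
    noise <- if (spec$sensor_noise_C > 0) {
      rnorm(n, sd = spec$sensor_noise_C)
    } else {
      numeric(n)
    }
    temp_true <- numeric(n)
    temp_meas <- numeric(n)
    heater <- logical(n)
    T_now <- spec$start_C
    for (i in seq_len(n)) {
      temp_true[i] <- T_now
      temp_meas[i] <- T_now + noise[i]
      heater[i] <- temp_meas[i] < spec$setpoint_C
      dT <- -(T_now - spec$ambient_C) / spec$thermal_time_constant_s +
        spec$heater_rate_C_per_s * as.numeric(heater[i])
      T_now <- T_now + spec$dt_s * dT
    }
    tibble(time_s = (seq_len(n) - 1) * spec$dt_s,
           temperature_C = temp_meas,
           temperature_true_C = temp_true,
           heater_on = heater)
  })
}

#' Hydrostatic pressure of a saline column
#'
#' Converts the height of the physiological-saline reservoir column to the
#' transmural pressure it sets, using 1 mmHg = 1.35951 cmH2O (standard
#' conditions).
#'
#' @param column_height_cmH2O Column height(s), cm of water.
#' @return Pressure(s) in mmHg.
#' @examples
#' hydrostatic_pressure_mmHg(10)      # a 10 cmH2O gradient ~ 7.36 mmHg
#' hydrostatic_pressure_mmHg(135.951) # 100 mmHg
#' @export
hydrostatic_pressure_mmHg <- function(column_height_cmH2O) {
  if (!is.numeric(column_height_cmH2O)) {
    stop_validation("`column_height_cmH2O` must be numeric")
  }
  column_height_cmH2O / 1.35951
}
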