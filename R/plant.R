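#' Virtual hemorrhaging patient: parameters
#'
#' Builds the parameter set for the software plant that stands in for a
#' hardware flow-loop test platform. The plant realizes the four response
#' features characterized for vasopressor dosing -- lag time (delay from a
#' dose change to any pressure response), responsiveness (first-order time
#' constant of the rise), real response (steady-state pressure change,
#' saturating Emax-style dose--response), and overshoot (transient peak above
#' the new steady state) -- plus a continuous-hemorrhage pressure drift.
#'
#' Hemorrhage is modeled as a constant volume loss whose pressure effect
#' accumulates through a fixed volume-to-pressure sensitivity
#' (`hemorrhage_map_slope`, mmHg per mL): with 10 mL/min bleeding and a slope
#' of 0.02 the mean arterial pressure (MAP) drifts down by 0.2 mmHg per
#' minute until counteracted by drug effect.
#'
#' @param baseline_map starting MAP, mmHg (scenario start pressure).
#' @param lag_time delay between a commanded dose change and its hemodynamic
#'   effect, seconds.
#' @param responsiveness_tau time constant of the first-order rise, seconds.
#' @param overshoot_frac fractional transient peak above the steady-state
#'   change after a dose step; 0 gives a monotone first-order response.
#' @param max_effect asymptote of the dose--response curve, mmHg.
#' @param half_effect_dose infusion rate producing half of `max_effect`,
#'   mL/min.
#' @param hemorrhage_rate continuous blood loss, mL/min.
#' @param hemorrhage_map_slope volume-to-pressure sensitivity, mmHg per mL.
#' @param noise_sd measurement/process noise standard deviation, mmHg (scaled
#'   by sqrt(dt) per step); 0 disables noise.
#' @param pulse_amplitude optional pulsatile overlay amplitude, mmHg
#'   (display only; not part of the controlled MAP).
#' @return an object of class `plant_params`.
#' @export
plant_params <- function(baseline_map = 35,
                         lag_time = 30,
                         responsiveness_tau = 60,
                         overshoot_frac = 0,
                         max_effect = 50,
                         half_effect_dose = 1.5,
                         hemorrhage_rate = 10,
                         hemorrhage_map_slope = 0.02,
                         noise_sd = 0,
                         pulse_amplitude = 0) {
  stopifnot(baseline_map > 0, lag_time >= 0, responsiveness_tau > 0,
            overshoot_frac >= 0, max_effect > 0, half_effect_dose > 0,
            hemorrhage_rate >= 0, hemorrhage_map_slope >= 0,
            noise_sd >= 0, pulse_amplitude >= 0)
  structure(list(baseline_map = baseline_map, lag_time = lag_time,
                 responsiveness_tau = responsiveness_tau,
                 overshoot_frac = overshoot_frac, max_effect = max_effect,
                 half_effect_dose = half_effect_dose,
                 hemorrhage_rate = hemorrhage_rate,
                 hemorrhage_map_slope = hemorrhage_map_slope,
                 noise_sd = noise_sd, pulse_amplitude = pulse_amplitude),
            class = "plant_params")
}

#' Initialize the plant state
#'
#' @param params a [plant_params()] object.
#' @param initial_dose infusion rate already running at t = 0, mL/min.
#' @return an object of class `plant_state` holding time, true MAP, the
#'   currently active (hemodynamically effective) dose, commanded dose,
#'   pending lagged dose changes and cumulative blood loss.
#' @export
plant_init <- function(params, initial_dose = 0) {
  stopifnot(inherits(params, "plant_params"), initial_dose >= 0)
  structure(list(time = 0,
                 map_true = params$baseline_map,
                 current_dose = initial_dose,  # commanded (record-keeping)
                 active_dose = initial_dose,   # hemodynamically effective
                 pending = list(),             # list of c(t_eff, dose)
                 cumulative_blood_loss = 0,
                 os_a = 0, os_b = 0),          # overshoot transient states
            class = "plant_state")
}

#' Steady-state MAP under a constant infusion rate
#'
#' Saturating (Emax-style) dose--response:
#' `baseline + max_effect * dose / (half_effect_dose + dose)`.
#' Monotone non-decreasing in dose and bounded by `baseline + max_effect`.
#' Hemorrhage drift is not included; it is a separate accumulating term in
#' [step_plant()].
#'
#' @param dose infusion rate, mL/min (>= 0).
#' @param params a [plant_params()] object.
#' @return steady-state MAP, mmHg.
#' @export
steady_state_map <- function(dose, params) {
  if (any(dose < 0)) stop("dose must be non-negative")
  params$baseline_map + params$max_effect * dose / (params$half_effect_dose + dose)
}

#' Command a new infusion rate
#'
#' The change is recorded immediately in `current_dose` but takes
#' hemodynamic effect only `lag_time` seconds later. Commanding the current
#' dose again is a no-op.
#'
#' @param state a `plant_state`.
#' @param new_dose commanded infusion rate, mL/min (>= 0).
#' @param params a [plant_params()] object.
#' @return updated `plant_state`.
#' @export
apply_dose <- function(state, new_dose, params) {
  if (new_dose < 0) stop("dose must be non-negative")
  if (new_dose == state$current_dose) return(state)
  state$pending[[length(state$pending) + 1L]] <-
    c(t_eff = state$time + params$lag_time, dose = new_dose)
  # keep pending sorted by effective time (stable for equal times)
  ord <- order(vapply(state$pending, `[[`, numeric(1), "t_eff"))
  state$pending <- state$pending[ord]
  state$current_dose <- new_dose
  state
}

#' Advance the plant by one Euler step
#'
#' MAP relaxes toward `steady_state_map(active dose)` minus the accumulated
#' hemorrhage pressure loss, with time constant `responsiveness_tau`; the
#' instantaneous drift `hemorrhage_map_slope * hemorrhage_rate * dt/60` is
#' also subtracted so that an untreated plant declines at exactly the drift
#' rate. When `overshoot_frac > 0`, each activated dose step injects an
#' alpha-function transient (critically damped two-stage filter) that peaks
#' at `overshoot_frac` times the steady-state step change before decaying.
#' Gaussian noise of sd `noise_sd * sqrt(dt)` is added when enabled (draws
#' come from R's RNG; seed at run level for reproducibility). MAP is clamped
#' to [5, 200] mmHg.
#'
#' @param state a `plant_state`.
#' @param dt integration step, seconds (0 < dt <= 1).
#' @param params a [plant_params()] object.
#' @return updated `plant_state`.
#' @export
step_plant <- function(state, dt, params) {
  stopifnot(dt > 0, dt <= 1)
  # activate pending dose changes due now
  while (length(state$pending) > 0L && state$pending[[1L]]["t_eff"] <= state$time) {
    new_active <- unname(state$pending[[1L]]["dose"])
    if (params$overshoot_frac > 0) {
      delta <- steady_state_map(new_active, params) -
        steady_state_map(state$active_dose, params)
      # alpha-function transient b(t) = K (t/tau) exp(-t/tau), peak K/e
      state$os_a <- state$os_a + exp(1) * params$overshoot_frac * delta
    }
    state$active_dose <- new_active
    state$pending <- state$pending[-1L]
  }
  tau <- params$responsiveness_tau
  drift <- params$hemorrhage_map_slope * params$hemorrhage_rate / 60  # mmHg/s
  target <- steady_state_map(state$active_dose, params) -
    params$hemorrhage_map_slope * state$cumulative_blood_loss + state$os_b
  dmap <- (target - state$map_true) / tau - drift
  noise <- if (params$noise_sd > 0) stats::rnorm(1, 0, params$noise_sd * sqrt(dt)) else 0
  state$map_true <- min(200, max(5, state$map_true + dt * dmap + noise))
  # overshoot transient states (critically damped pair, time constant tau)
  state$os_b <- state$os_b + dt * (state$os_a - state$os_b) / tau
  state$os_a <- state$os_a - dt * state$os_a / tau
  state$cumulative_blood_loss <- state$cumulative_blood_loss +
    params$hemorrhage_rate * dt / 60
  state$time <- state$time + dt
  state
}

#' Zero-order-hold MAP sampler
#'
#' Returns the MAP observation held since the most recent sample instant
#' (multiples of `sample_period`), emulating down-sampled non-invasive
#' measurement. Stateless helper: the caller passes the history of true MAP
#' values on the plant grid.
#'
#' @param times plant time grid, seconds.
#' @param maps MAP values on that grid, mmHg.
#' @param query_time time at which the held sample is requested, seconds.
#' @param sample_period sampling period, seconds (>= plant dt).
#' @return held MAP, mmHg.
#' @export
sample_map <- function(times, maps, query_time, sample_period) {
  stopifnot(length(times) == length(maps), sample_period > 0)
  t_sample <- floor(query_time / sample_period + 1e-9) * sample_period
  idx <- max(which(times <= t_sample + 1e-9))
  maps[idx]
}

#' Norepinephrine dosing table
#'
#' The stepwise dosing schedule used during hemorrhage resuscitation: eight
#' steps pairing dose (mcg/min) with infusion rate (mL/min) at a fixed drug
#' concentration of 4.0 mcg/mL, so dose = rate x concentration.
#'
#' @return a `dose_table` object: data.frame with columns `step`,
#'   `dose_mcg_min`, `rate_ml_min`, and attribute `concentration` (mcg/mL).
#' @export
dose_table <- function() {
  path <- system.file("extdata", "dose_steps.csv", package = "pclcbench")
  tab <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(diff(tab$rate_ml_min) > 0))
  structure(tab, concentration = 4.0, class = c("dose_table", "data.frame"))
}

#' Convert an infusion rate to a drug dose
#'
#' @param rate infusion rate, mL/min (>= 0).
#' @param table a [dose_table()] object (provides the concentration).
#' @return dose in mcg/min (`rate * concentration`).
#' @export
rate_to_dose <- function(rate, table = dose_table()) {
  if (any(rate < 0)) stop("rate must be non-negative")
  rate * attr(table, "concentration")
}
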