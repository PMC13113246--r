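#' ADRC tuning profile
#'
#' Active disturbance rejection control: a tracking differentiator (TD)
#' smooths the setpoint, an extended state observer (ESO) estimates MAP, its
#' derivative, and a lumped disturbance from the delayed measurement, and a
#' feedback law cancels the estimated disturbance. The observer gains follow
#' the bandwidth parameterization `beta = (3 w0, 3 w0^2, w0^3)`.
#'
#' @param kp,kd feedback gains (per s^2 and per s).
#' @param b system gain: MAP slew per unit infusion rate, mmHg/s per mL/min
#'   (must be nonzero).
#' @param omega0 observer bandwidth, rad/s.
#' @param td_speed tracking-differentiator natural frequency, rad/s.
#' @param max_rate_step largest infusion-rate change per tick, mL/min.
#' @param rate_bounds infusion-rate limits, mL/min.
#' @param kp_adapt_scale error magnitude (mmHg) at which the adaptive
#'   proportional gain reaches twice its nominal value (capped there).
#' @param trend_threshold MAP slope (mmHg/min) beyond which trend-aware
#'   limiting engages: rising faster than `+threshold` blocks further rate
#'   increases; falling faster than `-threshold` halves the allowed decrease.
#' @return an `adrc_tuning` object.
#' @export
adrc_tuning <- function(kp, kd, b = 0.08, omega0 = 0.06, td_speed = 0.03,
                        max_rate_step = 0.06, rate_bounds = c(0, 5),
                        kp_adapt_scale = 20, trend_threshold = 4) {
  if (b == 0) stop("system gain b must be nonzero")
  stopifnot(omega0 > 0, td_speed > 0, max_rate_step > 0, kp > 0, kd >= 0)
  structure(list(kp = kp, kd = kd, b = b,
                 eso_gains = c(3 * omega0, 3 * omega0^2, omega0^3),
                 td_speed = td_speed, max_rate_step = max_rate_step,
                 rate_bounds = rate_bounds, kp_adapt_scale = kp_adapt_scale,
                 trend_threshold = trend_threshold),
            class = "adrc_tuning")
}

#' Initialize ADRC controller state
#'
#' The TD reference and the observer MAP estimate start at the first
#' measurement so that the reference ramps smoothly from the patient's
#' actual pressure toward the setpoint.
#'
#' @param tuning an [adrc_tuning()] object.
#' @param initial_map first MAP measurement, mmHg.
#' @param initial_rate starting infusion rate, mL/min.
#' @param dt controller tick, seconds.
#' @return an `adrc_state` object.
#' @export
adrc_init <- function(tuning, initial_map, initial_rate = 0, dt = 10) {
  stopifnot(inherits(tuning, "adrc_tuning"), dt > 0)
  structure(list(tuning = tuning, dt = dt,
                 v1 = initial_map, v2 = 0,
                 z1 = initial_map, z2 = 0, z3 = 0,
                 current_rate = initial_rate),
            class = "adrc_state")
}

#' Tracking-differentiator update
#'
#' Critically damped second-order tracker: the smoothed reference `v1`
#' approaches the setpoint without overshoot and `v2` carries its
#' derivative; at a constant setpoint `v1 -> setpoint`, `v2 -> 0`.
#'
#' @param v1,v2 current reference and derivative states.
#' @param setpoint target MAP, mmHg.
#' @param dt tick, seconds.
#' @param r tracker natural frequency, rad/s.
#' @return numeric c(v1, v2).
#' @export
td_step <- function(v1, v2, setpoint, dt, r) {
  stopifnot(dt > 0, r > 0)
  v1_new <- v1 + dt * v2
  v2_new <- v2 + dt * (-r^2 * (v1 - setpoint) - 2 * r * v2)
  c(v1 = v1_new, v2 = v2_new)
}

#' Extended state observer update
#'
#' Standard third-order ESO driven by the innovation `e = z1 - measured`:
#' `z1 += dt (z2 - b1 e + b u)`, `z2 += dt (z3 - b2 e)`, `z3 += dt (-b3 e)`.
#' With stable gains `z1` converges to the measurement and `z3` absorbs the
#' lumped disturbance (here, mainly the hemorrhage drift and model error).
#'
#' @param z1,z2,z3 observer states (mmHg, mmHg/s, mmHg/s^2).
#' @param measured_delayed delayed MAP measurement, mmHg.
#' @param u_applied applied infusion rate, mL/min.
#' @param dt tick, seconds.
#' @param beta observer gains (length 3, all positive).
#' @param b system gain.
#' @return numeric c(z1, z2, z3).
#' @export
eso_step <- function(z1, z2, z3, measured_delayed, u_applied, dt, beta, b) {
  stopifnot(dt > 0, length(beta) == 3, all(beta > 0))
  e <- z1 - measured_delayed
  z1_new <- z1 + dt * (z2 - beta[1] * e + b * u_applied)
  z2_new <- z2 + dt * (z3 - beta[2] * e)
  z3_new <- z3 + dt * (-beta[3] * e)
  c(z1 = z1_new, z2 = z2_new, z3 = z3_new)
}

#' ADRC feedback law (before rate limiting)
#'
#' `u = (-kp_eff (z1 - v1) - kd z2 - z3) / b`, the disturbance-cancelling
#' form. The proportional gain is adapted online: it grows linearly with the
#' absolute tracking error up to twice its nominal value at
#' `kp_adapt_scale` mmHg, improving transients during large deviations.
#'
#' @param state an `adrc_state`.
#' @return unclipped control, mL/min.
#' @export
adrc_control <- function(state) {
  tn <- state$tuning
  err <- state$z1 - state$v1
  kp_eff <- tn$kp * min(2, 1 + abs(err) / tn$kp_adapt_scale)
  (-kp_eff * err - tn$kd * state$z2 - state$z3) / tn$b
}

#' One ADRC controller tick
#'
#' TD, ESO and feedback-law updates followed by trend-aware rate limiting:
#' when the estimated MAP slope exceeds `+trend_threshold` mmHg/min further
#' rate increases are blocked; below `-trend_threshold` the allowed decrease
#' is halved (vasopressor tapering restrained during steep decline).
#'
#' @param state an `adrc_state`.
#' @param measured sampled (delayed) MAP, mmHg.
#' @param target target MAP, mmHg.
#' @return list with elements `state` and `rate` (mL/min).
#' @export
adrc_step <- function(state, measured, target) {
  tn <- state$tuning
  v <- td_step(state$v1, state$v2, target, state$dt, tn$td_speed)
  state$v1 <- v[["v1"]]; state$v2 <- v[["v2"]]
  z <- eso_step(state$z1, state$z2, state$z3, measured, state$current_rate,
                state$dt, tn$eso_gains, tn$b)
  state$z1 <- z[["z1"]]; state$z2 <- z[["z2"]]; state$z3 <- z[["z3"]]
  u <- adrc_control(state)
  # trend-aware rate limiting (slope in mmHg/min)
  slope <- state$z2 * 60
  up_cap <- tn$max_rate_step
  down_cap <- tn$max_rate_step
  if (slope > tn$trend_threshold) up_cap <- 0
  if (slope < -tn$trend_threshold) down_cap <- tn$max_rate_step / 2
  delta <- min(up_cap, max(-down_cap, u - state$current_rate))
  rate <- min(tn$rate_bounds[2], max(tn$rate_bounds[1], state$current_rate + delta))
  state$current_rate <- rate
  list(state = state, rate = rate)
}
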