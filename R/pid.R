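#' First-order delay filter for the measured MAP
#'
#' One update of the low-pass filter that models the physiological latency
#' between drug delivery and hemodynamic response:
#' `p + (dt/tau) * (measured - p)`. Fixed point at the measured value;
#' repeated application converges geometrically with ratio `1 - dt/tau`.
#'
#' @param p_delayed current filter state, mmHg.
#' @param p_measured new measurement, mmHg.
#' @param dt controller tick, seconds.
#' @param tau filter time constant, seconds (default 15).
#' @return updated delayed-MAP estimate, mmHg.
#' @export
delay_filter_step <- function(p_delayed, p_measured, dt, tau = 15) {
  if (tau <= 0) stop("tau must be positive")
  stopifnot(dt > 0)
  p_delayed + (dt / tau) * (p_measured - p_delayed)
}

#' PID tuning profile
#'
#' Gains act on the error between target MAP and the delayed MAP estimate
#' (positive error drives the infusion rate up). The raw command
#' `kp*e + ki*I + kd*de/dt` is an infusion-rate increment per tick, clipped
#' to `max_rate_step`; the rate is kept within `rate_bounds`. Near the
#' setpoint (|error| < `antiwindup_band`) the integral accumulator is
#' multiplied by `antiwindup_decay` each tick instead of accumulating.
#'
#' @param kp,ki,kd proportional (per mmHg), integral (per mmHg s) and
#'   derivative (per mmHg/s) gains.
#' @param max_rate_step largest infusion-rate change per tick, mL/min.
#' @param antiwindup_band error band for integral decay, mmHg.
#' @param antiwindup_decay per-tick integral decay factor in (0, 1).
#' @param rate_bounds infusion-rate limits, mL/min.
#' @return a `pid_tuning` object.
#' @export
pid_tuning <- function(kp, ki, kd, max_rate_step,
                       antiwindup_band = 5, antiwindup_decay = 0.95,
                       rate_bounds = c(0, 5)) {
  stopifnot(antiwindup_decay > 0, antiwindup_decay < 1, max_rate_step > 0,
            length(rate_bounds) == 2, rate_bounds[1] >= 0)
  structure(list(kp = kp, ki = ki, kd = kd, max_rate_step = max_rate_step,
                 antiwindup_band = antiwindup_band,
                 antiwindup_decay = antiwindup_decay,
                 rate_bounds = rate_bounds),
            class = "pid_tuning")
}

#' Initialize PID controller state
#'
#' @param tuning a [pid_tuning()] object.
#' @param initial_map first MAP measurement, used to seed the delay filter.
#' @param initial_rate starting infusion rate, mL/min.
#' @param dt controller tick, seconds.
#' @param tau delay-filter time constant, seconds.
#' @return a `pid_state` object.
#' @export
pid_init <- function(tuning, initial_map, initial_rate = 0, dt = 10, tau = 15) {
  stopifnot(inherits(tuning, "pid_tuning"), tau > 0, dt > 0)
  structure(list(tuning = tuning, p_delayed = initial_map,
                 integral_acc = 0, prev_error = NA_real_,
                 current_rate = initial_rate, tau = tau, dt = dt),
            class = "pid_state")
}

#' One PID controller tick
#'
#' Updates the delay filter, forms the error `target - p_delayed`, applies
#' anti-windup integral handling and a backward-difference derivative, and
#' returns the rate-limited infusion command.
#'
#' @param state a `pid_state`.
#' @param measured sampled MAP, mmHg.
#' @param target target MAP, mmHg.
#' @return list with elements `state` (updated) and `rate` (mL/min).
#' @export
pid_step <- function(state, measured, target) {
  stopifnot(measured > 0, measured < 200, target > 0, target < 200)
  tn <- state$tuning
  state$p_delayed <- delay_filter_step(state$p_delayed, measured,
                                       state$dt, state$tau)
  error <- target - state$p_delayed
  if (abs(error) < tn$antiwindup_band) {
    state$integral_acc <- state$integral_acc * tn$antiwindup_decay
  } else {
    state$integral_acc <- state$integral_acc + error * state$dt
  }
  deriv <- if (is.na(state$prev_error)) 0 else (error - state$prev_error) / state$dt
  state$prev_error <- error
  cmd <- tn$kp * error + tn$ki * state$integral_acc + tn$kd * deriv
  delta <- min(tn$max_rate_step, max(-tn$max_rate_step, cmd))
  rate <- min(tn$rate_bounds[2], max(tn$rate_bounds[1], state$current_rate + delta))
  state$current_rate <- rate
  list(state = state, rate = rate)
}
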