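#' Patient-following controller tuning profile
#'
#' The patient-following controller (PFC) steps the dose up only when the
#' gradient of the smoothed relative error indicates that the current
#' dose's effect has saturated. Tuning adjusts the smoothing window
#' (conservative 10 samples, aggressive 5), the dose increment
#' (conservative 0.25 mL/min, aggressive 0.5) and the fraction of the
#' tracked gradient minimum used as the firing threshold (conservative 0.5,
#' aggressive 0.9 -- the aggressive threshold is crossed sooner as the
#' response slows).
#'
#' @param smooth_window rolling-average window for MAP smoothing, samples.
#' @param dose_increment dose step, mL/min.
#' @param threshold_frac fraction of the tracked gradient minimum.
#' @param rate_bounds infusion-rate limits, mL/min.
#' @return a `pfc_tuning` object.
#' @export
pfc_tuning <- function(smooth_window, dose_increment, threshold_frac,
                       rate_bounds = c(0, 5)) {
  stopifnot(smooth_window >= 1, dose_increment > 0,
            threshold_frac > 0, threshold_frac < 1)
  structure(list(smooth_window = smooth_window,
                 dose_increment = dose_increment,
                 threshold_frac = threshold_frac,
                 rate_bounds = rate_bounds),
            class = "pfc_tuning")
}

#' Initialize PFC state
#'
#' The controller starts at the first step of the dosing table
#' (0.13 mL/min) so that a vasopressor response exists to follow.
#'
#' @param tuning a [pfc_tuning()] object.
#' @param initial_rate starting infusion rate, mL/min.
#' @param dt controller tick, seconds.
#' @return a `pfc_state` object.
#' @export
pfc_init <- function(tuning, initial_rate = 0.13, dt = 10) {
  structure(list(tuning = tuning, dt = dt,
                 map_buffer = numeric(0),     # for rolling-average smoothing
                 e_buffer = numeric(0),       # last 5 relative errors
                 grad_min = NA_real_,
                 consec_count = 0L,
                 current_rate = initial_rate),
            class = "pfc_state")
}

#' Relative error of the smoothed MAP
#'
#' `e = (target - smoothed_map) / target`: 0 at target, positive below it,
#' negative on overshoot.
#'
#' @param smoothed_map rolling-average MAP, mmHg.
#' @param target target MAP, mmHg (> 0).
#' @return dimensionless relative error.
#' @export
relative_error <- function(smoothed_map, target) {
  stopifnot(target > 0)
  (target - smoothed_map) / target
}

#' Sliding-window error gradient
#'
#' Least-squares slope of the last five relative-error samples against
#' time. A least-squares slope (rather than an endpoint difference) is
#' robust to sample noise within the window.
#'
#' @param buffer exactly five relative-error values, oldest first.
#' @param tick sample spacing, seconds.
#' @return slope per second, or `NA` if the buffer is not yet full.
#' @export
error_gradient <- function(buffer, tick) {
  if (length(buffer) < 5) return(NA_real_)
  stopifnot(length(buffer) == 5, tick > 0)
  t <- seq(0, by = tick, length.out = 5)
  sum((t - mean(t)) * (buffer - mean(buffer))) / sum((t - mean(t))^2)
}

#' Track the local minimum of the error gradient
#'
#' The tracked minimum is only replaced by a new gradient that is at most
#' `1.05 * grad_min` (i.e. at least 5 % more negative than the current
#' minimum), so noise-level wiggles do not reset the reference.
#'
#' @param grad_min current tracked minimum (NA before tracking starts).
#' @param grad new gradient value.
#' @return updated tracked minimum.
#' @export
update_grad_min <- function(grad_min, grad) {
  if (is.na(grad_min)) return(grad)
  if (grad <= 1.05 * grad_min) grad else grad_min
}

#' One patient-following controller tick
#'
#' Smooths the MAP with a rolling average, converts it to a relative error,
#' computes the five-sample least-squares error gradient, and tracks the
#' gradient's local minimum. A sample qualifies when the gradient has risen
#' strictly above `threshold_frac * grad_min` (the response is flattening);
#' after five consecutive qualifying samples with MAP not within 1 % of the
#' target, the dose is increased by the tuning's increment and the gradient
#' tracking resets. Dose decreases (weaning) are out of scope: the rate
#' sequence is non-decreasing.
#'
#' @param state a `pfc_state`.
#' @param measured sampled MAP, mmHg.
#' @param target target MAP, mmHg.
#' @return list with elements `state` and `rate` (mL/min).
#' @export
pfc_tick <- function(state, measured, target) {
  stopifnot(target > 0)
  tn <- state$tuning
  state$map_buffer <- c(state$map_buffer, measured)
  if (length(state$map_buffer) > tn$smooth_window) {
    state$map_buffer <- state$map_buffer[-1L]
  }
  e <- relative_error(mean(state$map_buffer), target)
  state$e_buffer <- c(state$e_buffer, e)
  if (length(state$e_buffer) > 5) state$e_buffer <- state$e_buffer[-1L]
  grad <- error_gradient(state$e_buffer, state$dt)
  if (!is.na(grad)) {
    state$grad_min <- update_grad_min(state$grad_min, grad)
    qualifying <- !is.na(state$grad_min) && state$grad_min < 0 &&
      grad > tn$threshold_frac * state$grad_min
    if (qualifying) {
      state$consec_count <- state$consec_count + 1L
    } else {
      state$consec_count <- 0L
    }
    if (state$consec_count >= 5L && abs(measured - target) > 0.01 * target) {
      new_rate <- min(tn$rate_bounds[2], state$current_rate + tn$dose_increment)
      state$current_rate <- new_rate
      state$grad_min <- NA_real_
      state$consec_count <- 0L
      state$e_buffer <- numeric(0)  # track the response to the new dose
    }
  }
  list(state = state, rate = state$current_rate)
}
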