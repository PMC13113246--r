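#' Linear Z-, triangular, and S-shaped membership functions
#'
#' The three-label membership family used for both fuzzy controller inputs:
#' `Negative` is a linear Z-shape (1 at and below `lo`, falling to 0 at
#' `hi`), `Zero` a triangle, and `Positive` a linear S-shape (0 at `lo`,
#' saturating at 1 from `hi` on).
#'
#' @param x input value(s).
#' @param lo,hi breakpoints.
#' @param a,b,c triangle breakpoints (foot, peak, foot).
#' @return membership degree(s) in [0, 1].
#' @name membership
NULL

#' @rdname membership
#' @export
zmf_linear <- function(x, lo, hi) {
  stopifnot(lo < hi)
  pmin(1, pmax(0, (hi - x) / (hi - lo)))
}

#' @rdname membership
#' @export
smf_linear <- function(x, lo, hi) {
  stopifnot(lo < hi)
  pmin(1, pmax(0, (x - lo) / (hi - lo)))
}

#' @rdname membership
#' @export
trimf <- function(x, a, b, c) {
  stopifnot(a < b, b < c)
  pmax(0, pmin((x - a) / (b - a), (c - x) / (c - b)))
}

#' Membership set for one fuzzy input
#'
#' Bundles the three labels over a stated domain. Defaults define the error
#' input in percent of target: negative deviations saturate at -20 %, the
#' zero band spans +-5 %, positive deviations saturate at +20 %.
#'
#' @param neg c(lo, hi) for the Z-shaped Negative label.
#' @param zero c(a, b, c) for the triangular Zero label.
#' @param pos c(lo, hi) for the S-shaped Positive label.
#' @param domain input range (documentation of intent; not enforced).
#' @return a `membership_set` object with functions `negative`, `zero`,
#'   `positive`.
#' @export
membership_set <- function(neg = c(-20, -2), zero = c(-5, 0, 5),
                           pos = c(2, 20), domain = c(-100, 100)) {
  force(neg); force(zero); force(pos)
  structure(list(
    negative = function(x) zmf_linear(x, neg[1], neg[2]),
    zero = function(x) trimf(x, zero[1], zero[2], zero[3]),
    positive = function(x) smf_linear(x, pos[1], pos[2]),
    domain = domain), class = "membership_set")
}

#' Default membership sets for the rule-based controller
#'
#' Error is in percent of target; its rate of change in percent per second.
#' The rate breakpoints reflect physiologically plausible MAP slews (a fast
#' vasopressor response moves MAP by roughly 0.1-0.2 % of target per
#' second).
#' @return list with elements `error` and `rate`, each a [membership_set()].
#' @export
stepfis_memberships <- function() {
  list(error = membership_set(neg = c(-20, -2), zero = c(-5, 0, 5),
                              pos = c(2, 20), domain = c(-100, 100)),
       rate = membership_set(neg = c(-0.3, -0.02), zero = c(-0.15, 0, 0.15),
                             pos = c(0.02, 0.3), domain = c(-1, 1)))
}

#' Rule base of the step fuzzy controller
#'
#' Five IF-THEN rules over (error, rate-of-change) labels with consequents
#' Increase (+1), Maintain (0), Decrease (-1); the Decrease rule carries a
#' reduced weight of 0.75 so dose withdrawal is attenuated.
#'
#' @return data.frame with columns `rule`, `error`, `rate`, `consequent`,
#'   `weight`.
#' @export
stepfis_rules <- function() {
  path <- system.file("extdata", "stepfis_rules.csv", package = "pclcbench")
  rules <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(nrow(rules) == 5, all(rules$weight > 0), all(rules$weight <= 1))
  rules
}

#' Sugeno inference of the rule base
#'
#' Each rule fires with strength equal to the minimum of its antecedent
#' memberships (`Any` contributes 1). The crisp output is the
#' firing-strength-weighted average of the weighted consequents,
#' `sum(s_i * w_i * c_i) / sum(s_i)`, bounded in [-1, 1]: the rule weight
#' attenuates a rule's contribution (a lone Decrease rule yields -0.75, the
#' attenuated decrease plateau of the control surface), while the
#' normalization uses the raw firing strengths.
#'
#' @param error filtered error, percent of target (negative below target).
#' @param error_rate error derivative, percent per second.
#' @param rules rule base as from [stepfis_rules()].
#' @param memberships list(error=, rate=) of [membership_set()]s.
#' @return crisp output in [-1, 1]; 0 (Maintain) if no rule fires.
#' @export
fis_output <- function(error, error_rate, rules = stepfis_rules(),
                       memberships = stepfis_memberships()) {
  grade <- function(ms, label, x) {
    switch(label,
           Negative = ms$negative(x), Zero = ms$zero(x),
           Positive = ms$positive(x), Any = 1,
           stop("unknown label: ", label))
  }
  s <- vapply(seq_len(nrow(rules)), function(i) {
    min(grade(memberships$error, rules$error[i], error),
        grade(memberships$rate, rules$rate[i], error_rate))
  }, numeric(1))
  if (sum(s) <= 0) return(0)
  sum(s * rules$weight * rules$consequent) / sum(s)
}

#' Adaptive step size
#'
#' Doubles the base step when the filtered absolute error exceeds 30 % of
#' target (rapid correction of large deviations) and halves it below 3 %
#' (fine convergence near target); unchanged in between.
#'
#' @param base_step baseline step, mL/min.
#' @param abs_error absolute filtered error, percent of target.
#' @return step to apply this tick, mL/min.
#' @export
adapt_step <- function(base_step, abs_error) {
  stopifnot(abs_error >= 0, base_step > 0)
  if (abs_error > 30) 2 * base_step
  else if (abs_error < 3) base_step / 2
  else base_step
}

#' Online first-order Butterworth low-pass filter
#'
#' Designs the coefficients with [signal::butter()] (order 1) for the given
#' cutoff and tick, and applies the difference equation one sample at a
#' time, so the controller can filter its measurement stream online.
#' DC gain is 1.
#'
#' @param cutoff_hz cutoff frequency; must lie in (0, Nyquist) for the tick.
#' @param dt sampling interval of the stream, seconds.
#' @return a stateful filter object; call `obj$step(x)` per sample.
#' @export
butterworth_filter <- function(cutoff_hz, dt) {
  nyquist <- 1 / (2 * dt)
  if (!(cutoff_hz > 0 && cutoff_hz < nyquist)) {
    stop("cutoff must be in (0, Nyquist) = (0, ", nyquist, ") Hz")
  }
  ba <- signal::butter(1, cutoff_hz / nyquist, type = "low")
  env <- new.env()
  env$x_prev <- NA_real_
  env$y_prev <- NA_real_
  step <- function(x) {
    if (is.na(env$y_prev)) {  # initialize at first sample (no startup edge)
      env$x_prev <- x; env$y_prev <- x
      return(x)
    }
    y <- ba$b[1] * x + ba$b[2] * env$x_prev - ba$a[2] * env$y_prev
    env$x_prev <- x; env$y_prev <- y
    y
  }
  structure(list(step = step, coef = ba), class = "butter_filter")
}

#' Step-FIS tuning profile
#'
#' @param base_step baseline unit step, mL/min (aggressive 0.035,
#'   conservative 0.025).
#' @param cutoff_hz Butterworth cutoff for the MAP filter.
#' @param decision_band the crisp output must exceed +1/3 (increase) or fall
#'   below -1/3 (decrease) to act; the middle band holds the rate.
#' @param rate_bounds infusion-rate limits, mL/min.
#' @return a `stepfis_tuning` object.
#' @export
stepfis_tuning <- function(base_step, cutoff_hz = 0.01, decision_band = 1 / 3,
                           rate_bounds = c(0, 5)) {
  stopifnot(base_step > 0, decision_band > 0, decision_band < 1)
  structure(list(base_step = base_step, cutoff_hz = cutoff_hz,
                 decision_band = decision_band, rate_bounds = rate_bounds),
            class = "stepfis_tuning")
}

#' Initialize Step-FIS controller state
#'
#' @param tuning a [stepfis_tuning()] object.
#' @param initial_rate starting infusion rate, mL/min.
#' @param dt controller tick, seconds.
#' @return a `stepfis_state` object.
#' @export
stepfis_init <- function(tuning, initial_rate = 0, dt = 10) {
  structure(list(tuning = tuning, dt = dt,
                 filter = butterworth_filter(tuning$cutoff_hz, dt),
                 rules = stepfis_rules(),
                 memberships = stepfis_memberships(),
                 prev_error = NA_real_,
                 current_rate = initial_rate),
            class = "stepfis_state")
}

#' One Step-FIS controller tick
#'
#' Filters the measurement, forms the signed relative error (measured below
#' target is negative) and its derivative, runs the Sugeno inference, and
#' converts the crisp output into unit-step logic: above +1/3 the rate is
#' increased by the current (error-adapted) step, below -1/3 decreased,
#' otherwise held. The rate is clamped to its bounds.
#'
#' @param state a `stepfis_state`.
#' @param measured sampled MAP, mmHg.
#' @param target target MAP, mmHg (> 0).
#' @return list with elements `state` and `rate` (mL/min).
#' @export
stepfis_tick <- function(state, measured, target) {
  stopifnot(target > 0)
  tn <- state$tuning
  filt <- state$filter$step(measured)
  error <- 100 * (filt - target) / target
  error_rate <- if (is.na(state$prev_error)) 0 else
    (error - state$prev_error) / state$dt
  state$prev_error <- error
  out <- fis_output(error, error_rate, state$rules, state$memberships)
  step <- adapt_step(tn$base_step, abs(error))
  rate <- state$current_rate
  if (out > tn$decision_band) rate <- rate + step
  else if (out < -tn$decision_band) rate <- rate - step
  rate <- min(tn$rate_bounds[2], max(tn$rate_bounds[1], rate))
  state$current_rate <- rate
  list(state = state, rate = rate)
}
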