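test_that("delay filter matches its closed form", {
  # one update from 50 toward 60 with dt = 1, tau = 15
  expect_equal(delay_filter_step(50, 60, dt = 1, tau = 15),
               50 + (1 / 15) * 10, tolerance = 1e-12)  # 50.6667
  # fixed point at the measurement
  expect_equal(delay_filter_step(60, 60, dt = 1, tau = 15), 60)
  # geometric convergence with ratio 1 - dt/tau
  p <- 50
  errs <- numeric(5)
  for (i in 1:5) {
    p <- delay_filter_step(p, 60, dt = 1, tau = 15)
    errs[i] <- 60 - p
  }
  expect_equal(errs[-1] / errs[-5], rep(1 - 1 / 15, 4), tolerance = 1e-12)
  expect_error(delay_filter_step(50, 60, dt = 1, tau = 0), "positive")
})

test_that("pid_step holds the rate at zero error and decays the integral", {
  tn <- pid_tuning(kp = 0.01, ki = 1e-4, kd = 0.05, max_rate_step = 0.06)
  st <- pid_init(tn, initial_map = 65, initial_rate = 1)
  st$integral_acc <- 10
  res <- pid_step(st, measured = 65, target = 65)
  # inside the 5 mmHg anti-windup band the accumulator decays by 0.95
  expect_equal(res$state$integral_acc, 9.5)
  # the residual integral action is far below the rate quantum here
  expect_equal(res$rate, 1 + min(0.06, 1e-4 * 9.5), tolerance = 1e-9)
})

test_that("pid_step saturates at the per-tick rate limit and the bounds", {
  tn <- pid_tuning(kp = 1, ki = 0, kd = 0, max_rate_step = 0.06)
  st <- pid_init(tn, initial_map = 35, initial_rate = 0)
  res <- pid_step(st, measured = 35, target = 65)  # huge error
  expect_equal(res$rate, 0.06)  # clipped to one rate step
  st <- pid_init(tn, initial_map = 35, initial_rate = 4.99)
  res <- pid_step(st, measured = 35, target = 65)
  expect_equal(res$rate, 5)     # clamped at the upper bound
  st <- pid_init(tn, initial_map = 80, initial_rate = 0.03)
  res <- pid_step(st, measured = 80, target = 65)
  expect_equal(res$rate, 0)     # clamped at zero
})

test_that("PID with ki = kd = 0 reduces to rate-limited proportional control", {
  tn <- pid_tuning(kp = 0.02, ki = 0, kd = 0, max_rate_step = 0.06)
  st <- pid_init(tn, initial_map = 40, initial_rate = 0, dt = 10, tau = 15)
  measured <- seq(40, 64, length.out = 25)
  p_delayed <- 40
  rate_oracle <- 0
  for (m in measured) {
    res <- pid_step(st, m, 65)
    st <- res$state
    # independent oracle: delay filter + clipped proportional increment
    p_delayed <- p_delayed + (10 / 15) * (m - p_delayed)
    delta <- max(-0.06, min(0.06, 0.02 * (65 - p_delayed)))
    rate_oracle <- max(0, min(5, rate_oracle + delta))
    expect_equal(res$rate, rate_oracle, tolerance = 1e-12)
  }
})

test_that("tracking differentiator approaches the setpoint without overshoot", {
  v <- c(35, 0)
  v1s <- numeric(600)
  for (i in seq_along(v1s)) {
    v <- td_step(v[1], v[2], setpoint = 65, dt = 1, r = 0.05)
    v1s[i] <- v[1]
  }
  expect_true(all(v1s <= 65 + 1e-9))       # critically damped: no overshoot
  expect_true(all(diff(v1s) >= -1e-12))    # monotone approach
  expect_equal(v1s[length(v1s)], 65, tolerance = 0.5)
  # at the setpoint the tracker is at equilibrium
  v <- td_step(65, 0, setpoint = 65, dt = 1, r = 0.05)
  expect_equal(unname(v), c(65, 0))
})

test_that("ESO is at equilibrium when consistent and converges otherwise", {
  beta <- c(3 * 0.06, 3 * 0.06^2, 0.06^3)
  # consistent state, zero input: nothing moves
  z <- eso_step(60, 0, 0, measured_delayed = 60, u_applied = 0,
                dt = 10, beta = beta, b = 0.08)
  expect_equal(unname(z), c(60, 0, 0))
  # with b = 0 the observer ignores the input channel
  z1 <- eso_step(50, 0, 0, 60, u_applied = 0, dt = 10, beta = beta, b = 0)
  z2 <- eso_step(50, 0, 0, 60, u_applied = 3, dt = 10, beta = beta, b = 0)
  expect_identical(z1, z2)
  # observer error decays below 1 mmHg within 60 s (6 ticks) from 10 mmHg off
  z <- c(50, 0, 0)
  for (k in 1:6) z <- eso_step(z[1], z[2], z[3], 60, 0, 10, beta, 0.08)
  expect_lt(abs(z[1] - 60), 1)
})

test_that("adrc_control implements the disturbance-cancelling law", {
  # with a huge adaptation scale the gain stays nominal: u = -kp*(z1-v1)/b
  tn <- adrc_tuning(kp = 1, kd = 0, b = 1, kp_adapt_scale = 1e9)
  st <- adrc_init(tn, initial_map = 60)
  st$v1 <- 65; st$z1 <- 60; st$z2 <- 0; st$z3 <- 0
  expect_equal(adrc_control(st), 5)
  # adaptive gain doubles (and caps) at large errors
  tn2 <- adrc_tuning(kp = 1, kd = 0, b = 1, kp_adapt_scale = 20)
  st$tuning <- tn2
  st$z1 <- 65 - 40  # |err| = 40 = 2 x scale, capped at 2x
  expect_equal(adrc_control(st), 2 * 40)
  # the z3 estimate is cancelled through b
  st$tuning <- tn <- adrc_tuning(kp = 1, kd = 0, b = 0.08, kp_adapt_scale = 1e9)
  st$z1 <- st$v1 <- 65; st$z2 <- 0; st$z3 <- -0.004
  expect_equal(adrc_control(st), 0.004 / 0.08)
})

test_that("adrc trend-aware limiting blocks increases during a steep rise", {
  tn <- adrc_tuning(kp = 5, kd = 0, omega0 = 0.06, max_rate_step = 0.06,
                    trend_threshold = 4)
  st <- adrc_init(tn, initial_map = 55, initial_rate = 1, dt = 10)
  st$z2 <- 0.1  # estimated slope 6 mmHg/min > threshold
  res <- adrc_step(st, measured = 55, target = 65)
  expect_lte(res$rate, 1)  # increase blocked despite the large error
  # steep decline halves the allowed decrease: with a strongly negative
  # control demand the step is -max_rate_step/2 instead of -max_rate_step
  st <- adrc_init(tn, initial_map = 80, initial_rate = 1, dt = 10)
  st$v1 <- 65   # reference already at target: large positive tracking error
  st$z2 <- -0.1 # estimated slope -6 mmHg/min < -threshold
  res <- adrc_step(st, measured = 80, target = 65)
  expect_equal(res$rate, 1 - 0.06 / 2, tolerance = 1e-12)
})
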