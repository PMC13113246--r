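test_that("membership functions match their piecewise-linear definitions", {
  expect_equal(zmf_linear(c(-25, -20, -11, -2, 0), -20, -2),
               c(1, 1, 0.5, 0, 0))
  expect_equal(smf_linear(c(0, 2, 11, 20, 30), 2, 20),
               c(0, 0, 0.5, 1, 1))
  expect_equal(trimf(c(-5, -2.5, 0, 2.5, 5), -5, 0, 5),
               c(0, 0.5, 1, 0.5, 0))
  expect_error(trimf(0, 1, 0, 2))
})

test_that("rule base holds the five printed rules with the Decrease weight", {
  rules <- stepfis_rules()
  expect_equal(nrow(rules), 5)
  expect_setequal(rules$consequent, c(-1, 0, 1))
  dec <- rules[rules$consequent == -1, ]
  expect_equal(nrow(dec), 1)
  expect_equal(dec$weight, 0.75)  # attenuated dose withdrawal
  expect_true(all(rules$weight[rules$consequent != -1] == 1))
})

test_that("fis_output reproduces the control-surface plateaus", {
  # deep below target, flat: only the Increase rule fires fully
  expect_equal(fis_output(-40, 0), 1)
  # deep above target, falling: only the weighted Decrease rule fires,
  # giving the attenuated -0.75 plateau
  expect_equal(fis_output(40, -0.25), -0.75)
  # at target, flat: Maintain
  expect_equal(fis_output(0, 0), 0)
})

test_that("fis_output is bounded and monotone along the flat-rate slice", {
  grid_e <- seq(-60, 60, by = 3)
  grid_r <- seq(-0.5, 0.5, by = 0.05)
  vals <- outer(grid_e, grid_r, Vectorize(function(e, r) fis_output(e, r)))
  expect_true(all(vals >= -1 & vals <= 1))
  # more positive error (MAP above target) never asks for more drug
  slice <- vapply(grid_e, function(e) fis_output(e, 0), numeric(1))
  expect_true(all(diff(slice) <= 1e-12))
})

test_that("adapt_step implements the 3 % / 30 % rules", {
  expect_equal(adapt_step(0.035, 31), 0.07)    # doubled above 30 %
  expect_equal(adapt_step(0.035, 15), 0.035)   # unchanged in between
  expect_equal(adapt_step(0.035, 2.9), 0.0175) # halved below 3 %
  expect_equal(adapt_step(0.025, 30), 0.025)   # boundary: not doubled
  expect_equal(adapt_step(0.025, 3), 0.025)    # boundary: not halved
})

test_that("butterworth filter has unit DC gain and low-pass behavior", {
  f <- butterworth_filter(cutoff_hz = 0.01, dt = 10)
  # constant input is passed through unchanged from the first sample
  ys <- vapply(1:50, function(i) f$step(42), numeric(1))
  expect_equal(ys, rep(42, 50))
  # a step input converges to the new level (DC gain 1)
  f2 <- butterworth_filter(0.01, 10)
  f2$step(0)
  ys2 <- vapply(1:200, function(i) f2$step(10), numeric(1))
  expect_true(all(diff(ys2) >= -1e-12))
  expect_equal(ys2[200], 10, tolerance = 1e-6)
  # first-order pole: successive step-response errors decay geometrically
  errs <- 10 - ys2[1:10]
  ratios <- errs[-1] / errs[-10]
  expect_equal(ratios, rep(ratios[1], 9), tolerance = 1e-9)
  expect_error(butterworth_filter(0, 10), "Nyquist")
  expect_error(butterworth_filter(0.06, 10), "Nyquist")  # above 0.05 Hz
})

test_that("stepfis_tick applies the unit-step logic with adaptive steps", {
  tn <- stepfis_tuning(base_step = 0.025)
  # at target: rate held
  st <- stepfis_init(tn, initial_rate = 1)
  res <- stepfis_tick(st, measured = 65, target = 65)
  expect_equal(res$rate, 1)
  # measured 55 (error -15.4 %, inside the 3-30 % band), flat: exactly one
  # base step up
  st <- stepfis_init(tn, initial_rate = 1)
  res <- stepfis_tick(st, measured = 55, target = 65)
  expect_equal(res$rate, 1 + 0.025)
  # measured 45 (error -30.8 %, beyond 30 %): doubled step
  st <- stepfis_init(tn, initial_rate = 1)
  res <- stepfis_tick(st, measured = 45, target = 65)
  expect_equal(res$rate, 1 + 0.05)
  # slightly below target (error -1.5 %, under 3 %): the Zero-error rule
  # dominates and the rate is held
  st <- stepfis_init(tn, initial_rate = 1)
  res <- stepfis_tick(st, measured = 64, target = 65)
  expect_equal(res$rate, 1)
  # decreases clamp at zero
  st <- stepfis_init(tn, initial_rate = 0)
  res <- stepfis_tick(st, measured = 90, target = 65)
  expect_equal(res$rate, 0)
})

test_that("gbellmf is 1 at the center and decays symmetrically", {
  expect_equal(gbellmf(3, a = 2, b = 2, c = 3), 1)
  expect_equal(gbellmf(5, 2, 2, 3), 1 / (1 + 1))  # |x-c| = a: always 1/2
  expect_equal(gbellmf(1, 2, 2, 3), gbellmf(5, 2, 2, 3))
  expect_true(all(gbellmf(seq(-50, 50, 0.5), 2, 2, 3) > 0))
  expect_error(gbellmf(0, a = -1, b = 2, c = 0))
})

test_that("anfis_forward mixes consequents by normalized firing strengths", {
  pe <- cbind(a = rep(10, 3), b = rep(2, 3), c = c(-20, 0, 20))
  pr <- cbind(a = rep(0.2, 3), b = rep(2, 3), c = c(-0.3, 0, 0.3))
  # all-constant consequents: output is that constant everywhere
  m <- anfis_model(pe, pr, cbind(p = rep(0, 9), q = rep(0, 9), r = rep(2.5, 9)))
  xs <- seq(-40, 40, by = 5)
  expect_equal(anfis_forward(m, xs, rep(0, length(xs))),
               rep(2.5, length(xs)), tolerance = 1e-12)
  # linear consequents shared by all rules: output is that linear function
  m2 <- anfis_model(pe, pr, cbind(p = rep(-0.05, 9), q = rep(0, 9),
                                  r = rep(2, 9)))
  expect_equal(anfis_forward(m2, xs, rep(0, length(xs))),
               2 - 0.05 * xs, tolerance = 1e-12)
  # at an input far into one membership region, the matching rule dominates
  m3 <- anfis_model(pe, pr, cbind(p = rep(0, 9), q = rep(0, 9), r = 1:9))
  # error near MF1 center (-20), rate near MF3 center (0.3): rule (1,3) = 3
  expect_equal(anfis_forward(m3, -20, 0.3), 3, tolerance = 0.05)
})

test_that("anfis model JSON round-trips exactly", {
  pe <- cbind(a = c(5, 6, 7), b = c(2, 2.5, 2), c = c(-20, 0, 20))
  pr <- cbind(a = rep(0.2, 3), b = rep(2, 3), c = c(-0.3, 0, 0.3))
  cq <- matrix(seq(-1, 1, length.out = 27), 9, 3)
  m <- anfis_model(pe, pr, cq)
  path <- tempfile(fileext = ".json")
  anfis_write(m, path)
  m2 <- anfis_read(path)
  expect_equal(unclass(m2$premise_error), unclass(m$premise_error),
               ignore_attr = TRUE)
  expect_equal(unclass(m2$premise_rate), unclass(m$premise_rate),
               ignore_attr = TRUE)
  expect_equal(unclass(m2$consequents), unclass(m$consequents),
               ignore_attr = TRUE)
  unlink(path)
})

test_that("hybrid training recovers a synthetic model within 5 % RMSE", {
  # ground-truth 9-rule model
  pe <- cbind(a = rep(15, 3), b = rep(2, 3), c = c(-40, -10, 5))
  pr <- cbind(a = rep(0.15, 3), b = rep(2, 3), c = c(-0.3, 0, 0.3))
  set.seed(11)
  cq <- cbind(p = runif(9, -0.05, 0), q = runif(9, -2, 0), r = runif(9, 0, 4))
  truth <- anfis_model(pe, pr, cq)
  grid <- expand.grid(error = seq(-50, 10, length.out = 25),
                      error_rate = seq(-0.4, 0.4, length.out = 11))
  dose <- anfis_forward(truth, grid$error, grid$error_rate)
  dose <- pmax(0, pmin(5, dose))
  fit <- anfis_train(data.frame(grid, dose = dose), seed = 5)
  expect_lt(fit$meta$test_rmse, 0.05 * 5)  # < 5 % of the 0-5 mL/min range
  # the per-epoch history is non-increasing (LS step cannot hurt and the
  # gradient step is only accepted on improvement)
  expect_true(all(diff(fit$meta$history) <= 1e-9))
  # determinism
  fit2 <- anfis_train(data.frame(grid, dose = dose), seed = 5)
  expect_equal(fit$meta$train_rmse, fit2$meta$train_rmse, tolerance = 1e-12)
})

test_that("safeguard_scale weights the dose by the deviation from target", {
  # at target the multiplier is exactly 1
  expect_equal(safeguard_scale(2, 0, gain = -0.01), 2)
  # below target (negative error) a negative gain increases the dose
  expect_equal(safeguard_scale(2, -20, gain = -0.01), 2 * 1.2)
  # multiplier clamps at its bounds
  expect_equal(safeguard_scale(2, -200, gain = -0.01, bounds = c(0.5, 1.5)),
               2 * 1.5)
  expect_equal(safeguard_scale(2, 200, gain = -0.01, bounds = c(0.5, 1.5)),
               2 * 0.5)
  # the dose itself clamps at the dose bounds
  expect_equal(safeguard_scale(4.5, -20, gain = -0.01), 5)
})

test_that("shipped neuro-fuzzy models load and command sane doses", {
  for (id in c("anfis_aggressive", "anfis_conservative")) {
    path <- system.file("extdata", paste0(id, ".json"), package = "pclcbench")
    m <- anfis_read(path)
    grid <- expand.grid(e = seq(-50, 10, by = 2), r = seq(-0.4, 0.4, by = 0.1))
    out <- anfis_forward(m, grid$e, grid$r)
    expect_true(all(is.finite(out)))
    # deep hypotension with MAP still falling must demand substantial drug
    expect_gt(anfis_forward(m, -45, -0.1), 2)
    # at target and flat, the commanded dose is a moderate holding rate
    hold <- anfis_forward(m, 0, 0)
    expect_gt(hold, 0.5)
    expect_lt(hold, 4)
  }
})
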