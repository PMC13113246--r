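test_that("pclc_trace validates its contract", {
  t <- seq(0, 100, by = 10)
  expect_s3_class(pclc_trace(t, rep(65, 11), rep(1, 11), 65), "pclc_trace")
  expect_error(pclc_trace(c(0, 10, 10), rep(65, 3), rep(1, 3), 65),
               "strictly increasing")
  expect_error(pclc_trace(c(0, 10, 25), rep(65, 3), rep(1, 3), 65),
               "uniformly")
  expect_error(pclc_trace(t, rep(65, 11), rep(1, 11), target = -1))
})

test_that("trace CSV round-trips through write_trace/read_trace", {
  tr <- trace_from_pe(c(-10, -5, 0, 2, 1, 0, 0), target = 65)
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  expect_equal(tr2$map_mmhg, tr$map_mmhg)
  expect_equal(tr2$infusion_ml_min, tr$infusion_ml_min)
  expect_equal(attr(tr2, "target"), 65)
  expect_equal(attr(tr2, "duration"), attr(tr, "duration"))
  unlink(path)
})

test_that("performance error is percent of target", {
  expect_equal(performance_error(68.25, 65), 5)
  expect_equal(performance_error(61.75, 65), -5)
  expect_equal(performance_error(65, 65), 0)
})

test_that("mdpe, mdape and wobble on a frozen PE sample", {
  tr <- trace_from_pe(c(-2, 0, 2))
  expect_equal(mdpe(tr), 0)
  expect_equal(mdape(tr), 2)
  expect_equal(wobble(tr), 2)
  # constant bias: mdpe = mdape, wobble = 0
  tr2 <- trace_from_pe(rep(2, 10))
  expect_equal(mdpe(tr2), 2)
  expect_equal(mdape(tr2), 2)
  expect_equal(wobble(tr2), 0)
})

test_that("mdape dominates |mdpe| on random traces", {
  set.seed(2)
  for (i in 1:20) {
    tr <- trace_from_pe(stats::rnorm(60, mean = stats::runif(1, -5, 5), sd = 3))
    expect_gte(mdape(tr), abs(mdpe(tr)))
  }
})

test_that("rise_time interpolates the 90 % crossing", {
  # climb 35 -> 65 linearly over 10 min: 0.9*65 = 58.5 is crossed at
  # t = 600*(58.5-35)/30 = 470 s
  t <- seq(0, 1800, by = 10)
  m <- ifelse(t <= 600, 35 + 30 * t / 600, 65)
  tr <- pclc_trace(t, m, rep(1, length(t)), 65)
  expect_equal(rise_time(tr), 470 / 60, tolerance = 1e-9)
  # already above threshold at start
  expect_equal(rise_time(constant_trace()), 0)
  # never reached: sentinel = run duration in minutes
  low <- pclc_trace(t, rep(40, length(t)), rep(1, length(t)), 65)
  expect_equal(rise_time(low), 30)
})

test_that("mdape_ss restricts to post-rise samples with a fallback window", {
  # 20-min climb then constant at +1 %: steady-state error is exactly 1
  t <- seq(0, 1800, by = 10)
  m <- ifelse(t <= 1200, 35 + 30 * t / 1200, 65 * 1.01)
  tr <- pclc_trace(t, m, rep(1, length(t)), 65)
  expect_equal(mdape_ss(tr), 1, tolerance = 0.01)
  # whole-run MDAPE includes the climb and is much larger
  expect_gt(mdape(tr), mdape_ss(tr))
  # never-reaching trace: final-third fallback still yields a value
  low <- pclc_trace(t, rep(40, length(t)), rep(1, length(t)), 65)
  expect_equal(mdape_ss(low), 100 * 25 / 65, tolerance = 1e-9)
})

test_that("effectiveness counts the +-5 mmHg band", {
  t <- seq(0, 990, by = 10)  # 100 samples
  m <- c(rep(65, 60), rep(72, 40))  # 60 in band, 40 out (7 mmHg off)
  tr <- pclc_trace(t, m, rep(1, 100), 65)
  expect_equal(effectiveness(tr), 60)
  expect_equal(effectiveness(constant_trace()), 100)
  # boundary: exactly 5 mmHg off counts as in-band
  tr2 <- pclc_trace(c(0, 10), c(60, 70), c(1, 1), 65)
  expect_equal(effectiveness(tr2), 100)
})

test_that("target_overshoot is the peak excess, floored at zero", {
  tr <- trace_from_pe(c(-10, 0, 5, 3, 0))
  expect_equal(target_overshoot(tr), 5)
  under <- trace_from_pe(c(-10, -5, -1))
  expect_equal(target_overshoot(under), 0)
})

test_that("area metrics equal their plateau closed forms", {
  ref <- generate_reference_traces()
  # +5 % plateau equivalent to a 4-minute rectangle: area 0.2 min
  expect_equal(area_above(ref$traces$plateau_above),
               ref$manifest$plateau_above$area_above, tolerance = 1e-9)
  expect_equal(target_overshoot(ref$traces$plateau_above), 5,
               tolerance = 1e-9)
  # -10 % plateau after reaching target: area -0.3 min
  expect_equal(area_below(ref$traces$plateau_below),
               ref$manifest$plateau_below$area_below, tolerance = 1e-9)
  expect_lte(area_below(ref$traces$plateau_below), 0)
  expect_equal(area_above(constant_trace()), 0)
  expect_equal(area_below(constant_trace()), 0)
})

test_that("divergence is the end-window |PE| trend in percent per hour", {
  expect_equal(divergence(constant_trace()), 0)
  # |PE| rising linearly from 1 to 2 over the final 10 % (180 s = 0.05 h)
  t <- seq(0, 1800, by = 10)
  pe <- rep(1, length(t))
  w <- t >= 1620
  pe[w] <- 1 + (t[w] - 1620) / 180
  tr <- trace_from_pe(pe)
  expect_equal(divergence(tr), 1 / 0.05, tolerance = 1e-9)  # +20 %/h
  # converging trace: |PE| falling from 2 to 1 over the final window
  pe2 <- rep(1, length(t))
  pe2[w] <- 2 - (t[w] - 1620) / 180
  tr2 <- trace_from_pe(pe2)
  expect_equal(divergence(tr2), -1 / 0.05, tolerance = 1e-9)
})

test_that("infusion metrics match constructed profiles", {
  ref <- generate_reference_traces()
  expect_equal(mean_inf(ref$traces$constant), 1)
  expect_equal(max_rate_change(ref$traces$constant), 0)
  expect_equal(var_inf_rate(ref$traces$constant), 0)
  # square wave 0/0.2 with 1-min half-period: every 2-min window holds half
  # of each level, population SD exactly 0.1
  expect_equal(var_inf_rate(ref$traces$square_rate),
               ref$manifest$square_rate$var_inf_rate, tolerance = 1e-9)
  # a steady ramp in rate: the smoothed slope equals the raw slope
  t <- seq(0, 1800, by = 10)
  ramp_rate <- 0.002 * t  # slope 0.002 mL/min per s = 0.12 per minute
  tr <- pclc_trace(t, rep(65, length(t)), ramp_rate, 65)
  expect_equal(max_rate_change(tr), 0.12, tolerance = 1e-9)
})

test_that("compute_all_metrics emits the full thirteen-metric set", {
  ms <- compute_all_metrics(constant_trace())
  expect_s3_class(ms, "metric_set")
  expect_named(ms, c("mdpe", "mdape", "mdape_ss", "target_overshoot",
                     "effectiveness", "wobble", "divergence", "rise_time",
                     "mean_inf", "area_above", "area_below",
                     "max_rate_change", "var_inf_rate"))
  expect_equal(ms$mdape, 0)
  expect_equal(ms$effectiveness, 100)
  expect_equal(ms$rise_time, 0)
  expect_error(compute_all_metrics(data.frame()), "pclc_trace")
})
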