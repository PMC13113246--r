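#' Scenario configuration
#'
#' A benchmark scenario: the virtual patient starts hypotensive (35, 45 or
#' 55 mmHg) with a continuous 10 mL/min hemorrhage, and the controller must
#' reach and hold a 65 mmHg target for 30 minutes.
#'
#' @param start_map starting MAP, mmHg (35, 45 or 55 for the standard
#'   battery; any value below target is accepted).
#' @param target_map target MAP, mmHg.
#' @param duration_min run duration, minutes.
#' @param hemorrhage_rate continuous bleed, mL/min.
#' @param controller_tick controller period, seconds.
#' @param plant_dt plant integration step, seconds.
#' @param seed RNG seed for the run.
#' @param noise enable measurement/process noise.
#' @param noise_sd noise standard deviation when enabled, mmHg.
#' @return a `scenario_config` object.
#' @export
scenario_config <- function(start_map = 35, target_map = 65,
                            duration_min = 30, hemorrhage_rate = 10,
                            controller_tick = 10, plant_dt = 0.25,
                            seed = 1L, noise = FALSE, noise_sd = 1) {
  stopifnot(duration_min > 0, controller_tick >= plant_dt,
            target_map > start_map,
            abs(controller_tick / plant_dt -
                  round(controller_tick / plant_dt)) < 1e-9)
  structure(list(start_map = start_map, target_map = target_map,
                 duration_min = duration_min,
                 hemorrhage_rate = hemorrhage_rate,
                 controller_tick = controller_tick, plant_dt = plant_dt,
                 seed = as.integer(seed), noise = noise, noise_sd = noise_sd),
            class = "scenario_config")
}

#' Default tuning profiles for the ten controller configurations
#'
#' Gains not fixed by the controller descriptions (PID and ADRC gains, the
#' neuro-fuzzy safeguard parameters) were tuned once against the default
#' plant to meet the stated rise-time intents -- aggressive profiles target
#' a 4-6 minute rise, conservative 7-10 minutes at the 35 mmHg start -- and
#' live here as documented defaults. Printed constants (step sizes 0.035 /
#' 0.025 mL/min, patient-following windows 10/5, increments 0.25/0.5 and
#' threshold fractions 0.5/0.9) are used verbatim.
#'
#' @return named list: configuration id -> tuning object.
#' @export
controller_profiles <- function() {
  anfis_path <- function(p) system.file("extdata", p, package = "pclcbench")
  list(
    pid_aggressive = pid_tuning(kp = 0.015, ki = 1e-4, kd = 0.05,
                                max_rate_step = 0.06),
    pid_conservative = pid_tuning(kp = 0.008, ki = 6e-5, kd = 0.08,
                                  max_rate_step = 0.035),
    stepfis_aggressive = stepfis_tuning(base_step = 0.035),
    stepfis_conservative = stepfis_tuning(base_step = 0.025),
    anfis_aggressive = anfis_tuning(anfis_path("anfis_aggressive.json"),
                                    safeguard_gain = -0.01,
                                    safeguard_bounds = c(0.5, 1.5)),
    anfis_conservative = anfis_tuning(anfis_path("anfis_conservative.json"),
                                      safeguard_gain = -0.005,
                                      safeguard_bounds = c(0.8, 1.2)),
    adrc_aggressive = adrc_tuning(kp = 0.05, kd = 0.5, omega0 = 0.06,
                                  td_speed = 0.05, max_rate_step = 0.06),
    adrc_conservative = adrc_tuning(kp = 0.02, kd = 0.5, omega0 = 0.05,
                                    td_speed = 0.03, max_rate_step = 0.035),
    pfc_aggressive = pfc_tuning(smooth_window = 5, dose_increment = 0.5,
                                threshold_frac = 0.9),
    pfc_conservative = pfc_tuning(smooth_window = 10, dose_increment = 0.25,
                                  threshold_frac = 0.5)
  )
}

#' Instantiate a controller by configuration id
#'
#' @param id one of [configuration_ids()], or "null" (rate identically 0,
#'   open-loop hemorrhage) or "oracle" (constant rate solving the plant
#'   steady state at target; used as a simulation oracle in tests).
#' @param initial_map first MAP measurement, mmHg.
#' @param dt controller tick, seconds.
#' @param profiles tuning profiles, as [controller_profiles()].
#' @param oracle_rate rate used by the "oracle" controller.
#' @return list with fields `id`, `state`, `initial_rate` and
#'   `step(state, measured, target)`.
#' @export
make_controller <- function(id, initial_map, dt = 10,
                            profiles = controller_profiles(),
                            oracle_rate = NULL) {
  if (id == "null") {
    return(list(id = id, state = list(), initial_rate = 0,
                step = function(state, measured, target)
                  list(state = state, rate = 0)))
  }
  if (id == "oracle") {
    stopifnot(!is.null(oracle_rate))
    return(list(id = id, state = list(), initial_rate = oracle_rate,
                step = function(state, measured, target)
                  list(state = state, rate = oracle_rate)))
  }
  if (!id %in% names(profiles)) stop("unknown controller id: ", id)
  tuning <- profiles[[id]]
  arch <- sub("_(aggressive|conservative)$", "", id)
  switch(arch,
         pid = list(id = id, state = pid_init(tuning, initial_map, dt = dt),
                    initial_rate = 0, step = pid_step),
         stepfis = list(id = id, state = stepfis_init(tuning, dt = dt),
                        initial_rate = 0, step = stepfis_tick),
         anfis = list(id = id, state = anfis_init(tuning, dt = dt),
                      initial_rate = 0, step = anfis_tick),
         adrc = list(id = id, state = adrc_init(tuning, initial_map, dt = dt),
                     initial_rate = 0, step = adrc_step),
         pfc = list(id = id, state = pfc_init(tuning, dt = dt),
                    initial_rate = 0.13, step = pfc_tick),
         stop("unknown architecture: ", arch))
}

# small stable FNV-1a hash of a configuration for provenance records
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run one closed-loop scenario
#'
#' Initializes the plant at the scenario's starting pressure, integrates it
#' at `plant_dt`, invokes the controller every `controller_tick` with the
#' zero-order-held MAP sample, and routes commanded rates through the
#' lagged dose path. Deterministic under a fixed seed.
#'
#' @param id controller configuration id (see [make_controller()]).
#' @param scenario a [scenario_config()].
#' @param plant optional [plant_params()]; defaults to the package's
#'   default plant at the scenario's starting pressure.
#' @param profiles tuning profiles.
#' @param ... passed to [make_controller()] (e.g. `oracle_rate`).
#' @return a `run_record`: list with `scenario`, `controller`, `trace`
#'   (a [pclc_trace()]), `metrics` (a `metric_set`), `config_hash`,
#'   `version` and `wall_time_s`.
#' @export
run_closed_loop <- function(id, scenario = scenario_config(),
                            plant = NULL, profiles = controller_profiles(),
                            ...) {
  stopifnot(inherits(scenario, "scenario_config"))
  t0 <- proc.time()[["elapsed"]]
  if (is.null(plant)) {
    plant <- plant_params(baseline_map = scenario$start_map,
                          hemorrhage_rate = scenario$hemorrhage_rate,
                          noise_sd = if (scenario$noise) scenario$noise_sd else 0)
  }
  set.seed(scenario$seed)
  tick <- scenario$controller_tick
  dt <- scenario$plant_dt
  n_ticks <- round(scenario$duration_min * 60 / tick)
  steps_per_tick <- round(tick / dt)
  ctrl <- make_controller(id, initial_map = plant$baseline_map, dt = tick,
                          profiles = profiles, ...)
  state <- plant_init(plant, initial_dose = ctrl$initial_rate)
  times <- rates <- maps <- numeric(n_ticks + 1)
  rate <- ctrl$initial_rate
  for (k in 0:n_ticks) {
    i <- k + 1
    times[i] <- state$time
    maps[i] <- state$map_true  # zero-order hold refreshed at each tick
    if (k < n_ticks) {
      res <- tryCatch(ctrl$step(ctrl$state, maps[i], scenario$target_map),
                      error = function(e)
                        stop("controller '", id, "' failed at t = ",
                             state$time, " s: ", conditionMessage(e)))
      ctrl$state <- res$state
      if (res$rate != rate) {
        state <- apply_dose(state, res$rate, plant)
        rate <- res$rate
      }
      rates[i] <- rate
      for (s in seq_len(steps_per_tick)) state <- step_plant(state, dt, plant)
    } else {
      rates[i] <- rate
    }
  }
  trace <- pclc_trace(times, maps, rates, target = scenario$target_map,
                      duration = scenario$duration_min * 60)
  structure(list(scenario = scenario, controller = id, trace = trace,
                 metrics = compute_all_metrics(trace),
                 config_hash = config_hash(list(id, scenario, plant)),
                 version = as.character(utils::packageVersion("pclcbench")),
                 wall_time_s = proc.time()[["elapsed"]] - t0),
            class = "run_record")
}

#' Run the full benchmark battery
#'
#' All ten controller configurations across the three starting pressures
#' (30 closed-loop runs), assembled into per-scenario metric panels and the
#' scoring pipeline: per-scenario aggregate terms, study averages, and the
#' final ranking.
#'
#' @param scenarios starting pressures, mmHg.
#' @param seed base RNG seed; each run derives its own seed from it.
#' @param ids controller configuration ids to run.
#' @param ... passed to [scenario_config()].
#' @return a `battery_result`: list with `records` (nested by scenario),
#'   `panels`, `term_sets`, `average` (study-average `term_set`) and
#'   `ranking`.
#' @export
run_battery <- function(scenarios = c(35, 45, 55), seed = 1L,
                        ids = configuration_ids(), ...) {
  profiles <- controller_profiles()
  records <- list()
  panels <- list()
  for (s_i in seq_along(scenarios)) {
    s <- scenarios[s_i]
    scen_records <- list()
    for (c_i in seq_along(ids)) {
      run_seed <- (seed + 1000L * s_i + c_i) %% .Machine$integer.max
      scen <- scenario_config(start_map = s, seed = run_seed, ...)
      scen_records[[ids[c_i]]] <- run_closed_loop(ids[c_i], scen,
                                                  profiles = profiles)
    }
    records[[as.character(s)]] <- scen_records
    panels[[as.character(s)]] <- metric_panel(
      lapply(scen_records, `[[`, "metrics"), scenario = s)
  }
  term_sets <- lapply(panels, compute_terms)
  result <- list(records = records, panels = panels, term_sets = term_sets)
  if (setequal(scenarios, c(35, 45, 55))) {
    result$average <- study_average(unname(term_sets))
    result$ranking <- rank_configurations(result$average)
  }
  structure(result, class = "battery_result")
}

#' Constructed reference traces with closed-form metrics
#'
#' Emits a small library of analytically tractable traces -- constant at
#' target, linear climb, plateau excursions above/below target, and a
#' square-wave infusion profile -- together with a manifest of their exact
#' metric values, used to validate the metric suite.
#'
#' @param seed accepted for interface uniformity; the traces are
#'   deterministic constructions.
#' @param tick sample spacing, seconds.
#' @return list with `traces` (named list of [pclc_trace()]s) and
#'   `manifest` (named list of expected metric values per trace).
#' @export
generate_reference_traces <- function(seed = 1L, tick = 10) {
  target <- 65
  dur <- 1800
  t <- seq(0, dur, by = tick)
  n <- length(t)
  traces <- list()
  manifest <- list()

  # constant at target
  traces$constant <- pclc_trace(t, rep(target, n), rep(1, n), target)
  manifest$constant <- list(mdpe = 0, mdape = 0, wobble = 0,
                            target_overshoot = 0, effectiveness = 100,
                            rise_time = 0, area_above = 0, area_below = 0,
                            mean_inf = 1, max_rate_change = 0,
                            var_inf_rate = 0, divergence = 0)

  # linear climb 35 -> 65 over 10 min, then hold at target
  climb <- ifelse(t <= 600, 35 + (target - 35) * t / 600, target)
  traces$ramp <- pclc_trace(t, climb, rep(0.5, n), target)
  manifest$ramp <- list(rise_time = 600 * (0.9 * target - 35) /
                          (target - 35) / 60,
                        target_overshoot = 0, area_above = 0)

  # +5 % plateau, trapezoid-equivalent to a 4 min rectangle
  above <- rep(target, n)
  above[t >= 600 & t < 840] <- target * 1.05
  traces$plateau_above <- pclc_trace(t, above, rep(1, n), target)
  manifest$plateau_above <- list(area_above = 0.05 * 4,
                                 target_overshoot = 5)

  # -10 % plateau, trapezoid-equivalent to a 3 min rectangle
  below <- rep(target, n)
  below[t >= 900 & t < 1080] <- target * 0.90
  traces$plateau_below <- pclc_trace(t, below, rep(1, n), target)
  manifest$plateau_below <- list(area_below = -0.10 * 3, rise_time = 0)

  # square-wave infusion, 2 min period, levels 0 / 0.2
  sq <- ifelse((t %/% 60) %% 2 == 0, 0, 0.2)
  traces$square_rate <- pclc_trace(t, rep(target, n), sq, target)
  manifest$square_rate <- list(var_inf_rate = 0.1)

  list(traces = traces, manifest = manifest)
}
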