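#' Closed-loop run trace
#'
#' The interchange object between simulation and evaluation: uniformly
#' ticked MAP and infusion-rate series for one run, with the target
#' pressure and total duration attached.
#'
#' @param times sample times, seconds, strictly increasing and uniform.
#' @param map_values MAP at each sample, mmHg.
#' @param infusion_rates infusion rate at each sample, mL/min.
#' @param target target MAP, mmHg.
#' @param duration run duration, seconds (default: last time).
#' @return a `pclc_trace` object (data.frame with attributes `target` and
#'   `duration`).
#' @export
pclc_trace <- function(times, map_values, infusion_rates, target,
                       duration = max(times)) {
  stopifnot(length(times) == length(map_values),
            length(times) == length(infusion_rates),
            target > 0, duration > 0)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  dts <- diff(times)
  if (length(dts) > 1 && max(abs(dts - dts[1])) > 1e-6) {
    stop("trace must be uniformly sampled")
  }
  structure(data.frame(time_s = times, map_mmhg = map_values,
                       infusion_ml_min = infusion_rates),
            target = target, duration = duration,
            class = c("pclc_trace", "data.frame"))
}

#' Write / read a trace as CSV
#'
#' Plain-text schema `time_s,map_mmhg,map_sampled_mmhg,infusion_ml_min`
#' with the target and duration carried in `#`-comment headers.
#'
#' @param trace a [pclc_trace()].
#' @param path file path.
#' @param map_sampled optional held/sampled MAP column; defaults to the
#'   trace MAP.
#' @return `read_trace` returns a `pclc_trace`; `write_trace` the path,
#'   invisibly.
#' @export
write_trace <- function(trace, path, map_sampled = NULL) {
  if (is.null(map_sampled)) map_sampled <- trace$map_mmhg
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# target_mmhg: %.10g", attr(trace, "target")), con)
  writeLines(sprintf("# duration_s: %.10g", attr(trace, "duration")), con)
  df <- data.frame(time_s = trace$time_s, map_mmhg = trace$map_mmhg,
                   map_sampled_mmhg = map_sampled,
                   infusion_ml_min = trace$infusion_ml_min)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  hdr <- readLines(path, n = 10)
  get_num <- function(key) {
    line <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(line) != 1) stop("trace file missing header: ", key)
    as.numeric(sub(".*: ", "", line))
  }
  df <- utils::read.csv(path, comment.char = "#")
  pclc_trace(df$time_s, df$map_mmhg, df$infusion_ml_min,
             target = get_num("target_mmhg"), duration = get_num("duration_s"))
}

#' Performance error
#'
#' `PE = 100 * (map - target) / target`, percent of target.
#'
#' @param map MAP value(s), mmHg.
#' @param target target MAP, mmHg (> 0).
#' @return performance error(s), percent.
#' @export
performance_error <- function(map, target) {
  stopifnot(target > 0)
  100 * (map - target) / target
}

# least-squares slope of y against x
ls_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Median performance error
#' @param trace a [pclc_trace()].
#' @return MDPE, percent.
#' @export
mdpe <- function(trace) {
  stats::median(performance_error(trace$map_mmhg, attr(trace, "target")))
}

#' Median absolute performance error
#' @param trace a [pclc_trace()].
#' @return MDAPE, percent.
#' @export
mdape <- function(trace) {
  stats::median(abs(performance_error(trace$map_mmhg, attr(trace, "target"))))
}

#' Wobble: dispersion of performance errors about MDPE
#' @param trace a [pclc_trace()].
#' @return median absolute deviation of PE from MDPE, percent.
#' @export
wobble <- function(trace) {
  pe <- performance_error(trace$map_mmhg, attr(trace, "target"))
  stats::median(abs(pe - stats::median(pe)))
}

#' Rise time efficiency
#'
#' Time for MAP to first reach 90 % of the target, in minutes, with linear
#' interpolation of the crossing between samples; equals the run duration
#' if the threshold is never reached.
#'
#' @param trace a [pclc_trace()].
#' @return rise time, minutes.
#' @export
rise_time <- function(trace) {
  target <- attr(trace, "target")
  thresh <- 0.9 * target
  m <- trace$map_mmhg
  t <- trace$time_s
  if (m[1] >= thresh) return(0)
  above <- which(m >= thresh)
  if (length(above) == 0) return(attr(trace, "duration") / 60)
  i <- above[1]
  # linear interpolation of the crossing
  t_cross <- t[i - 1] + (thresh - m[i - 1]) / (m[i] - m[i - 1]) * (t[i] - t[i - 1])
  t_cross / 60
}

#' Steady-state median absolute performance error
#'
#' MDAPE restricted to samples after the rise time; if 90 % of target is
#' never reached, restricted to the final third of the run so a value is
#' still produced for runs that never settle.
#'
#' @param trace a [pclc_trace()].
#' @return MDAPE_SS, percent.
#' @export
mdape_ss <- function(trace) {
  target <- attr(trace, "target")
  rt_s <- rise_time(trace) * 60
  if (rt_s >= attr(trace, "duration")) {
    keep <- trace$time_s > 2 / 3 * attr(trace, "duration")
  } else {
    keep <- trace$time_s > rt_s
  }
  stats::median(abs(performance_error(trace$map_mmhg[keep], target)))
}

#' Effectiveness: share of time within +/- 5 mmHg of target
#' @param trace a [pclc_trace()].
#' @return percent of samples with |MAP - target| <= 5 mmHg.
#' @export
effectiveness <- function(trace) {
  100 * mean(abs(trace$map_mmhg - attr(trace, "target")) <= 5)
}

#' Maximal target overshoot
#' @param trace a [pclc_trace()].
#' @return `max(0, 100 * (max(MAP) - target) / target)`, percent.
#' @export
target_overshoot <- function(trace) {
  target <- attr(trace, "target")
  max(0, 100 * (max(trace$map_mmhg) - target) / target)
}

#' Cumulative area above target (over-resuscitation)
#'
#' Trapezoidal integral of the positive part of the fractional performance
#' error over time in minutes, so a sustained +5 % excursion for 4 minutes
#' contributes 0.2 min.
#'
#' @param trace a [pclc_trace()].
#' @return area, minutes (>= 0).
#' @export
area_above <- function(trace) {
  pe_frac <- pmax(0, performance_error(trace$map_mmhg, attr(trace, "target")) / 100)
  t_min <- trace$time_s / 60
  sum(diff(t_min) * (utils::head(pe_frac, -1) + utils::tail(pe_frac, -1)) / 2)
}

#' Cumulative area below target after first reaching it (under-resuscitation)
#'
#' Trapezoidal integral of the negative part of the fractional performance
#' error, restricted to times after the rise time, reported non-positive.
#'
#' @param trace a [pclc_trace()].
#' @return area, minutes (<= 0).
#' @export
area_below <- function(trace) {
  rt_s <- rise_time(trace) * 60
  keep <- trace$time_s > rt_s
  if (sum(keep) < 2) return(0)
  pe_frac <- pmax(0, -performance_error(trace$map_mmhg[keep], attr(trace, "target")) / 100)
  t_min <- trace$time_s[keep] / 60
  -sum(diff(t_min) * (utils::head(pe_frac, -1) + utils::tail(pe_frac, -1)) / 2)
}

#' Divergence: end-of-run trend of the absolute performance error
#'
#' Least-squares slope of |PE| against time in hours over the final 10 % of
#' the run; negative values indicate convergence.
#'
#' @param trace a [pclc_trace()].
#' @return slope, percent per hour; `NA` with fewer than 3 window samples.
#' @export
divergence <- function(trace) {
  keep <- trace$time_s >= 0.9 * attr(trace, "duration")
  if (sum(keep) < 3) return(NA_real_)
  ape <- abs(performance_error(trace$map_mmhg[keep], attr(trace, "target")))
  ls_slope(trace$time_s[keep] / 3600, ape)
}

#' Mean infusion rate
#' @param trace a [pclc_trace()].
#' @return mean rate, mL/min.
#' @export
mean_inf <- function(trace) mean(trace$infusion_ml_min)

#' Maximum infusion-rate change after 3-minute smoothing
#'
#' The infusion-rate series is smoothed with a centered 3-minute moving
#' average; the metric is the maximum absolute slope between successive
#' smoothed samples, in mL/min per minute.
#'
#' @param trace a [pclc_trace()].
#' @return max rate change, mL/min^2 (per-minute time base).
#' @export
max_rate_change <- function(trace) {
  dt_s <- diff(trace$time_s)[1]
  n <- length(trace$infusion_ml_min)
  w <- max(1L, round(180 / dt_s))
  if (w %% 2 == 0) w <- w + 1L  # centered window
  if (w > n) w <- if (n %% 2 == 1L) n else n - 1L  # short traces
  if (w < 1L) return(0)
  sm <- stats::filter(trace$infusion_ml_min, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  sm <- sm[!is.na(sm)]
  if (length(sm) < 2) return(0)
  max(abs(diff(sm))) / (dt_s / 60)
}

#' Variability of the infusion rate
#'
#' Median over sliding 2-minute windows of the within-window (population)
#' standard deviation of infusion rates.
#'
#' @param trace a [pclc_trace()].
#' @return variability, mL/min.
#' @export
var_inf_rate <- function(trace) {
  dt_s <- diff(trace$time_s)[1]
  w <- max(2L, round(120 / dt_s))
  r <- trace$infusion_ml_min
  n <- length(r)
  if (n < w) return(0)
  sds <- vapply(seq_len(n - w + 1L), function(i) {
    x <- r[i:(i + w - 1L)]
    sqrt(mean((x - mean(x))^2))
  }, numeric(1))
  stats::median(sds)
}

#' Compute the full thirteen-metric set for one run
#'
#' @param trace a [pclc_trace()].
#' @return a one-row data.frame of class `metric_set` with columns `mdpe`,
#'   `mdape`, `mdape_ss`, `target_overshoot`, `effectiveness`, `wobble`,
#'   `divergence`, `rise_time`, `mean_inf`, `area_above`, `area_below`,
#'   `max_rate_change`, `var_inf_rate`.
#' @export
compute_all_metrics <- function(trace) {
  stopifnot(inherits(trace, "pclc_trace"))
  out <- data.frame(
    mdpe = mdpe(trace), mdape = mdape(trace), mdape_ss = mdape_ss(trace),
    target_overshoot = target_overshoot(trace),
    effectiveness = effectiveness(trace), wobble = wobble(trace),
    divergence = divergence(trace), rise_time = rise_time(trace),
    mean_inf = mean_inf(trace), area_above = area_above(trace),
    area_below = area_below(trace), max_rate_change = max_rate_change(trace),
    var_inf_rate = var_inf_rate(trace))
  class(out) <- c("metric_set", "data.frame")
  out
}
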