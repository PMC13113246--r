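# pclcbench

Benchmarking closed-loop vasopressor controllers in simulated hemorrhagic
shock.

A patient bleeding at 10 mL/min starts hypotensive (mean arterial
pressure, MAP, of 35, 45 or 55 mmHg) and a physiological closed-loop
controller must titrate norepinephrine to reach and hold a permissive
65 mmHg target for 30 minutes. `pclcbench` provides:

- a **virtual hemorrhaging patient**: saturating Emax dose–response,
  30 s dose lag, 60 s first-order responsiveness, optional overshoot
  transient and measurement noise, and a hemorrhage drift that depresses
  MAP at exactly 0.2 mmHg/min untreated;
- **five controller architectures**, each in aggressive and conservative
  tunings (ten configurations): PID with delay filtering and anti-windup,
  a rule-based Sugeno fuzzy controller with unit-step dosing logic
  (Step-FIS), an adaptive neuro-fuzzy controller trained by hybrid least
  squares + backpropagation (AN-FIS), active disturbance rejection
  control (ADRC) with an extended state observer, and a patient-following
  controller (PFC) that steps the dose only when the error gradient shows
  the current dose has saturated;
- a **thirteen-metric evaluation suite** in the Varvel tradition (MDPE,
  MDAPE, wobble, divergence, effectiveness, rise time, overshoot,
  over/under-resuscitation areas, infusion-smoothness statistics);
- a **scoring pipeline** that median-normalizes each metric across
  configurations, aggregates them into five terms (stability, overshoot,
  undershoot, infusion, effectiveness), multiplies into an overall score
  (lower is better), averages across scenarios, ranks, and probes weight
  sensitivity;
- **shipped reference panels** from a hardware flow-loop benchmark of the
  same ten configurations, which the scoring pipeline reproduces — the
  package's primary worked example.

See `vignettes/methods.Rmd` for the model, the tuning rationale, and the
scoring conventions (including why the two-element aggregate terms use
divisor 3 and how zero medians are handled).

## Worked example: scoring the reference benchmark

Compute the 35 mmHg aggregate terms from the shipped reference metric
panel and rank the study averages:

```r
library(pclcbench)

terms35 <- compute_terms(reference_panel(35))
terms35[, c("configuration", "stable", "overshoot", "undershoot",
            "infusion", "effectiveness_term", "overall")]
#>         configuration stable overshoot undershoot infusion effectiveness_term overall
#>        pid_aggressive  3.061     7.417      0.670    0.930              3.467   41.88
#>      pid_conservative  2.826     0.894      1.318    0.764              4.684   27.18
#>    stepfis_aggressive  0.512     0.791      0.510    1.614              0.356    1.22
#>  stepfis_conservative  0.789     0.457      0.727    1.260              0.753    2.43
#>      anfis_aggressive  0.534     0.987      0.501    1.184              0.582    1.86
#>    anfis_conservative  0.618     0.112      0.623    0.919              0.575    1.31
#>       adrc_aggressive  2.221     1.705      0.624    0.898              0.855    4.66
#>     adrc_conservative  0.981     0.208      1.125    0.727              1.297    3.95
#>        pfc_aggressive  3.220     1.323      0.656    1.250              1.738   11.21
#>      pfc_conservative  4.347     0.000      2.052    0.933             28.154  206.43

avg <- study_average(lapply(c(35, 45, 55),
                            function(s) compute_terms(reference_panel(s))))
head(rank_configurations(avg), 4)
#>  rank        configuration score
#>     1   anfis_conservative 0.632
#>     2 stepfis_conservative 1.350
#>     3    adrc_conservative 1.984
#>     4     anfis_aggressive 4.684
```

The conservative AN-FIS configuration wins, followed by conservative
Step-FIS and conservative ADRC, with a greater-than-2x score gap to
fourth place — and `sensitivity_analysis(reference_term_sets())` shows
this top three survives halving or doubling any single term weight.

## Worked example: one closed-loop run

```r
rec <- run_closed_loop("anfis_conservative",
                       scenario_config(start_map = 35, seed = 7))
round(as.data.frame(rec$metrics), 3)
#>    mdpe mdape mdape_ss target_overshoot effectiveness wobble divergence
#>  -3.393 3.393    3.222                0        92.265  1.341     12.417
#>  rise_time mean_inf area_above area_below max_rate_change var_inf_rate
#>       2.02    2.553          0     -0.911            0.64         0.01
```

`run_battery(seed = 1)` runs all 30 scenario/configuration combinations
(about 15 s) and returns panels, terms, study averages and the ranking.
Simulated runs reproduce the qualitative published behavior (aggressive
tunings rise at least as fast as conservative ones; PFC is slowest and
its conservative tuning never reaches the target band), but not
trace-level hardware numbers — the hardware dynamics and original gains
are not public. The shipped reference panels are the quantitative anchor.

## Command line

A thin CLI wraps the package functions:

```sh
EXE=$(Rscript -e 'cat(system.file("exec", "pclcbench.R", package = "pclcbench"))')
Rscript "$EXE" simulate --id pid_aggressive --start 35 --seed 1 --out trace.csv
Rscript "$EXE" battery --seed 1 --out-dir results
Rscript "$EXE" metrics --trace trace.csv
Rscript "$EXE" score            # shipped fixture panels -> terms + ranking
Rscript "$EXE" sensitivity
Rscript "$EXE" fixtures --out-dir fixtures
```

Scenario and plant fields can be overridden with a YAML or JSON
`--config` file; every run writes a JSON provenance block (version, seed,
configuration hash).

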