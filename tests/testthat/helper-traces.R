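# Shared test helpers.

# Build a uniformly ticked trace whose performance errors are exactly `pe`
# (percent of target), with a constant infusion rate.
trace_from_pe <- function(pe, target = 65, tick = 10, rate = 1) {
  n <- length(pe)
  pclc_trace(times = seq(0, by = tick, length.out = n),
             map_values = target * (1 + pe / 100),
             infusion_rates = rep(rate, n),
             target = target)
}

# A constant-at-target trace of n samples.
constant_trace <- function(n = 181, target = 65, tick = 10, rate = 1) {
  trace_from_pe(rep(0, n), target = target, tick = tick, rate = rate)
}
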