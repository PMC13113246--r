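Package: pclcbench
Title: Benchmarking Closed-Loop Vasopressor Controllers in Simulated Hemorrhagic Shock
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a hemorrhaging virtual patient whose mean arterial pressure
    responds to norepinephrine infusion, closes the loop with five controller
    architectures (PID, rule-based Sugeno fuzzy with unit-step logic, adaptive
    neuro-fuzzy, active disturbance rejection, and a patient-following gradient
    controller), each in aggressive and conservative tunings, and evaluates every
    run with a thirteen-metric performance suite (median performance error family,
    effectiveness, rise time, over/under-resuscitation areas, infusion-smoothness
    statistics). Per-scenario metric panels are median-normalized into five
    aggregate terms and an overall score used to rank controller configurations,
    with a weight sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
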