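#!/usr/bin/env Rscript
# Train the two shipped neuro-fuzzy dosing models on plant-simulator sweep
# traces and write them to inst/extdata/ as versioned JSON.
#
# Run from the repository root after installing the package:
#   Rscript scripts/train_anfis_models.R
#
# The teacher policy maps (error %, error rate %/s) to an infusion rate:
# a holding dose near the rate that sustains the target on the default
# plant, a steeper proportional correction inside a +/-6 % band, a gentler
# one outside it, and a derivative term that backs off while MAP is already
# moving toward target. The aggressive teacher uses higher proportional
# and lower derivative weighting than the conservative one.

library(pclcbench)

teacher <- function(error, error_rate, k_small, k_large, k_deriv,
                    hold_dose = 2.25, band = 6, bounds = c(0, 5)) {
  e_in <- pmax(-band, pmin(band, error))
  e_out <- error - e_in
  d <- hold_dose - k_small * e_in - k_large * e_out - k_deriv * error_rate
  pmax(bounds[1], pmin(bounds[2], d))
}

# (error, error_rate) samples along staircase-dose plant runs plus a
# covering grid, so the model sees both realistic trajectories and the
# corners of the input box
sweep_samples <- function(seed) {
  set.seed(seed)
  target <- 65
  rows <- list()
  for (stair in list(c(0, 0.5, 1, 2, 3), c(0.13, 0.25, 0.5, 1, 2),
                     c(0, 1, 2, 4, 5))) {
    params <- plant_params(baseline_map = 35)
    st <- plant_init(params, initial_dose = stair[1])
    prev_e <- NA
    k <- 0
    while (st$time < 1500) {
      if (st$time %% 300 == 0 && st$time > 0) {
        idx <- min(length(stair), st$time %/% 300 + 1)
        st <- apply_dose(st, stair[idx], params)
      }
      for (i in 1:40) st <- step_plant(st, 0.25, params)  # one 10 s tick
      e <- 100 * (st$map_true - target) / target
      de <- if (is.na(prev_e)) 0 else (e - prev_e) / 10
      prev_e <- e
      rows[[length(rows) + 1]] <- c(e, de)
    }
  }
  traj <- do.call(rbind, rows)
  grid <- as.matrix(expand.grid(error = seq(-50, 10, length.out = 25),
                                error_rate = seq(-0.4, 0.4, length.out = 13)))
  rbind(traj, grid)
}

train_one <- function(name, k_small, k_large, k_deriv, seed) {
  xs <- sweep_samples(seed)
  dose <- teacher(xs[, 1], xs[, 2], k_small, k_large, k_deriv)
  data <- data.frame(error = xs[, 1], error_rate = xs[, 2], dose = dose)
  model <- anfis_train(data, seed = seed, max_epochs = 100)
  out <- file.path("inst", "extdata", paste0(name, ".json"))
  anfis_write(model, out)
  cat(sprintf("%s: n=%d train RMSE %.4f, test RMSE %.4f (%d epochs) -> %s\n",
              name, nrow(data), model$meta$train_rmse, model$meta$test_rmse,
              model$meta$epochs, out))
}

train_one("anfis_aggressive", k_small = 0.12, k_large = 0.035, k_deriv = 1.5,
          seed = 42)
train_one("anfis_conservative", k_small = 0.08, k_large = 0.022, k_deriv = 2.5,
          seed = 43)
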