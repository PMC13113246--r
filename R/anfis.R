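#' Generalized bell membership function
#'
#' `1 / (1 + |(x - c)/a|^(2b))`: strictly positive everywhere, equal to 1 at
#' the center `c`, with half-width `a` and shape exponent `b`.
#'
#' @param x input value(s).
#' @param a half-width (> 0).
#' @param b shape exponent (> 0).
#' @param c center.
#' @return membership degree(s) in (0, 1].
#' @export
gbellmf <- function(x, a, b, c) {
  stopifnot(a > 0, b > 0)
  1 / (1 + abs((x - c) / a)^(2 * b))
}

#' Construct an adaptive neuro-fuzzy model
#'
#' First-order Sugeno network with two inputs (error in percent of target,
#' error rate in percent per second), three generalized-bell membership
#' functions per input, and the full 3 x 3 = 9 rule grid. Each rule's
#' consequent is linear in (error, error_rate, 1). Firing strengths are the
#' products of the two input memberships, normalized to sum to one before
#' the consequents are mixed.
#'
#' @param premise_error,premise_rate 3 x 3 matrices of (a, b, c) rows, one
#'   per membership function.
#' @param consequents 9 x 3 matrix: per-rule coefficients (p, q, r) of
#'   `p*error + q*error_rate + r`. Rules are ordered error-MF-major:
#'   rule (i, j) = row 3*(i-1)+j pairs error MF i with rate MF j.
#' @return an `anfis_model` object.
#' @export
anfis_model <- function(premise_error, premise_rate, consequents) {
  premise_error <- as.matrix(premise_error)
  premise_rate <- as.matrix(premise_rate)
  consequents <- as.matrix(consequents)
  stopifnot(all(dim(premise_error) == c(3, 3)),
            all(dim(premise_rate) == c(3, 3)),
            all(dim(consequents) == c(9, 3)),
            all(premise_error[, 1] > 0), all(premise_rate[, 1] > 0),
            all(premise_error[, 2] > 0), all(premise_rate[, 2] > 0))
  colnames(premise_error) <- colnames(premise_rate) <- c("a", "b", "c")
  colnames(consequents) <- c("p", "q", "r")
  structure(list(premise_error = premise_error, premise_rate = premise_rate,
                 consequents = consequents, meta = list()),
            class = "anfis_model")
}

# normalized firing strengths for vectors of inputs: n x 9 matrix
anfis_firing <- function(model, error, error_rate) {
  mu_e <- sapply(1:3, function(i)
    gbellmf(error, model$premise_error[i, 1], model$premise_error[i, 2],
            model$premise_error[i, 3]))
  mu_r <- sapply(1:3, function(j)
    gbellmf(error_rate, model$premise_rate[j, 1], model$premise_rate[j, 2],
            model$premise_rate[j, 3]))
  mu_e <- matrix(mu_e, ncol = 3)
  mu_r <- matrix(mu_r, ncol = 3)
  w <- matrix(NA_real_, nrow = length(error), ncol = 9)
  for (i in 1:3) for (j in 1:3) w[, 3 * (i - 1) + j] <- mu_e[, i] * mu_r[, j]
  tot <- rowSums(w)
  stopifnot(all(tot > 0))  # gbell memberships are strictly positive
  w / tot
}

#' Evaluate the neuro-fuzzy model
#'
#' @param model an [anfis_model()].
#' @param error error, percent of target (vectorized).
#' @param error_rate error rate, percent per second (vectorized).
#' @return predicted infusion rate(s), mL/min (unconstrained; see
#'   [safeguard_scale()] for the dosing safeguards).
#' @export
anfis_forward <- function(model, error, error_rate) {
  wn <- anfis_firing(model, error, error_rate)
  f <- cbind(error, error_rate, 1) %*% t(model$consequents)  # n x 9
  rowSums(wn * f)
}

#' Hybrid training of the neuro-fuzzy model
#'
#' Alternates an exact least-squares solve of the 27 consequent parameters
#' (premises frozen; the LS step can only decrease training error) with
#' gradient-descent steps on the 18 premise parameters, computed by central
#' finite differences on the training RMSE. A 70/30 train/test split is
#' applied internally. Training stops when the epoch-over-epoch improvement
#' in training RMSE falls below `tol` or after `max_epochs` epochs. If the
#' least-squares system is rank deficient, a small ridge penalty is used
#' (with a warning).
#'
#' @param data data.frame or matrix with columns error, error_rate, dose.
#' @param seed RNG seed for the split and initialization jitter.
#' @param max_epochs epoch cap (default 100).
#' @param lr learning rate for the premise gradient step (relative scale).
#' @param tol stop when training RMSE improves by less than this.
#' @return an `anfis_model` with `meta` holding train/test RMSE and the
#'   per-epoch training-RMSE history.
#' @export
anfis_train <- function(data, seed = 1, max_epochs = 100, lr = 0.05,
                        tol = 1e-6) {
  data <- as.data.frame(data)
  names(data)[1:3] <- c("error", "error_rate", "dose")
  stopifnot(nrow(data) >= 30)
  set.seed(seed)
  n <- nrow(data)
  idx <- sample.int(n)
  n_train <- floor(0.7 * n)
  train <- data[idx[seq_len(n_train)], ]
  test <- data[idx[-seq_len(n_train)], ]

  init_premise <- function(x) {
    r <- range(x)
    centers <- seq(r[1], r[2], length.out = 3)
    a <- max(diff(r) / 4, 1e-3)
    cbind(a = rep(a, 3), b = rep(2, 3), c = centers)
  }
  pe <- init_premise(train$error)
  pr <- init_premise(train$error_rate)
  model <- anfis_model(pe, pr, matrix(0, 9, 3))

  solve_consequents <- function(model, dat) {
    wn <- anfis_firing(model, dat$error, dat$error_rate)
    X <- do.call(cbind, lapply(1:9, function(r_)
      wn[, r_] * cbind(dat$error, dat$error_rate, 1)))
    theta <- tryCatch(qr.solve(X, dat$dose),
                      error = function(e) {
                        warning("rank-deficient least-squares system; using ridge fallback")
                        XtX <- crossprod(X) + diag(1e-8, ncol(X))
                        solve(XtX, crossprod(X, dat$dose))
                      })
    model$consequents <- matrix(theta, nrow = 9, ncol = 3, byrow = TRUE)
    colnames(model$consequents) <- c("p", "q", "r")
    model
  }
  rmse <- function(model, dat)
    sqrt(mean((anfis_forward(model, dat$error, dat$error_rate) - dat$dose)^2))

  history <- numeric(0)
  prev <- Inf
  for (epoch in seq_len(max_epochs)) {
    before_ls <- rmse(model, train)
    model <- solve_consequents(model, train)
    after_ls <- rmse(model, train)
    stopifnot(after_ls <= before_ls + 1e-9)  # LS optimality given premises
    # central-difference gradient step on the 18 premise parameters
    params <- c(model$premise_error, model$premise_rate)
    scale <- pmax(abs(params), 1e-3)
    grad <- numeric(length(params))
    h <- 1e-4 * scale
    for (k in seq_along(params)) {
      up <- params; up[k] <- up[k] + h[k]
      dn <- params; dn[k] <- dn[k] - h[k]
      mu <- model; mu$premise_error <- matrix(up[1:9], 3, 3)
      mu$premise_rate <- matrix(up[10:18], 3, 3)
      md <- model; md$premise_error <- matrix(dn[1:9], 3, 3)
      md$premise_rate <- matrix(dn[10:18], 3, 3)
      if (any(mu$premise_error[, 1:2] <= 0) || any(mu$premise_rate[, 1:2] <= 0) ||
          any(md$premise_error[, 1:2] <= 0) || any(md$premise_rate[, 1:2] <= 0)) {
        grad[k] <- 0
      } else {
        grad[k] <- (rmse(mu, train) - rmse(md, train)) / (2 * h[k])
      }
    }
    gnorm <- sqrt(sum((grad * scale)^2))
    if (gnorm > 0) {
      cand <- params - lr * grad * scale^2 / gnorm
      mc <- model
      mc$premise_error <- matrix(cand[1:9], 3, 3)
      mc$premise_rate <- matrix(cand[10:18], 3, 3)
      ok <- all(mc$premise_error[, 1:2] > 0) && all(mc$premise_rate[, 1:2] > 0)
      if (ok && rmse(mc, train) < after_ls) {
        colnames(mc$premise_error) <- colnames(mc$premise_rate) <- c("a", "b", "c")
        model <- mc
      }
    }
    cur <- rmse(model, train)
    history <- c(history, cur)
    if (abs(prev - cur) < tol) break
    prev <- cur
  }
  model <- solve_consequents(model, train)
  model$meta <- list(train_rmse = rmse(model, train),
                     test_rmse = rmse(model, test),
                     epochs = length(history), seed = seed,
                     history = history)
  model
}

#' Safeguard scaling of the neuro-fuzzy dose
#'
#' Dosing adjustments are proportionally weighted by the deviation from
#' target: the raw model output is multiplied by
#' `clamp(1 + gain * error, lo, hi)` and the result clamped to the dose
#' bounds, preventing excessively low or high vasopressor administration
#' independent of training.
#'
#' @param raw_dose model output, mL/min (>= 0 after clamping upstream).
#' @param error error in percent of target (negative below target).
#' @param gain scaling gain per percent of error.
#' @param bounds multiplier bounds c(lo, hi), 0 < lo < 1 < hi.
#' @param dose_bounds output dose limits, mL/min.
#' @return constrained dose, mL/min.
#' @export
safeguard_scale <- function(raw_dose, error, gain,
                            bounds = c(0.5, 1.5), dose_bounds = c(0, 5)) {
  stopifnot(raw_dose >= 0, bounds[1] > 0, bounds[1] < 1, bounds[2] > 1)
  mult <- min(bounds[2], max(bounds[1], 1 + gain * error))
  min(dose_bounds[2], max(dose_bounds[1], raw_dose * mult))
}

#' Write / read a neuro-fuzzy model as JSON
#'
#' Versioned plain-text schema carrying the generalized-bell parameter
#' triples and the consequent matrix.
#'
#' @param model an `anfis_model`.
#' @param path file path.
#' @return `anfis_read` returns an `anfis_model`; `anfis_write` the path,
#'   invisibly.
#' @export
anfis_write <- function(model, path) {
  obj <- list(schema = "pclcbench-anfis-1",
              premise_error = unclass(model$premise_error),
              premise_rate = unclass(model$premise_rate),
              consequents = unclass(model$consequents),
              meta = model$meta[c("train_rmse", "test_rmse", "epochs", "seed")])
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname anfis_write
#' @export
anfis_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$schema, "pclcbench-anfis-1"))
  m <- anfis_model(obj$premise_error, obj$premise_rate, obj$consequents)
  m$meta <- obj$meta
  m
}

#' Neuro-fuzzy controller tuning profile
#'
#' The aggressive and conservative profiles pair a trained model (fitted to
#' plant-simulator sweep traces; see the shipped model files) with
#' safeguard scaling parameters: the conservative profile uses a lower
#' scaling gain and tighter multiplier bounds, yielding minimal dosage
#' adjustments, while the aggressive profile permits larger weighted doses.
#'
#' @param model an `anfis_model` (or path to a model JSON).
#' @param safeguard_gain scaling gain per percent of error (negative error,
#'   i.e. below target, should increase dose, so the gain is negative).
#' @param safeguard_bounds multiplier bounds c(lo, hi).
#' @param rate_bounds dose limits, mL/min.
#' @return an `anfis_tuning` object.
#' @export
anfis_tuning <- function(model, safeguard_gain,
                         safeguard_bounds = c(0.5, 1.5),
                         rate_bounds = c(0, 5)) {
  if (is.character(model)) model <- anfis_read(model)
  stopifnot(inherits(model, "anfis_model"))
  structure(list(model = model, safeguard_gain = safeguard_gain,
                 safeguard_bounds = safeguard_bounds,
                 rate_bounds = rate_bounds),
            class = "anfis_tuning")
}

#' Initialize the neuro-fuzzy controller state
#' @param tuning an [anfis_tuning()] object.
#' @param initial_rate starting infusion rate, mL/min.
#' @param dt controller tick, seconds.
#' @return an `anfis_state` object.
#' @export
anfis_init <- function(tuning, initial_rate = 0, dt = 10) {
  structure(list(tuning = tuning, dt = dt, prev_error = NA_real_,
                 current_rate = initial_rate),
            class = "anfis_state")
}

#' One neuro-fuzzy controller tick
#'
#' Forms the error (percent of target, negative below target) and its
#' derivative, evaluates the trained Sugeno network for a dose, and applies
#' the safeguard scaling.
#'
#' @param state an `anfis_state`.
#' @param measured sampled MAP, mmHg.
#' @param target target MAP, mmHg.
#' @return list with elements `state` and `rate` (mL/min).
#' @export
anfis_tick <- function(state, measured, target) {
  stopifnot(target > 0)
  tn <- state$tuning
  error <- 100 * (measured - target) / target
  error_rate <- if (is.na(state$prev_error)) 0 else
    (error - state$prev_error) / state$dt
  state$prev_error <- error
  raw <- anfis_forward(tn$model, error, error_rate)
  raw <- max(0, raw)
  rate <- safeguard_scale(raw, error, tn$safeguard_gain,
                          tn$safeguard_bounds, tn$rate_bounds)
  state$current_rate <- rate
  list(state = state, rate = rate)
}
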