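#' Canonical controller configuration identifiers
#'
#' The ten benchmarked configurations: five architectures (PID, step fuzzy,
#' neuro-fuzzy, active disturbance rejection, patient-following), each in
#' aggressive and conservative tunings.
#' @return character vector of the ten ids, fixed order.
#' @export
configuration_ids <- function() {
  c("pid_aggressive", "pid_conservative",
    "stepfis_aggressive", "stepfis_conservative",
    "anfis_aggressive", "anfis_conservative",
    "adrc_aggressive", "adrc_conservative",
    "pfc_aggressive", "pfc_conservative")
}

#' Assemble a per-scenario metric panel
#'
#' @param metric_sets named list (configuration id -> `metric_set` row) for
#'   one scenario; all ten configurations must be present with no missing
#'   metric values.
#' @param scenario scenario label (starting MAP, mmHg).
#' @return a `metric_panel`: data.frame with one row per configuration and
#'   attribute `scenario`.
#' @export
metric_panel <- function(metric_sets, scenario) {
  ids <- configuration_ids()
  if (!all(ids %in% names(metric_sets))) {
    stop("panel is missing configurations: ",
         paste(setdiff(ids, names(metric_sets)), collapse = ", "))
  }
  panel <- do.call(rbind, lapply(ids, function(id) {
    row <- as.data.frame(metric_sets[[id]])
    cbind(configuration = id, row)
  }))
  if (anyNA(panel)) stop("panel contains missing metric values")
  rownames(panel) <- NULL
  structure(panel, scenario = scenario,
            class = c("metric_panel", "data.frame"))
}

#' Median normalization of one metric across configurations
#'
#' Each value is replaced by `|value| / median(|values|)` across the
#' configurations of one scenario, making metrics dimensionless and
#' comparably scaled while staying robust to poor-performing outliers.
#' If the median is zero (a metric can be identically zero for most
#' configurations), zeros map to 0 and nonzero values are normalized by the
#' smallest nonzero absolute value instead (with a message); an all-zero
#' vector returns zeros with a warning.
#'
#' @param values numeric vector, one value per configuration (>= 2).
#' @return normalized non-negative values.
#' @export
normalize_to_median <- function(values) {
  stopifnot(length(values) >= 2)
  av <- abs(values)
  med <- stats::median(av)
  if (med == 0) {
    nz <- av[av > 0]
    if (length(nz) == 0) {
      warning("all values are zero; normalization returns zeros")
      return(av)
    }
    message("median is zero; normalizing nonzero values by the smallest nonzero magnitude")
    return(av / min(nz))
  }
  av / med
}

#' Aggregate terms from a metric panel
#'
#' With `n(.)` the within-panel median normalization of absolute values:
#' \itemize{
#'   \item stable = (n(MDAPE_SS) + n(Wobble) + n(|Divergence|)) / 3
#'   \item overshoot = (n(TargetOvershoot) + n(AreaAbove)) / 3
#'   \item undershoot = (n(RiseTime) + n(|AreaBelow|)) / 3
#'   \item infusion = (n(MeanInf) + n(MaxRateChange) + n(VarInfRate)) / 3
#'   \item effectiveness_term = n(MDAPE) / n(Effectiveness)
#' }
#' The divisor 3 is used for all four additive terms, including the
#' two-element overshoot and undershoot sums: this is the convention the
#' published aggregate-score tables are internally consistent with (see the
#' methods vignette). `divisor2 = TRUE` selects the two-element divisor-2
#' variant instead.
#'
#' @param panel a [metric_panel()].
#' @param divisor2 use divisor 2 for the two-element terms.
#' @return a `term_set` data.frame: one row per configuration with columns
#'   `stable`, `overshoot`, `undershoot`, `infusion`, `effectiveness_term`
#'   and `overall` (equal-weight overall score), attribute `scenario`.
#' @export
compute_terms <- function(panel, divisor2 = FALSE) {
  stopifnot(inherits(panel, "metric_panel"))
  n <- function(col) normalize_to_median(panel[[col]])
  d2 <- if (divisor2) 2 else 3
  stable <- (n("mdape_ss") + n("wobble") + n("divergence")) / 3
  overshoot <- (n("target_overshoot") + n("area_above")) / d2
  undershoot <- (n("rise_time") + n("area_below")) / d2
  infusion <- (n("mean_inf") + n("max_rate_change") + n("var_inf_rate")) / 3
  eff <- n("mdape") / n("effectiveness")
  terms <- data.frame(configuration = panel$configuration,
                      stable = stable, overshoot = overshoot,
                      undershoot = undershoot, infusion = infusion,
                      effectiveness_term = eff)
  terms$overall <- apply(terms[-1], 1, function(r)
    overall_score(r[c("stable", "overshoot", "undershoot",
                      "infusion", "effectiveness_term")]))
  structure(terms, scenario = attr(panel, "scenario"),
            class = c("term_set", "data.frame"))
}

#' Overall aggregate score
#'
#' `(w_s*stable + w_o*overshoot + w_u*undershoot + w_i*infusion) *
#' (w_e*effectiveness_term)`; lower is better. Default weights are all 1.
#'
#' @param terms named numeric vector or one-row data.frame with entries
#'   `stable`, `overshoot`, `undershoot`, `infusion`, `effectiveness_term`.
#' @param weights named numeric vector with entries `stable`, `overshoot`,
#'   `undershoot`, `infusion`, `effectiveness` (all > 0).
#' @return the score (dimensionless).
#' @export
overall_score <- function(terms,
                          weights = c(stable = 1, overshoot = 1,
                                      undershoot = 1, infusion = 1,
                                      effectiveness = 1)) {
  terms <- unlist(terms)
  stopifnot(all(weights > 0))
  (weights[["stable"]] * terms[["stable"]] +
     weights[["overshoot"]] * terms[["overshoot"]] +
     weights[["undershoot"]] * terms[["undershoot"]] +
     weights[["infusion"]] * terms[["infusion"]]) *
    (weights[["effectiveness"]] * terms[["effectiveness_term"]])
}

#' Average per-scenario results across the three scenarios
#'
#' Arithmetic mean of the per-scenario values (terms and overall scores
#' alike) over the scenario set {35, 45, 55} mmHg.
#'
#' @param term_sets list of three `term_set`s, with scenario attributes
#'   35, 45 and 55.
#' @return a `term_set`-like data.frame of study averages (scenario
#'   attribute `"average"`).
#' @export
study_average <- function(term_sets) {
  scen <- vapply(term_sets, function(x) as.numeric(attr(x, "scenario")), numeric(1))
  if (!setequal(scen, c(35, 45, 55))) {
    stop("study average requires exactly the scenarios 35, 45 and 55 mmHg")
  }
  ids <- term_sets[[1]]$configuration
  stopifnot(all(vapply(term_sets, function(x)
    identical(x$configuration, ids), logical(1))))
  num <- Reduce(`+`, lapply(term_sets, function(x) as.matrix(x[-1]))) / length(term_sets)
  out <- data.frame(configuration = ids, num)
  structure(out, scenario = "average", class = c("term_set", "data.frame"))
}

#' Rank configurations by score (ascending; lowest = best)
#'
#' Ties are broken lexicographically by configuration id.
#'
#' @param scores named numeric vector (configuration id -> score) or a
#'   `term_set` (its `overall` column is used).
#' @return data.frame with columns `rank`, `configuration`, `score`.
#' @export
rank_configurations <- function(scores) {
  if (inherits(scores, "term_set")) {
    scores <- stats::setNames(scores$overall, scores$configuration)
  }
  ord <- order(scores, names(scores))
  data.frame(rank = seq_along(scores),
             configuration = names(scores)[ord],
             score = unname(scores[ord]))
}

#' Weight sensitivity analysis of the aggregate score
#'
#' Perturbs each of the five term weights independently to 0.5x, 1x and 2x
#' (the others held at 1), recomputes study-average overall scores and
#' rankings, and reports any rank changes relative to the equal-weight
#' baseline.
#'
#' @param term_sets list of three per-scenario `term_set`s (35/45/55).
#' @param factors weight multipliers to test.
#' @return a `sensitivity_result`: list with `baseline` ranking and a
#'   data.frame `rankings` (term, factor, rank, configuration, score,
#'   rank_changed).
#' @export
sensitivity_analysis <- function(term_sets,
                                 factors = c(0.5, 1, 2)) {
  term_names <- c("stable", "overshoot", "undershoot", "infusion",
                  "effectiveness")
  score_with <- function(weights) {
    per_scen <- lapply(term_sets, function(ts) {
      vapply(seq_len(nrow(ts)), function(i)
        overall_score(ts[i, c("stable", "overshoot", "undershoot",
                              "infusion", "effectiveness_term")],
                      weights), numeric(1))
    })
    avg <- Reduce(`+`, per_scen) / length(per_scen)
    stats::setNames(avg, term_sets[[1]]$configuration)
  }
  base_w <- stats::setNames(rep(1, 5), term_names)
  baseline <- rank_configurations(score_with(base_w))
  rows <- list()
  for (term in term_names) {
    for (f in factors) {
      w <- base_w
      w[term] <- f
      rk <- rank_configurations(score_with(w))
      rk$term <- term
      rk$factor <- f
      rk$rank_changed <- rk$configuration != baseline$configuration
      rows[[length(rows) + 1L]] <- rk
    }
  }
  structure(list(baseline = baseline, rankings = do.call(rbind, rows)),
            class = "sensitivity_result")
}
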