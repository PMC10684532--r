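#' Relative benefit of an optimized allocation over a uniform baseline
#'
#' Expresses the optimized expected advanced-cancer incidence relative to
#' giving every quantile the baseline regimen, as advanced cancers averted
#' per 1000 advanced cancers expected under the baseline:
#' `1000 * (P_baseline - P_optimized) / P_baseline`. Both objectives are
#' computed from the same `p` matrix, so a scale error in absolute risk
#' cancels exactly.
#'
#' @param problem A [build_problem()] object.
#' @param assignment An optimal `assignment` for `problem`.
#' @param baseline_label Label of the baseline regimen (must be in the
#'   problem).
#' @return A list of class `benefit_result` with `baseline_objective`,
#'   `optimized_objective`, `reduction_per_1000`.
#' @export
relative_benefit <- function(problem, assignment, baseline_label) {
  stopifnot(inherits(problem, "screening_problem"),
            inherits(assignment, "assignment"))
  jb <- match(baseline_label, problem$labels)
  if (is.na(jb))
    stop(sprintf("baseline regimen '%s' is not in the problem",
                 baseline_label), call. = FALSE)
  if (assignment$status != "optimal")
    stop("assignment is not optimal (status: ", assignment$status, ")",
         call. = FALSE)
  base <- sum(problem$p[, jb])
  opt <- assignment$objective
  structure(list(baseline_objective = base, optimized_objective = opt,
                 reduction_per_1000 = 1000 * (base - opt) / base),
            class = "benefit_result")
}

#' @export
print.benefit_result <- function(x, ...) {
  cat(sprintf("Expected advanced cancers: baseline %.6g, optimized %.6g\n",
              x$baseline_objective, x$optimized_objective))
  cat(sprintf("Reduction: %.1f per 1000 advanced cancers under the baseline\n",
              x$reduction_per_1000))
  invisible(x)
}

#' Sweep the resource budget
#'
#' Re-optimizes over a grid of budgets expressed as multiples of the
#' baseline-for-all cost (`H = c * K * h_baseline`), tracing how the benefit
#' and the optimal risk-group sizes respond to more or fewer total screens.
#' The default grid 0.6-1.6 in steps of 0.05 brackets the
#' same-resources-as-baseline point (multiple 1.0). Budgets below the cost of
#' the cheapest-regimen-for-all plan are flagged infeasible, not errors.
#'
#' @param quantiles A [risk_quantiles()] object.
#' @param regimens List of [regimen()] objects.
#' @param params An [nh_params()] object.
#' @param budget_multiples Positive multiples of the baseline budget.
#' @param baseline_label Baseline regimen label.
#' @param p_matrix Optional override of the advanced-risk matrix (used by
#'   sensitivity scenarios).
#' @return A data.frame of class `sweep_result`: one row per budget multiple
#'   with `budget_multiple`, `budget`, `feasible`, `reduction_per_1000`, and
#'   one `share_<label>` column (percent of the population) per regimen.
#' @export
resource_sweep <- function(quantiles, regimens, params,
                           budget_multiples = seq(0.6, 1.6, by = 0.05),
                           baseline_label = "3y", p_matrix = NULL) {
  stopifnot(all(budget_multiples > 0))
  base_problem <- build_problem(quantiles, regimens, params,
                                baseline_label = baseline_label,
                                p_matrix = p_matrix)
  H0 <- base_problem$budget
  labels <- base_problem$labels
  rows <- lapply(budget_multiples, function(cmul) {
    pr <- base_problem
    pr$budget <- cmul * H0
    sol <- solve_lp(pr)
    row <- data.frame(budget_multiple = cmul, budget = pr$budget,
                      feasible = sol$status == "optimal",
                      reduction_per_1000 = NA_real_)
    shares <- stats::setNames(rep(NA_real_, length(labels)),
                              paste0("share_", labels))
    if (sol$status == "optimal") {
      sol <- canonicalize(sol)
      row$reduction_per_1000 <-
        relative_benefit(pr, sol, baseline_label)$reduction_per_1000
      shares[] <- 100 * colSums(sol$x) / nrow(sol$x)
    }
    cbind(row, as.data.frame(as.list(shares)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Define a sensitivity scenario
#'
#' A scenario perturbs the stage-mix and detection parameters by absolute
#' deltas: `delta_a`/`delta_b` shift the advanced fractions among
#' screen-detected and interval cancers, and `delta_s` shifts the
#' screen-detected fraction itself, after the closed-form model, either for
#' all regimens or only for the labels in `s_regimens`. Perturbed
#' probabilities are clipped to \[0, 1\] with a warning.
#'
#' @param name Scenario label.
#' @param delta_a,delta_b Absolute shifts on the advanced fractions.
#' @param delta_s Absolute shift on the screen-detected fraction.
#' @param s_regimens Regimen labels the `delta_s` applies to; `NULL` = all.
#' @return A list of class `sensitivity_scenario`.
#' @export
sensitivity_scenario <- function(name, delta_a = 0, delta_b = 0,
                                 delta_s = 0, s_regimens = NULL) {
  structure(list(name = name, delta_a = delta_a, delta_b = delta_b,
                 delta_s = delta_s, s_regimens = s_regimens),
            class = "sensitivity_scenario")
}

#' The default robustness scenario set
#'
#' Seven scenarios: absolute +/-10% on the advanced fraction among
#' screen-detected (`a`) and among interval (`b`) cancers; absolute +/-5% on
#' the screen-detected fraction for all regimens (equivalent to lower test
#' sensitivity or faster progression across the board); and -5% on the
#' screen-detected fraction for the non-baseline regimens only (the case
#' where the baseline performs better than anticipated relative to the
#' alternatives).
#'
#' @param s_only_labels Labels for the regimen-restricted screen-detection
#'   scenario (default the 1- and 4-year regimens).
#' @return A list of [sensitivity_scenario()] objects.
#' @export
default_sensitivity_scenarios <- function(s_only_labels = c("1y", "4y")) {
  list(
    sensitivity_scenario("a+0.10", delta_a = 0.10),
    sensitivity_scenario("a-0.10", delta_a = -0.10),
    sensitivity_scenario("b+0.10", delta_b = 0.10),
    sensitivity_scenario("b-0.10", delta_b = -0.10),
    sensitivity_scenario("s+0.05 all", delta_s = 0.05),
    sensitivity_scenario("s-0.05 all", delta_s = -0.05),
    sensitivity_scenario(paste0("s-0.05 ", paste(s_only_labels, collapse = "/")),
                         delta_s = -0.05, s_regimens = s_only_labels))
}

# advanced-risk matrix under a scenario's perturbations
perturbed_p_matrix <- function(quantiles, regimens, params, scenario) {
  labels <- vapply(regimens, `[[`, character(1), "label")
  u <- vapply(regimens, `[[`, numeric(1), "interval_years")
  s <- screen_detected_fraction(params, u)
  apply_s <- if (is.null(scenario$s_regimens)) rep(TRUE, length(u))
             else labels %in% scenario$s_regimens
  s2 <- s + ifelse(apply_s, scenario$delta_s, 0)
  a2 <- params$adv_frac_screen + scenario$delta_a
  b2 <- params$adv_frac_interval + scenario$delta_b
  clipped <- any(s2 < 0 | s2 > 1) || a2 < 0 || a2 > 1 || b2 < 0 || b2 > 1
  if (clipped)
    warning(sprintf("scenario '%s': perturbed probabilities clipped to [0, 1]",
                    scenario$name), call. = FALSE)
  s2 <- pmin(1, pmax(0, s2))
  a2 <- min(1, max(0, a2)); b2 <- min(1, max(0, b2))
  cj <- a2 * s2 + b2 * (1 - s2)
  outer(quantiles$mean_risk, cj)
}

#' Run sensitivity scenarios
#'
#' Re-builds the advanced-risk matrix under each perturbation, re-optimizes
#' at the baseline-equivalent budget, and reports the resulting thresholds
#' and relative benefit. The baseline objective is recomputed under the same
#' perturbation, so each row answers "if the world were like this, what would
#' the optimized programme gain over baseline-for-all".
#'
#' @param scenarios List of [sensitivity_scenario()] objects (the unperturbed
#'   base run is always included first as scenario `"base"`).
#' @param quantiles,regimens,params,baseline_label As in [resource_sweep()].
#' @param budget Absolute budget; defaults to baseline-for-all.
#' @return A data.frame of class `sensitivity_result`: per scenario, the
#'   reduction per 1000 and one `share_<label>` column per regimen, plus a
#'   `thresholds` list-column of [thresholds_from_assignment()] tables when
#'   score boundaries are available.
#' @export
run_sensitivity <- function(scenarios, quantiles, regimens, params,
                            baseline_label = "3y", budget = NULL) {
  scenarios <- c(list(sensitivity_scenario("base")), scenarios)
  labels <- vapply(regimens, `[[`, character(1), "label")
  rows <- lapply(scenarios, function(sc) {
    pm <- perturbed_p_matrix(quantiles, regimens, params, sc)
    pr <- build_problem(quantiles, regimens, params, budget = budget,
                        baseline_label = if (is.null(budget)) baseline_label
                                         else NULL,
                        p_matrix = pm)
    sol <- canonicalize(solve_lp(pr))
    ben <- relative_benefit(pr, sol, baseline_label)
    shares <- stats::setNames(as.list(100 * colSums(sol$x) / nrow(sol$x)),
                              paste0("share_", labels))
    thr <- if (!is.null(quantiles$boundaries))
      list(thresholds_from_assignment(quantiles, sol)) else list(NULL)
    cbind(data.frame(scenario = sc$name,
                     reduction_per_1000 = ben$reduction_per_1000),
          as.data.frame(shares, check.names = FALSE),
          data.frame(thresholds = I(thr)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_result", "data.frame")
  out
}
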