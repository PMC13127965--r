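#' Per-component incremental costs of a scenario
#'
#' Computes the incremental cost of each modelled component against
#' current practice ("no intervention"). The sign convention follows
#' cost-consequence reporting: **savings are negative incremental costs**.
#' For a participating headcount N:
#'
#' * absenteeism: `-N * days_avoided * cost_per_day`
#' * presenteeism: `-N * days_avoided * cost_per_day`
#' * turnover: `-N * (reduction_pp / 100) * cost_per_case`
#' * intervention: `N * cost_per_person + fixed_cost`
#'
#' Components without an effect size are omitted (not modelled), so the
#' result names only what the scenario actually values. Arithmetic is at
#' full floating precision; rounding happens only in the report layer.
#'
#' @param scenario A `cc_scenario`.
#' @return Named numeric vector of incremental costs (currency); names are
#'   a subset of `absenteeism`, `presenteeism`, `turnover` plus always
#'   `intervention`.
#' @seealso [evaluate_scenario()] for totals, [render_results()] for
#'   rounded report tables.
#' @export
component_costs <- function(scenario) {
  if (!inherits(scenario, "cc_scenario"))
    cc_abort("'scenario' must be a 'cc_scenario' object", "wellcost_validation_error")
  N <- scenario$n_participants
  out <- numeric(0)
  for (comp in names(.cc_components)) {
    keys <- .cc_components[[comp]]
    eff <- scenario$effects[[keys[["effect"]]]]
    if (is.null(eff)) next
    unit <- scenario$unit_costs[[keys[["unit"]]]]
    if (is.null(unit))
      cc_abort(sprintf(
        "scenario '%s': effect '%s' has no matching unit cost (component: %s)",
        scenario$name, keys[["effect"]], comp),
        "wellcost_validation_error", component = comp)
    if (comp == "turnover") eff <- eff / 100
    out[comp] <- -N * eff * unit
  }
  out["intervention"] <- N * scenario$cost_per_person + scenario$fixed_cost
  out
}

#' Evaluate the cost-consequence model for one scenario
#'
#' Runs the deterministic model: component incremental costs are summed
#' into the total incremental cost, and the total is divided by the
#' *participating* headcount (not the whole-company headcount) to give the
#' net cost per person. A negative total means the intervention is cost
#' saving over the one-year horizon.
#'
#' @param scenario A `cc_scenario`.
#' @return An object of class `cc_result` with elements `scenario`,
#'   `components` (as [component_costs()]), `total` and `net_per_person`.
#' @examples
#' s4 <- bundled_scenarios()$scenario_4
#' r <- evaluate_scenario(s4)
#' r$total          # -5215.2
#' coef(r)          # component incremental costs
#' @export
evaluate_scenario <- function(scenario) {
  if (!inherits(scenario, "cc_scenario"))
    cc_abort("'scenario' must be a 'cc_scenario' object", "wellcost_validation_error")
  if (scenario$n_participants == 0)
    cc_abort(sprintf("scenario '%s': n_participants must be positive", scenario$name),
             "wellcost_validation_error", field = "n_participants")
  comp <- component_costs(scenario)
  total <- sum(comp)
  structure(
    list(
      scenario = scenario,
      components = comp,
      total = total,
      net_per_person = total / scenario$n_participants
    ),
    class = "cc_result"
  )
}

#' @export
coef.cc_result <- function(object, ...) object$components

#' @export
print.cc_result <- function(x, ...) {
  cat(sprintf("Cost-consequence result: %s (%s participants)\n",
              x$scenario$name, format(x$scenario$n_participants)))
  labels <- c(.cc_component_labels[names(x$components)])
  vals <- vapply(x$components, format_currency, "")
  width <- max(nchar(c(labels, "Net cost per person")))
  for (i in seq_along(labels))
    cat(sprintf("  %-*s  %10s\n", width, labels[i], vals[i]))
  cat(sprintf("  %-*s  %10s\n", width, "Total costs", format_currency(x$total)))
  cat(sprintf("  %-*s  %10s\n", width, "Net cost per person",
              format_currency(x$net_per_person)))
  cat("(savings shown as negative incremental costs; display rounded to whole currency units)\n")
  invisible(x)
}

#' @export
summary.cc_result <- function(object, ...) {
  interv <- object$components[["intervention"]]
  bcr <- if (interv > 0) benefit_cost_ratio(object) else NA_real_
  structure(
    list(result = object, benefit_cost_ratio = bcr,
         cost_saving = object$total < 0),
    class = "summary.cc_result"
  )
}

#' @export
print.summary.cc_result <- function(x, ...) {
  print(x$result)
  if (!is.na(x$benefit_cost_ratio))
    cat(sprintf("Benefit-cost ratio: %.3f\n", x$benefit_cost_ratio))
  cat(if (x$cost_saving) "The intervention is cost saving in this scenario.\n"
      else "The intervention is not cost saving in this scenario.\n")
  invisible(x)
}

#' Benefit-cost ratio of an evaluated scenario
#'
#' Convenience metric: monetised benefits (the negated sum of the
#' non-intervention components) divided by the intervention cost. A ratio
#' above 1 means every unit of currency invested returns more than one
#' unit in avoided productivity losses. Not part of the core
#' cost-consequence output, where costs and consequences are listed side
#' by side, but often requested as a single return-on-investment figure.
#'
#' @param result A `cc_result` (or a `cc_scenario`, which is evaluated
#'   first).
#' @return Ratio (dimensionless). `0` when no benefit component is
#'   modelled; error of class `wellcost_undefined_ratio_error` when the
#'   intervention cost is zero.
#' @export
benefit_cost_ratio <- function(result) {
  if (inherits(result, "cc_scenario")) result <- evaluate_scenario(result)
  if (!inherits(result, "cc_result"))
    cc_abort("'result' must be a 'cc_result' or 'cc_scenario'",
             "wellcost_validation_error")
  comp <- result$components
  interv <- comp[["intervention"]]
  if (interv == 0)
    cc_abort("benefit-cost ratio undefined: intervention cost is zero",
             "wellcost_undefined_ratio_error")
  benefits <- comp[setdiff(names(comp), "intervention")]
  if (!length(benefits)) return(0)
  (-sum(benefits)) / interv
}
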