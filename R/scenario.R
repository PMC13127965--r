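#' Scalar model inputs addressable in sensitivity analysis
#'
#' The closed list of identifiers naming the nine scalar inputs of the
#' cost-consequence model. Sensitivity and break-even functions accept only
#' these identifiers, and tornado ties are broken by this fixed order so
#' that output is byte-stable across runs.
#'
#' @format A character vector of length 9.
#' @seealso [one_way()], [tornado()], [break_even()]
#' @export
cc_parameters <- c(
  "n_participants", "cost_per_person", "fixed_cost",
  "absenteeism_per_day", "presenteeism_per_day", "turnover_per_case",
  "absenteeism_days_avoided", "presenteeism_days_avoided",
  "turnover_reduction_pp"
)

# component -> (unit-cost key, effect key); order fixes report row order
.cc_components <- list(
  absenteeism  = c(unit = "absenteeism_per_day",  effect = "absenteeism_days_avoided"),
  presenteeism = c(unit = "presenteeism_per_day", effect = "presenteeism_days_avoided"),
  turnover     = c(unit = "turnover_per_case",    effect = "turnover_reduction_pp")
)

.cc_unit_cost_keys <- vapply(.cc_components, `[[`, "", "unit")
.cc_effect_keys <- vapply(.cc_components, `[[`, "", "effect")

cc_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "wellcost_error", "error")))
}

.check_scalar <- function(x, field, scenario_name, min = NULL, any_sign = FALSE) {
  where <- if (is.null(scenario_name)) field else paste0(scenario_name, "$", field)
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    cc_abort(sprintf("'%s' must be a single finite number", where),
             "wellcost_validation_error", field = field)
  if (!any_sign && !is.null(min) && x < min)
    cc_abort(sprintf("'%s' must be >= %s (got %s)", where, min, x),
             "wellcost_validation_error", field = field)
  as.numeric(x)
}

#' Define a workplace intervention scenario
#'
#' Constructs and validates one scenario of the cost-consequence model: a
#' participating workforce, the intervention's cost structure, the monetary
#' unit costs of lost productivity, and the intervention's annual effect
#' sizes. The model covers a single year in a single currency; there is no
#' discounting.
#'
#' The intervention cost has two parts: `cost_per_person` scales with the
#' participating headcount, while `fixed_cost` is an organisation-level
#' lump sum (for example, working time released for all participants
#' regardless of headcount pricing).
#'
#' Unit costs and effects are optional by component. A component absent
#' from `effects` is *not modelled* — it is omitted from results rather
#' than contributing a zero saving. An effect present without its matching
#' unit cost is a validation error, since the effect cannot be monetised.
#' Effect sizes may be negative: a negative `absenteeism_days_avoided`
#' encodes an annual *increase* in absenteeism.
#'
#' `turnover_reduction_pp` is expressed in percentage points of the
#' participating headcount per year, so cases avoided equal
#' `n_participants * turnover_reduction_pp / 100`.
#'
#' @param name Scenario label (single string).
#' @param n_participants Employees receiving the intervention (persons,
#'   >= 1). Fractional values are permitted; sensitivity analysis treats
#'   headcount as continuous.
#' @param cost_per_person Intervention cost per participant per year
#'   (currency, >= 0).
#' @param fixed_cost Organisation-level intervention cost per year not
#'   scaling with headcount (currency, >= 0).
#' @param unit_costs Named list with any of `absenteeism_per_day`,
#'   `presenteeism_per_day` (currency per day) and `turnover_per_case`
#'   (currency per case), all >= 0.
#' @param effects Named list with any of `absenteeism_days_avoided`,
#'   `presenteeism_days_avoided` (days per participant per year) and
#'   `turnover_reduction_pp` (percentage points per year). Any sign.
#'
#' @return An object of class `cc_scenario`.
#' @examples
#' base <- cc_scenario("base_case", n_participants = 50, cost_per_person = 100,
#'   unit_costs = list(absenteeism_per_day = 189.76, presenteeism_per_day = 379.51),
#'   effects = list(absenteeism_days_avoided = 4.3, presenteeism_days_avoided = 9.6))
#' evaluate_scenario(base)
#' @export
cc_scenario <- function(name, n_participants, cost_per_person = 0,
                        fixed_cost = 0, unit_costs = list(), effects = list()) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    cc_abort("'name' must be a non-empty string", "wellcost_validation_error")
  x <- structure(
    list(
      name = name,
      n_participants = n_participants,
      cost_per_person = cost_per_person,
      fixed_cost = fixed_cost,
      unit_costs = unit_costs,
      effects = effects
    ),
    class = "cc_scenario"
  )
  validate_cc_scenario(x)
}

#' Validate a scenario object
#'
#' Checks every type invariant of the model: positive participating
#' headcount, non-negative costs, known component names, and that every
#' effect has a matching unit cost to monetise it. Called by
#' [cc_scenario()] and [read_scenarios()]; useful directly after manual
#' modification of a scenario.
#'
#' @param x A `cc_scenario` object.
#' @return `x`, invisibly unchanged, if valid; otherwise an error of class
#'   `wellcost_validation_error` naming the offending field.
#' @export
validate_cc_scenario <- function(x) {
  if (!inherits(x, "cc_scenario"))
    cc_abort("not a 'cc_scenario' object", "wellcost_validation_error")
  nm <- x$name
  x$n_participants <- .check_scalar(x$n_participants, "n_participants", nm, min = 1)
  x$cost_per_person <- .check_scalar(x$cost_per_person, "cost_per_person", nm, min = 0)
  x$fixed_cost <- .check_scalar(x$fixed_cost, "fixed_cost", nm, min = 0)

  for (slot in c("unit_costs", "effects")) {
    v <- x[[slot]]
    if (is.null(v)) v <- list()
    if (!is.list(v))
      cc_abort(sprintf("'%s$%s' must be a named list", nm, slot),
               "wellcost_validation_error", field = slot)
    allowed <- if (slot == "unit_costs") .cc_unit_cost_keys else .cc_effect_keys
    bad <- setdiff(names(v), allowed)
    if (length(bad) || (length(v) && is.null(names(v))))
      cc_abort(sprintf("unknown %s key(s) in scenario '%s': %s", slot, nm,
                       paste(if (length(bad)) bad else "<unnamed>", collapse = ", ")),
               "wellcost_validation_error", field = slot)
    x[[slot]] <- v
  }
  for (k in names(x$unit_costs))
    x$unit_costs[[k]] <- .check_scalar(x$unit_costs[[k]], k, nm, min = 0)
  for (k in names(x$effects))
    x$effects[[k]] <- .check_scalar(x$effects[[k]], k, nm, any_sign = TRUE)

  # an effect without its unit cost cannot be monetised
  for (comp in names(.cc_components)) {
    keys <- .cc_components[[comp]]
    if (!is.null(x$effects[[keys[["effect"]]]]) &&
        is.null(x$unit_costs[[keys[["unit"]]]]))
      cc_abort(sprintf(
        "scenario '%s': effect '%s' is present but unit cost '%s' is missing (component: %s)",
        nm, keys[["effect"]], keys[["unit"]], comp),
        "wellcost_validation_error", field = keys[["unit"]], component = comp)
  }
  invisible(x)
}

# Current value of one scalar parameter; error if its component is absent.
.get_parameter <- function(scenario, parameter) {
  if (!parameter %in% cc_parameters)
    cc_abort(sprintf("unknown parameter '%s' (must be one of: %s)",
                     parameter, paste(cc_parameters, collapse = ", ")),
             "wellcost_validation_error", field = parameter)
  if (parameter %in% names(scenario)) return(scenario[[parameter]])
  slot <- if (parameter %in% .cc_unit_cost_keys) "unit_costs" else "effects"
  v <- scenario[[slot]][[parameter]]
  if (is.null(v))
    cc_abort(sprintf("parameter '%s' is not present in scenario '%s'",
                     parameter, scenario$name),
             "wellcost_validation_error", field = parameter)
  v
}

#' Substitute one scalar input of a scenario
#'
#' Returns a copy of `scenario` with a single model input replaced,
#' leaving every other input unchanged — the elementary move of one-way
#' sensitivity analysis.
#'
#' @param scenario A `cc_scenario`.
#' @param parameter One identifier from [cc_parameters]. The referenced
#'   component must already be present in the scenario; substitution never
#'   adds a component.
#' @param value Replacement value.
#' @param check If `TRUE` (default) the substituted value must respect the
#'   type invariants (unit costs >= 0, headcount >= 1). `FALSE` skips the
#'   range checks, which is useful when probing the affine total outside
#'   the admissible input domain.
#' @return A `cc_scenario` with the substitution applied.
#' @export
with_parameter <- function(scenario, parameter, value, check = TRUE) {
  .get_parameter(scenario, parameter)  # existence + known identifier
  if (check) {
    min <- if (parameter == "n_participants") 1 else 0
    any_sign <- parameter %in% .cc_effect_keys
    value <- .check_scalar(value, parameter, scenario$name,
                           min = min, any_sign = any_sign)
  } else {
    value <- .check_scalar(value, parameter, scenario$name, any_sign = TRUE)
  }
  if (parameter %in% names(scenario)) {
    scenario[[parameter]] <- value
  } else if (parameter %in% .cc_unit_cost_keys) {
    scenario$unit_costs[[parameter]] <- value
  } else {
    scenario$effects[[parameter]] <- value
  }
  scenario
}

#' @export
print.cc_scenario <- function(x, ...) {
  cat(sprintf("Cost-consequence scenario: %s\n", x$name))
  cat(sprintf("  participants: %s\n", format(x$n_participants)))
  cat(sprintf("  intervention: %s per person + %s fixed per year\n",
              format_currency(x$cost_per_person, exact = TRUE),
              format_currency(x$fixed_cost, exact = TRUE)))
  for (comp in names(.cc_components)) {
    keys <- .cc_components[[comp]]
    unit <- x$unit_costs[[keys[["unit"]]]]
    eff <- x$effects[[keys[["effect"]]]]
    if (is.null(unit) && is.null(eff)) next
    unit_txt <- if (is.null(unit)) "unit cost not given" else
      paste0(format_currency(unit, exact = TRUE),
             if (comp == "turnover") "/case" else "/day")
    eff_txt <- if (is.null(eff)) "not modelled" else
      paste0(format(eff), if (comp == "turnover") " pp/year" else " days/year avoided")
    cat(sprintf("  %-12s %s, %s\n", paste0(comp, ":"), unit_txt, eff_txt))
  }
  invisible(x)
}
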