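#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the model twice with a single input set to the lower and
#' upper bound of its range, all other inputs held at their base values —
#' the standard one-way DSA move for a deterministic decision model.
#'
#' @param scenario A `cc_scenario`.
#' @param parameter One identifier from [cc_parameters]; its component
#'   must be present in the scenario.
#' @param low,high Bounds for the input (`low <= high`); each must respect
#'   the type invariants (unit costs >= 0, headcount >= 1).
#' @return List with elements `low` and `high`, each a `cc_result` from
#'   [evaluate_scenario()] on the substituted scenario.
#' @export
one_way <- function(scenario, parameter, low, high) {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || !is.finite(low) || !is.finite(high))
    cc_abort("'low' and 'high' must be single finite numbers",
             "wellcost_validation_error")
  if (low > high)
    cc_abort(sprintf("invalid range for '%s': low (%s) > high (%s)",
                     parameter, low, high),
             "wellcost_validation_error", field = parameter)
  list(
    low = evaluate_scenario(with_parameter(scenario, parameter, low)),
    high = evaluate_scenario(with_parameter(scenario, parameter, high))
  )
}

#' Default sensitivity ranges for a scenario
#'
#' Symmetric +/-50% bands around each base input value, for every
#' parameter present in the scenario. A scale-free default for a model
#' with no empirical input distributions; override any parameter by
#' passing explicit ranges to [tornado()] (or `dsa_ranges` in a config
#' file). For negative base values (effects encoding a worsening) the
#' band is sorted so that `low <= high`. Lower bounds for
#' `n_participants` are floored at 1 to respect the headcount invariant.
#'
#' @param scenario A `cc_scenario`.
#' @param fraction Half-width of the band as a fraction of the base value
#'   (default 0.5).
#' @return Data frame with columns `parameter`, `low`, `high`, in
#'   canonical parameter order.
#' @export
default_dsa_ranges <- function(scenario, fraction = 0.5) {
  present <- cc_parameters[vapply(cc_parameters, function(p) {
    !inherits(try(.get_parameter(scenario, p), silent = TRUE), "try-error")
  }, logical(1))]
  rows <- lapply(present, function(p) {
    base <- .get_parameter(scenario, p)
    bounds <- sort(c(base * (1 - fraction), base * (1 + fraction)))
    if (p == "n_participants") bounds <- pmax(bounds, 1)
    data.frame(parameter = p, low = bounds[1], high = bounds[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tornado table for one-way sensitivity analysis
#'
#' Runs [one_way()] for each supplied parameter range and orders the
#' entries by descending span (the absolute difference between the totals
#' at the two bounds), the ordering used to draw a tornado diagram. Ties
#' are broken by the fixed [cc_parameters] order so output is
#' deterministic.
#'
#' @param scenario A `cc_scenario`.
#' @param ranges Data frame (or list of lists) with columns/fields
#'   `parameter`, `low`, `high`. Defaults to [default_dsa_ranges()].
#' @return A `cc_tornado` data frame with columns `parameter`, `low`,
#'   `high`, `total_at_low`, `total_at_high`, `span`, sorted by
#'   descending span. Plot it for a tornado diagram; serialise with
#'   [write_report_csv()].
#' @examples
#' torn <- tornado(bundled_scenarios()$base_case)
#' torn$parameter[1]  # the most influential input
#' @export
tornado <- function(scenario, ranges = default_dsa_ranges(scenario)) {
  if (is.list(ranges) && !is.data.frame(ranges))
    ranges <- do.call(rbind, lapply(ranges, function(r)
      data.frame(parameter = r$parameter, low = r$low, high = r$high,
                 stringsAsFactors = FALSE)))
  if (is.null(ranges) || !NROW(ranges)) {
    out <- data.frame(parameter = character(), low = numeric(),
                      high = numeric(), total_at_low = numeric(),
                      total_at_high = numeric(), span = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("cc_tornado", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    p <- ranges$parameter[i]
    res <- one_way(scenario, p, ranges$low[i], ranges$high[i])
    data.frame(parameter = p, low = ranges$low[i], high = ranges$high[i],
               total_at_low = res$low$total, total_at_high = res$high$total,
               span = abs(res$high$total - res$low$total),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$span, match(out$parameter, cc_parameters))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cc_tornado", "data.frame")
  out
}

#' @export
print.cc_tornado <- function(x, ...) {
  cat("One-way sensitivity analysis (tornado order)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Tornado diagram
#'
#' Horizontal bar chart of the one-way sensitivity totals: one bar per
#' parameter spanning `total_at_low` to `total_at_high`, widest span on
#' top, with a vertical reference line at the base-case total when
#' supplied.
#'
#' @param x A `cc_tornado` table.
#' @param base_total Optional base-case total incremental cost, drawn as a
#'   dashed reference line.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cc_tornado <- function(x, base_total = NULL, ...) {
  if (!nrow(x)) {
    warning("empty tornado table; nothing to plot")
    return(invisible(x))
  }
  n <- nrow(x)
  lo <- pmin(x$total_at_low, x$total_at_high)
  hi <- pmax(x$total_at_low, x$total_at_high)
  xlim <- range(c(lo, hi, base_total))
  old <- graphics::par(mar = c(4.5, 11, 2.5, 1))
  on.exit(graphics::par(old))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "Total incremental cost", ylab = "",
                 main = "One-way sensitivity analysis", ...)
  ypos <- rev(seq_len(n))  # widest bar on top
  graphics::rect(lo, ypos - 0.35, hi, ypos + 0.35, col = "steelblue",
                 border = "grey30")
  graphics::axis(2, at = ypos, labels = x$parameter, las = 1, cex.axis = 0.8)
  if (!is.null(base_total))
    graphics::abline(v = base_total, lty = 2, col = "grey40")
  invisible(x)
}

#' Break-even (threshold) analysis
#'
#' Solves for the value of one input at which the total incremental cost
#' is exactly zero — the point where the intervention switches between
#' cost incurring and cost saving. The model is affine in every scalar
#' input, so the threshold is found in closed form from the affine
#' coefficients rather than by search.
#'
#' No threshold exists when the input has a zero coefficient (for
#' example, a unit cost whose effect size is zero), or when the input is
#' `n_participants` with no fixed cost: total cost then scales
#' proportionally with headcount and never crosses zero. Both cases raise
#' an error of class `wellcost_no_threshold_error`.
#'
#' The returned threshold is the algebraic root and may fall outside the
#' admissible input domain (for example, a negative unit cost or a
#' fractional headcount); this is deliberate — threshold values are
#' decision-relevant even when unattainable, signalling that no
#' attainable value breaks even.
#'
#' @param scenario A `cc_scenario`.
#' @param parameter One identifier from [cc_parameters]; its component
#'   must be present in the scenario.
#' @return The threshold value of the input (numeric scalar).
#' @examples
#' break_even(bundled_scenarios()$base_case, "cost_per_person")  # 4459.264
#' @export
break_even <- function(scenario, parameter) {
  base_value <- .get_parameter(scenario, parameter)
  base_total <- evaluate_scenario(scenario)$total
  slope <- .affine_slope(scenario, parameter)
  if (slope == 0)
    cc_abort(sprintf(
      "no break-even threshold: total cost does not depend on '%s' in scenario '%s'",
      parameter, scenario$name),
      "wellcost_no_threshold_error", field = parameter)
  if (parameter == "n_participants" && scenario$fixed_cost == 0)
    cc_abort(sprintf(
      "no break-even threshold for 'n_participants' in scenario '%s': with no fixed cost the total scales with headcount and never crosses zero",
      scenario$name),
      "wellcost_no_threshold_error", field = parameter)
  base_value - base_total / slope
}

# d(total)/d(parameter): the model is affine, so these are exact.
.affine_slope <- function(scenario, parameter) {
  N <- scenario$n_participants
  eff <- function(k) {
    v <- scenario$effects[[k]]
    if (is.null(v)) 0 else v
  }
  unit <- function(k) {
    v <- scenario$unit_costs[[k]]
    if (is.null(v)) 0 else v
  }
  switch(parameter,
    n_participants = scenario$cost_per_person -
      (eff("absenteeism_days_avoided") * unit("absenteeism_per_day") +
       eff("presenteeism_days_avoided") * unit("presenteeism_per_day") +
       eff("turnover_reduction_pp") / 100 * unit("turnover_per_case")),
    cost_per_person = N,
    fixed_cost = 1,
    absenteeism_per_day = -N * eff("absenteeism_days_avoided"),
    presenteeism_per_day = -N * eff("presenteeism_days_avoided"),
    turnover_per_case = -N * eff("turnover_reduction_pp") / 100,
    absenteeism_days_avoided = -N * unit("absenteeism_per_day"),
    presenteeism_days_avoided = -N * unit("presenteeism_per_day"),
    turnover_reduction_pp = -N * unit("turnover_per_case") / 100
  )
}
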