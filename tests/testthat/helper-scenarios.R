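# Shared test helpers: random scenario generator and an independent
# bisection oracle for break-even thresholds.

get_param <- function(s, p) {
  if (p %in% names(s)) s[[p]]
  else if (!is.null(s$unit_costs[[p]])) s$unit_costs[[p]]
  else s$effects[[p]]
}

# Random valid scenario; caller controls the RNG seed. Components are
# included independently (at least one), effects may be negative, and the
# fixed cost is zero half the time so both affine regimes get exercised.
random_scenario <- function(name = "random") {
  include <- stats::runif(3) < 0.7
  if (!any(include)) include[sample.int(3, 1)] <- TRUE
  unit_costs <- list()
  effects <- list()
  if (include[1]) {
    unit_costs$absenteeism_per_day <- stats::runif(1, 1, 500)
    effects$absenteeism_days_avoided <- stats::runif(1, -5, 15)
  }
  if (include[2]) {
    unit_costs$presenteeism_per_day <- stats::runif(1, 1, 600)
    effects$presenteeism_days_avoided <- stats::runif(1, -5, 20)
  }
  if (include[3]) {
    unit_costs$turnover_per_case <- stats::runif(1, 100, 30000)
    effects$turnover_reduction_pp <- stats::runif(1, -3, 5)
  }
  cc_scenario(
    name = name,
    n_participants = sample.int(1000, 1),
    cost_per_person = stats::runif(1, 0, 700),
    fixed_cost = if (stats::runif(1) < 0.5) 0 else stats::runif(1, 0, 120000),
    unit_costs = unit_costs,
    effects = effects
  )
}

# Parameters of a scenario on which the total actually depends, excluding
# the headcount-with-no-fixed-cost case where the total never crosses zero.
eligible_breakeven_parameters <- function(s) {
  present <- intersect(cc_parameters,
                       c("n_participants", "cost_per_person", "fixed_cost",
                         names(s$unit_costs), names(s$effects)))
  keep <- vapply(present, function(p) {
    f <- function(v) evaluate_scenario(with_parameter(s, p, v, check = FALSE))$total
    base <- get_param(s, p)
    slope <- f(base + 1) - f(base)
    if (slope == 0) return(FALSE)
    !(p == "n_participants" && s$fixed_cost == 0)
  }, logical(1))
  present[keep]
}

# Independent oracle: bracket-expansion + bisection on evaluate_scenario,
# never touching the closed-form solver.
bisect_break_even <- function(s, parameter, tol = 1e-10, maxit = 300L) {
  f <- function(v) evaluate_scenario(with_parameter(s, parameter, v, check = FALSE))$total
  base <- get_param(s, parameter)
  lo <- base - 1
  hi <- base + 1
  for (i in seq_len(80L)) {
    if (f(lo) * f(hi) <= 0) break
    w <- hi - lo
    lo <- lo - w
    hi <- hi + w
  }
  stopifnot(f(lo) * f(hi) <= 0)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    if (hi - lo < tol * max(1, abs(mid))) break
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
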