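test_that("component costs follow the model arithmetic on hand-built scenarios", {
  # hand arithmetic: -N * effect * unit cost per component, savings negative
  s <- cc_scenario("tiny", n_participants = 10, cost_per_person = 5,
                   unit_costs = list(absenteeism_per_day = 100),
                   effects = list(absenteeism_days_avoided = 1))
  comp <- component_costs(s)
  expect_equal(comp, c(absenteeism = -1000, intervention = 50))

  # large-company fixture: lump-sum intervention, equal daily unit costs
  s1 <- bundled_scenarios()$scenario_1
  comp1 <- component_costs(s1)
  expect_equal(comp1[["absenteeism"]], -600 * 1.3 * 216)   # -168480
  expect_equal(comp1[["presenteeism"]], -600 * 2.5 * 216)  # -324000
  expect_equal(comp1[["intervention"]], 110000)
  expect_false("turnover" %in% names(comp1))

  # turnover effect is percentage points of the participating headcount
  s4 <- bundled_scenarios()$scenario_4
  comp4 <- component_costs(s4)
  expect_equal(comp4[["turnover"]], -40 * (2 / 100) * 9119)  # -7295.2

  # null intervention: everything zero
  s0 <- cc_scenario("null", n_participants = 3,
                    unit_costs = list(absenteeism_per_day = 50),
                    effects = list(absenteeism_days_avoided = 0))
  expect_equal(unname(component_costs(s0)), c(0, 0))
})

test_that("evaluation sums components and divides by the participating headcount", {
  fx <- bundled_scenarios()
  r4 <- evaluate_scenario(fx$scenario_4)
  expect_equal(r4$total, sum(r4$components))
  expect_equal(r4$total, -5215.2)
  expect_equal(r4$net_per_person, -5215.2 / 40)

  # opt-in participation: denominator is the 75 opted-in employees
  r2 <- evaluate_scenario(fx$scenario_2)
  expect_equal(r2$total, 345)
  expect_equal(r2$net_per_person, 4.6)

  z <- evaluate_scenario(cc_scenario("zero", n_participants = 8))
  expect_equal(z$total, 0)
  expect_equal(z$net_per_person, 0)

  expect_equal(coef(r4), r4$components)
  expect_output(print(r4), "Total costs")
})

test_that("validation rejects inconsistent or degenerate scenarios", {
  # an effect that cannot be monetised names its component
  err <- tryCatch(
    cc_scenario("bad", n_participants = 10,
                effects = list(presenteeism_days_avoided = 2)),
    error = identity)
  expect_s3_class(err, "wellcost_validation_error")
  expect_match(conditionMessage(err), "presenteeism")

  expect_error(cc_scenario("none", n_participants = 0),
               class = "wellcost_validation_error")
  expect_error(cc_scenario("neg", n_participants = 5, cost_per_person = -1),
               class = "wellcost_validation_error")
  expect_error(
    cc_scenario("negunit", n_participants = 5,
                unit_costs = list(absenteeism_per_day = -10)),
    class = "wellcost_validation_error")
  expect_error(
    cc_scenario("typo", n_participants = 5,
                unit_costs = list(absenteeism_cost = 10)),
    class = "wellcost_validation_error")
})

test_that("benefit-cost ratio divides monetised benefits by intervention cost", {
  s <- cc_scenario("r", n_participants = 10, cost_per_person = 500,
                   unit_costs = list(absenteeism_per_day = 100),
                   effects = list(absenteeism_days_avoided = 10))
  # benefits -10000, intervention +5000
  expect_equal(benefit_cost_ratio(evaluate_scenario(s)), 2)

  expect_equal(benefit_cost_ratio(bundled_scenarios()$scenario_4),
               7295.2 / 2080)

  only_cost <- cc_scenario("cost_only", n_participants = 4, cost_per_person = 10)
  expect_equal(benefit_cost_ratio(evaluate_scenario(only_cost)), 0)

  free <- cc_scenario("free", n_participants = 4,
                      unit_costs = list(absenteeism_per_day = 100),
                      effects = list(absenteeism_days_avoided = 1))
  expect_error(benefit_cost_ratio(free),
               class = "wellcost_undefined_ratio_error")
})

test_that("model is additive, affine and sign-consistent across random scenarios", {
  set.seed(42)
  for (i in 1:60) {
    s <- random_scenario(paste0("prop_", i))
    r <- evaluate_scenario(s)
    # additivity: total is the exact component sum
    expect_identical(r$total, sum(r$components))
    expect_equal(r$net_per_person * s$n_participants, r$total)

    # affinity: with no fixed cost, doubling headcount doubles the total
    s0 <- s
    s0$fixed_cost <- 0
    r1 <- evaluate_scenario(s0)
    r2 <- evaluate_scenario(with_parameter(s0, "n_participants",
                                           2 * s0$n_participants))
    expect_equal(r2$total, 2 * r1$total)
    expect_equal(r2$net_per_person, r1$net_per_person)

    # sign: positive effects give non-positive benefit components,
    # and negating an effect negates its component
    for (comp in setdiff(names(r$components), "intervention")) {
      eff_key <- switch(comp, absenteeism = "absenteeism_days_avoided",
                        presenteeism = "presenteeism_days_avoided",
                        turnover = "turnover_reduction_pp")
      eff <- s$effects[[eff_key]]
      if (eff > 0) expect_lte(r$components[[comp]], 0)
      flipped <- evaluate_scenario(with_parameter(s, eff_key, -eff))
      expect_equal(flipped$components[[comp]], -r$components[[comp]])
    }
  }
})

test_that("an omitted effect and a zero effect give identical totals", {
  set.seed(7)
  for (i in 1:20) {
    s <- random_scenario(paste0("omit_", i))
    comp <- setdiff(names(component_costs(s)), "intervention")[1]
    eff_key <- switch(comp, absenteeism = "absenteeism_days_avoided",
                      presenteeism = "presenteeism_days_avoided",
                      turnover = "turnover_reduction_pp")
    zeroed <- with_parameter(s, eff_key, 0)
    omitted <- s
    omitted$effects[[eff_key]] <- NULL
    omitted <- validate_cc_scenario(omitted)
    expect_identical(evaluate_scenario(zeroed)$total,
                     evaluate_scenario(omitted)$total)
    # but the component row itself is present only when modelled
    expect_true(comp %in% names(component_costs(zeroed)))
    expect_false(comp %in% names(component_costs(omitted)))
  }
})
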