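test_that("utility weights subtract background morbidity and disability", {
  expect_equal(utility_weight("healthy", pyld = 0.05), 0.95)
  expect_equal(utility_weight("chd_later", pyld = 0.05), 0.869)
  expect_equal(utility_weight("chd_year1", pyld = 0.05), 0.869)
  expect_equal(utility_weight("stroke_later", pyld = 0.05), 0.724)
  expect_identical(utility_weight("dead_cvd", pyld = 0.05), 0)
  expect_identical(utility_weight("dead_other", pyld = 0.9), 0)
  expect_error(utility_weight("stroke_later", pyld = 0.8), "exceeds 1")
})

test_that("discount factors follow the closed form from the reference year", {
  expect_equal(discount_factor(2011, discount_spec(0.03)), 1.0)
  expect_equal(discount_factor(2021, discount_spec(0.03)), 1.03^-10)
  expect_equal(round(discount_factor(2021, discount_spec(0.03)), 4), 0.7441)
  expect_equal(discount_factor(2050, discount_spec(0)), 1.0)
  expect_error(discount_factor(2005, discount_spec(0.03)), "precedes")
  expect_error(discount_spec(-0.01), "non-negative")
})

test_that("state costs combine the base schedule with the scale-ups", {
  costs <- default_inputs()$costs
  expect_equal(state_cost("chd_year1", "female", 60, costs), 16258 * 1.2)
  expect_equal(state_cost("healthy", "female", 60, costs), 2381 * 1.2)
  expect_equal(state_cost("healthy", "female", 62, costs), 2381 * 1.2)
  expect_identical(state_cost("dead_cvd", "male", 70, costs), 0)
  # old-age multipliers kick in at 65, 75 and 85
  base65 <- subset(costs, sex == "male" & age_start == 65)$chd_subsequent_cost
  expect_equal(state_cost("chd_later", "male", 65, costs), base65 * 1.2 * 1.1)
  base77 <- subset(costs, sex == "male" & age_start == 75)$stroke_first_year_cost
  expect_equal(state_cost("stroke_year1", "male", 77, costs), base77 * 1.2 * 1.2)
  base90 <- subset(costs, sex == "female" & age_start == 90)$healthy_annual_cost
  expect_equal(state_cost("healthy", "female", 90, costs), base90 * 1.2 * 1.3)
})

test_that("accrual matches hand arithmetic on a single-cycle toy", {
  inp <- toy_inputs(n_bands = 1L, inc_chd = 0, inc_stroke = 0, cf_chd = 0,
                    cf_stroke = 0, bg_mort = 0, prev_chd = 0.2,
                    prev_stroke = 0.1, pyld = 0.05)
  traj <- run_cohort(inp, builtin_scenarios("do_nothing"))
  led <- accrue(traj, inp, discount_spec(0.03))
  # nobody moves: every cycle has 70% healthy, 20% CHD-later, 30% utility mix
  u <- 0.7 * 0.95 + 0.2 * (0.95 - 0.081) + 0.1 * (0.95 - 0.226)
  per_year_q <- u * sum(inp$population$count)
  y1 <- subset(led$detail, year == 2011)
  expect_equal(sum(y1$qalys), per_year_q, tolerance = 1e-12)
  expect_equal(sum(y1$qalys_disc), per_year_q, tolerance = 1e-12)  # factor 1
  # costs in 2011: ages 35-39 carry no old-age multiplier
  per_year_c <- (0.7 * 2000 + 0.2 * 5000 + 0.1 * 6000) * 1.2 *
    sum(inp$population$count)
  expect_equal(sum(y1$costs), per_year_c, tolerance = 1e-9)
})

test_that("discounted accrual equals undiscounted times closed-form factors", {
  inp <- default_inputs()
  led <- accrue(run_cohort(inp, builtin_scenarios("subst25")), inp,
                discount_spec(0.03))
  d <- led$detail
  expect_equal(d$qalys_disc, d$qalys * 1.03^-(d$year - 2011), tolerance = 1e-12)
  expect_equal(d$costs_disc, d$costs * 1.03^-(d$year - 2011), tolerance = 1e-12)
  led0 <- accrue(run_cohort(inp, builtin_scenarios("subst25")), inp,
                 discount_spec(0))
  expect_gte(led0$totals$qalys_disc, led$totals$qalys_disc)
  expect_equal(led0$totals$qalys_disc, led0$totals$qalys)
})

test_that("stratum-level ledgers sum exactly to totals", {
  inp <- default_inputs()
  led <- accrue(run_cohort(inp, builtin_scenarios("bread280")), inp)
  expect_equal(sum(led$detail$qalys_disc), led$totals$qalys_disc)
  expect_equal(sum(led$detail$costs_disc) + led$one_off_cost,
               led$totals$costs_disc)
})

test_that("a zero-effect zero-cost scenario is exactly null against do-nothing", {
  inp <- default_inputs()
  null_scen <- intervention_spec("null", 0, phase_in_years = 1L, one_off_cost = 0)
  comp <- accrue(run_cohort(inp, builtin_scenarios("do_nothing")), inp)
  led <- accrue(run_cohort(inp, null_scen), inp)
  inc <- incremental(led, comp)
  expect_identical(inc$delta_qalys, 0)
  expect_identical(inc$delta_costs, 0)
  expect_identical(inc$classification, "equivalent")
})

test_that("an identical scenario with a one-off cost differs only by that cost", {
  inp <- toy_inputs()
  comp <- accrue(run_cohort(inp, builtin_scenarios("do_nothing")), inp)
  costed <- intervention_spec("lawonly", 0, phase_in_years = 1L,
                              one_off_cost = 3680000)
  inc <- incremental(accrue(run_cohort(inp, costed), inp), comp)
  expect_identical(inc$delta_qalys, 0)
  expect_equal(inc$delta_costs, 3680000)
  expect_false(inc$classification == "dominant")
})

test_that("dominance classification matches its defining inequalities", {
  set.seed(42)
  for (i in 1:200) {
    dq <- round(rnorm(1, 0, 100), ifelse(i %% 5 == 0, 0, 4))
    dc <- round(rnorm(1, 0, 1e6), ifelse(i %% 7 == 0, 0, 2))
    if (i %% 11 == 0) dq <- 0
    if (i %% 13 == 0) dc <- 0
    cls <- classify_incremental(dq, dc)
    expect_identical(cls$classification == "dominant", dq > 0 && dc < 0)
    if (dq > 0 && dc > 0) {
      expect_identical(cls$classification, "icer")
      expect_equal(cls$icer, dc / dq)
    } else {
      expect_true(is.na(cls$icer))
    }
    if (dq < 0 && dc > 0) expect_identical(cls$classification, "dominated")
  }
})

test_that("incremental refuses ledgers from different inputs", {
  a <- generate_inputs(1); b <- generate_inputs(2)
  la <- accrue(run_cohort(a, builtin_scenarios("do_nothing")), a)
  lb <- accrue(run_cohort(b, builtin_scenarios("subst59")), b)
  expect_error(incremental(lb, la), "fingerprint")
})

test_that("per-capita values aggregate consistently across partitions", {
  inp <- default_inputs()
  comp <- accrue(run_cohort(inp, builtin_scenarios("do_nothing")), inp)
  inc <- incremental(accrue(run_cohort(inp, builtin_scenarios("subst59")), inp),
                     comp)
  whole <- per_capita(inc, inp$population, "all")
  expect_equal(whole$qalys_per_adult,
               inc$delta_qalys / sum(inp$population$count))
  for (axis in list(c("maori", "non_maori"), c("male", "female"),
                    c("under65", "65plus"))) {
    parts <- lapply(axis, per_capita, result = inc,
                    population = inp$population)
    pops <- vapply(parts, `[[`, numeric(1), "population")
    expect_equal(sum(pops), sum(inp$population$count))
    wq <- sum(pops * vapply(parts, `[[`, numeric(1), "qalys_per_adult")) / sum(pops)
    wc <- sum(pops * vapply(parts, `[[`, numeric(1), "cost_per_adult")) / sum(pops)
    expect_equal(wq, whole$qalys_per_adult, tolerance = 1e-9)
    expect_equal(wc, whole$cost_per_adult, tolerance = 1e-9)
  }
  expect_error(per_capita(inc, inp$population,
                          function(d) rep(FALSE, nrow(d))), "no strata")
})
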