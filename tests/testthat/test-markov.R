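test_that("secular trend applies the annual change and freezes at the end year", {
  expect_equal(trended_rate(0.01, -0.02, 2016, 2011, 2026), 0.01 * 0.98^5)
  expect_equal(trended_rate(0.01, -0.02, 2040, 2011, 2026), 0.01 * 0.98^15)
  expect_equal(trended_rate(0.01, -0.02, 2026, 2011, 2026),
               trended_rate(0.01, -0.02, 2035, 2011, 2026))
  expect_equal(trended_rate(0.037, 0, 2030), 0.037)
})

test_that("rate-to-probability conversion is exponential and bounded", {
  expect_equal(rate_to_prob(0), 0)
  expect_equal(rate_to_prob(0.01), 1 - exp(-0.01))
  expect_equal(round(rate_to_prob(0.01), 5), 0.00995)
  expect_lt(rate_to_prob(10), 1)
  expect_error(rate_to_prob(-0.1), "non-negative")
})

test_that("transition rows are stochastic and match the competing-risk formulas", {
  inp <- toy_inputs(inc_chd = 0.02, inc_stroke = 0.01, cf_chd = 0.06,
                    cf_stroke = 0.09, bg_mort = 0.03)
  st <- data.frame(sex = "female", ethnicity = "maori", age_start = 40)
  P <- transition_probabilities(st, 2015, inp)
  expect_equal(unname(rowSums(P)), rep(1, 7), tolerance = 1e-12)
  expect_true(all(P >= 0 & P <= 1))

  # independent brute-force enumeration of the exponential apportionment
  tot <- 0.02 + 0.01 + 0.03
  p_exit <- 1 - exp(-tot)
  expect_equal(P["healthy", "chd_year1"], p_exit * 0.02 / tot, tolerance = 1e-14)
  expect_equal(P["healthy", "stroke_year1"], p_exit * 0.01 / tot, tolerance = 1e-14)
  expect_equal(P["healthy", "dead_other"], p_exit * 0.03 / tot, tolerance = 1e-14)
  tot_c <- 0.06 + 0.03
  expect_equal(P["chd_year1", "dead_cvd"],
               (1 - exp(-tot_c)) * 0.06 / tot_c, tolerance = 1e-14)
  expect_equal(P["chd_year1", "chd_later"], exp(-tot_c), tolerance = 1e-14)
  # first-year survivors move on; nobody remains in a first-year state
  expect_equal(P["chd_year1", "chd_year1"], 0)
  expect_equal(P["stroke_year1", "stroke_year1"], 0)
})

test_that("scenario multipliers touch only the healthy-to-disease entries", {
  inp <- toy_inputs()
  st <- data.frame(sex = "male", ethnicity = "non_maori", age_start = 45)
  P0 <- transition_probabilities(st, 2015, inp)
  m <- incidence_multipliers(builtin_scenarios("subst59"), "male", 2015, inp,
                             band_starts = sort(unique(inp$strata$age_start)))
  P1 <- transition_probabilities(st, 2015, inp, multipliers = m)
  expect_lt(P1["healthy", "chd_year1"], P0["healthy", "chd_year1"])
  expect_lt(P1["healthy", "stroke_year1"], P0["healthy", "stroke_year1"])
  for (from in c("chd_year1", "chd_later", "stroke_year1", "stroke_later"))
    expect_equal(P1[from, ], P0[from, ], tolerance = 1e-14)
})

test_that("all-zero rates leave the cohort in place", {
  inp <- toy_inputs(inc_chd = 0, inc_stroke = 0, cf_chd = 0, cf_stroke = 0,
                    bg_mort = 0)
  st <- data.frame(sex = "female", ethnicity = "non_maori", age_start = 35)
  P <- transition_probabilities(st, 2012, inp)
  expect_equal(P["healthy", "healthy"], 1)
  expect_equal(P["chd_later", "chd_later"], 1)
  expect_equal(P["chd_year1", "chd_later"], 1)  # tunnel still advances
})

test_that("the cohort run matches a transition-matrix-power oracle to 1e-12", {
  inp <- toy_inputs(n_bands = 3L)
  traj <- run_cohort(inp, builtin_scenarios("do_nothing"))
  subs <- traj$subcohorts
  # constant rates + no trend: occupancy at cycle t is v0 %*% P^t
  i <- which(subs$sex == "male" & subs$ethnicity == "maori" & subs$age0 == 35)
  st <- data.frame(sex = "male", ethnicity = "maori", age_start = 35)
  P <- transition_probabilities(st, 2011, inp)
  v0 <- c(healthy = 1 - 0.02 - 0.01, chd_year1 = 0, chd_later = 0.02,
          stroke_year1 = 0, stroke_later = 0.01, dead_cvd = 0, dead_other = 0)
  for (t in c(1L, 2L, 5L, 20L, 60L)) {
    expect_equal(unname(traj$occupancy[i, , t]),
                 unname(drop(v0 %*% mat_power(P, t))), tolerance = 1e-12)
  }
})

test_that("occupancy is conserved at every cycle of a full run", {
  inp <- default_inputs()
  for (nm in c("do_nothing", "subst59")) {
    traj <- run_cohort(inp, builtin_scenarios(nm))
    sums <- apply(traj$occupancy, c(1, 3), sum)
    expect_lt(max(abs(sums - 1)), 1e-9)
  }
})

test_that("death is absorbing and everyone is dead by age 100", {
  traj <- run_cohort(default_inputs(), builtin_scenarios("bread280"))
  dead <- traj$occupancy[, "dead_cvd", ] + traj$occupancy[, "dead_other", ]
  expect_true(all(t(apply(dead, 1, diff)) >= -1e-12))
  # final cycle: every sub-cohort has reached age >= 100, fully absorbed
  final <- traj$occupancy[, , length(traj$years)]
  expect_equal(unname(final[, "dead_cvd"] + final[, "dead_other"]),
               rep(1, nrow(final)), tolerance = 1e-9)
})

test_that("the run is deterministic and interventions order healthy occupancy", {
  inp <- default_inputs()
  a <- run_cohort(inp, builtin_scenarios("do_nothing"))
  b <- run_cohort(inp, builtin_scenarios("do_nothing"))
  expect_identical(a$occupancy, b$occupancy)

  h_dn <- apply(a$occupancy[, "healthy", ], 2, sum)
  h25 <- apply(run_cohort(inp, builtin_scenarios("subst25"))$occupancy[, "healthy", ], 2, sum)
  h59 <- apply(run_cohort(inp, builtin_scenarios("subst59"))$occupancy[, "healthy", ], 2, sum)
  expect_true(all(h59 >= h25 - 1e-12))
  expect_true(all(h25 >= h_dn - 1e-12))
})

test_that("baseline prevalent cases start in the subsequent-year states", {
  inp <- toy_inputs(prev_chd = 0.1, prev_stroke = 0.05,
                    inc_chd = 0, inc_stroke = 0, cf_chd = 0, cf_stroke = 0,
                    bg_mort = 0)
  traj <- run_cohort(inp, builtin_scenarios("do_nothing"))
  first <- traj$occupancy[, , 1]
  expect_equal(unname(first[, "chd_later"]), rep(0.1, nrow(first)))
  expect_equal(unname(first[, "stroke_later"]), rep(0.05, nrow(first)))
  expect_true(all(first[, c("chd_year1", "stroke_year1")] == 0))
})

test_that("long-format export preserves occupancy and ages advance by one", {
  inp <- toy_inputs(n_bands = 2L)
  traj <- run_cohort(inp, builtin_scenarios("do_nothing"))
  long <- trajectory_long(traj)
  expect_equal(sum(long$fraction), length(traj$years) * nrow(traj$subcohorts))
  one <- long[long$sex == "male" & long$ethnicity == "maori" &
                long$age0 == 36 & long$state == "healthy", ]
  expect_equal(diff(one$age[order(one$year)]),
               rep(1L, length(traj$years) - 1L))
})
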