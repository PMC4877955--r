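# Shared fixtures, built in code.

# Default synthetic inputs at the pinned seed, generated once per test run.
default_inputs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_inputs(seed = 1L)
    cache
  }
})

# A miniature input set: one sex x one ethnicity is not possible (the strata
# enumeration is fixed), so the toy keeps all four sex/ethnicity cells but
# only `n_bands` age bands, constant rates and no secular trend. Suitable
# for closed-form/matrix-power oracles.
toy_inputs <- function(n_bands = 3L, inc_chd = 0.01, inc_stroke = 0.005,
                       cf_chd = 0.05, cf_stroke = 0.08, bg_mort = 0.02,
                       prev_chd = 0.02, prev_stroke = 0.01, pyld = 0.05) {
  band_starts <- seq(35L, by = 5L, length.out = n_bands)
  strata <- enumerate_strata(band_starts)
  epi <- cbind(strata, data.frame(
    inc_chd = inc_chd, inc_stroke = inc_stroke,
    cf_chd = cf_chd, cf_stroke = cf_stroke,
    prev_chd = prev_chd, prev_stroke = prev_stroke,
    bg_mort = bg_mort, pyld = pyld, dw_chd = 0.081, dw_stroke = 0.226))
  population <- cbind(strata[c("sex", "ethnicity", "age_band", "age_start")],
                      count = 1000)
  cs <- unique(strata[c("sex", "age_band", "age_start")])
  costs <- data.frame(sex = cs$sex, age_band = cs$age_band,
                      age_start = cs$age_start,
                      healthy_annual_cost = 2000,
                      chd_first_year_cost = 16000, chd_subsequent_cost = 5000,
                      stroke_first_year_cost = 20000, stroke_subsequent_cost = 6000,
                      stringsAsFactors = FALSE)
  cfg <- generator_config()
  trend <- cfg$trend
  trend$incidence_apc <- 0
  trend$case_fatality_apc <- 0
  trend$background_mortality_apc_non_maori <- 0
  trend$background_mortality_apc_maori <- 0
  inputs <- structure(list(
    strata = strata, population = population, epi = epi, costs = costs,
    trend = trend, sodium = cfg$sodium, morbidity = cfg$morbidity,
    bp_response = cfg$bp_response, hazard_ratios = cfg$hazard_ratios,
    generator_seed = 0L), class = "salt_inputs")
  inputs$fingerprint <- input_fingerprint(inputs)
  inputs
}

# matrix power by repeated multiplication (independent of the engine)
mat_power <- function(P, k) {
  out <- diag(nrow(P))
  for (i in seq_len(k)) out <- out %*% P
  out
}
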