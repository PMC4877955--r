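#' Validate a model-input set
#'
#' Checks every structural invariant the simulation relies on and returns the
#' violations as a character vector (empty when the inputs are valid). This is
#' a total function: malformed values produce violations, not errors, so it
#' can be used to vet hand-edited input files. Each message names the table,
#' the field and, for per-stratum quantities, the offending stratum.
#'
#' Checked invariants: complete 2 x 2 x 13 stratum enumeration; positive
#' population counts; non-negative rates; CHD/stroke incidence and background
#' mortality non-decreasing in age within sex x ethnicity; Maori rates at
#' least non-Maori rates at every age; prevalences in `[0, 1)` with the two
#' diseases jointly below 1; disability weights in `[0, 1)` with
#' `pyld + max(dw) < 1`; non-negative costs with first-year disease costs
#' above subsequent-year costs; sodium source shares summing to 1 with the
#' bread share inside the processed-food share; zero trend after the freeze
#' year is implied by construction (the freeze year itself is checked to be
#' at or after baseline).
#'
#' @param inputs a `salt_inputs` object.
#' @return character vector of violation messages; `character(0)` if valid.
#' @examples
#' length(validate_inputs(generate_inputs(seed = 1)))  # 0
#' @export
validate_inputs <- function(inputs) {
  v <- character(0)
  add <- function(...) v <<- c(v, sprintf(...))

  expected <- enumerate_strata()
  key_exp <- stratum_key(expected)
  key_got <- stratum_key(inputs$epi)
  missing <- setdiff(key_exp, key_got)
  for (m in missing) add("EpiRateTable: missing stratum %s", m)
  extra <- setdiff(key_got, key_exp)
  for (m in extra) add("EpiRateTable: unexpected stratum %s", m)
  if (length(missing) || length(extra)) return(v)

  epi <- inputs$epi[match(key_exp, key_got), ]
  keys <- key_exp

  pop <- inputs$population
  kp <- stratum_key(pop)
  if (!setequal(kp, key_exp)) {
    add("PopulationTable: stratum enumeration incomplete")
  } else {
    pop <- pop[match(key_exp, kp), ]
    bad <- which(!(pop$count > 0))
    for (i in bad) add("PopulationTable: count must be > 0 in stratum %s", keys[i])
  }

  rate_fields <- c("inc_chd", "inc_stroke", "cf_chd", "cf_stroke", "bg_mort")
  for (f in rate_fields) {
    bad <- which(epi[[f]] < 0 | !is.finite(epi[[f]]))
    for (i in bad) add("EpiRateTable: %s negative or non-finite in stratum %s", f, keys[i])
  }
  for (f in c("prev_chd", "prev_stroke")) {
    bad <- which(epi[[f]] < 0 | epi[[f]] >= 1)
    for (i in bad) add("EpiRateTable: %s outside [0, 1) in stratum %s", f, keys[i])
  }
  bad <- which(epi$prev_chd + epi$prev_stroke >= 1)
  for (i in bad) add("EpiRateTable: prev_chd + prev_stroke >= 1 in stratum %s", keys[i])

  # age-monotone incidence and background mortality within sex x ethnicity
  for (f in c("inc_chd", "inc_stroke", "bg_mort")) {
    for (s in SALT_SEXES) for (e in SALT_ETHNICITIES) {
      i <- which(epi$sex == s & epi$ethnicity == e)
      i <- i[order(epi$age_start[i])]
      drop <- which(diff(epi[[f]][i]) < -1e-12)
      for (d in drop)
        add("EpiRateTable: %s decreases with age at stratum %s", f, keys[i[d + 1L]])
    }
  }
  # ethnic ordering: Maori rate >= non-Maori at every age
  for (f in rate_fields) {
    for (s in SALT_SEXES) {
      im <- which(epi$sex == s & epi$ethnicity == "maori")
      inm <- which(epi$sex == s & epi$ethnicity == "non_maori")
      im <- im[order(epi$age_start[im])]
      inm <- inm[order(epi$age_start[inm])]
      low <- which(epi[[f]][im] < epi[[f]][inm] - 1e-12)
      for (d in low)
        add("EpiRateTable: %s for maori below non_maori at stratum %s", f, keys[im[d]])
    }
  }

  for (f in c("dw_chd", "dw_stroke")) {
    bad <- which(epi[[f]] < 0 | epi[[f]] >= 1)
    for (i in bad) add("MorbidityTable: %s outside [0, 1) in stratum %s", f, keys[i])
  }
  bad <- which(epi$pyld < 0 | epi$pyld >= 1)
  for (i in bad) add("MorbidityTable: pyld outside [0, 1) in stratum %s", keys[i])
  bad <- which(epi$pyld + pmax(epi$dw_chd, epi$dw_stroke) >= 1)
  for (i in bad)
    add("MorbidityTable: pyld + max disability weight >= 1 in stratum %s", keys[i])

  co <- inputs$costs
  ck <- paste(co$sex, co$age_band, sep = "/")
  cost_fields <- c("healthy_annual_cost", "chd_first_year_cost", "chd_subsequent_cost",
                   "stroke_first_year_cost", "stroke_subsequent_cost")
  for (f in cost_fields) {
    bad <- which(co[[f]] < 0)
    for (i in bad) add("CostTable: %s negative in cell %s", f, ck[i])
  }
  bad <- which(co$chd_first_year_cost <= co$chd_subsequent_cost)
  for (i in bad) add("CostTable: chd_first_year_cost not above chd_subsequent_cost in cell %s", ck[i])
  bad <- which(co$stroke_first_year_cost <= co$stroke_subsequent_cost)
  for (i in bad) add("CostTable: stroke_first_year_cost not above stroke_subsequent_cost in cell %s", ck[i])

  so <- inputs$sodium
  if (abs(so$share_processed_food + so$share_table_salt + so$share_other - 1) > 1e-9)
    add("SodiumBaseline: source shares do not sum to 1")
  if (so$share_bread > so$share_processed_food + 1e-12)
    add("SodiumBaseline: share_bread exceeds share_processed_food")
  if (so$intake_male <= 0 || so$intake_female <= 0)
    add("SodiumBaseline: intakes must be positive")

  tr <- inputs$trend
  if (tr$trend_end_year < tr$baseline_year)
    add("TrendSpec: trend_end_year before baseline_year")

  bp <- inputs$bp_response
  if (any(bp$sbp_per_100mmol <= 0))
    add("BpResponseTable: sbp_per_100mmol must be positive")
  if (any(diff(bp$sbp_per_100mmol) < 0))
    add("BpResponseTable: sbp_per_100mmol must be non-decreasing in age")

  hr <- inputs$hazard_ratios
  hrt <- hazard_ratio_table(hr)
  if (any(hrt$hr_chd < hr$chd_lo - 1e-9 | hrt$hr_chd > hr$chd_hi + 1e-9))
    add("HazardRatioTable: CHD hazard ratio outside printed range")
  if (any(hrt$hr_stroke < hr$stroke_lo - 1e-9 | hrt$hr_stroke > hr$stroke_hi + 1e-9))
    add("HazardRatioTable: stroke hazard ratio outside printed range")
  if (any(diff(hrt$hr_chd) < -1e-12) || any(diff(hrt$hr_stroke) < -1e-12))
    add("HazardRatioTable: hazard ratios must be non-decreasing in age")

  v
}
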