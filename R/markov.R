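#' Apply a secular trend to an annual rate
#'
#' Rates decline (or grow) by a constant annual percentage change from the
#' baseline year until the trend end year, after which they are held
#' constant: `base_rate * (1 + apc) ^ min(year - baseline, end - baseline)`.
#'
#' @param base_rate annual rate at the baseline year.
#' @param apc annual percentage change as a fraction (e.g. -0.02).
#' @param year calendar year (>= baseline).
#' @param baseline_year,trend_end_year trend window.
#' @return trended rate.
#' @examples
#' trended_rate(0.01, -0.02, 2016, 2011, 2026)  # 0.01 * 0.98^5
#' @export
trended_rate <- function(base_rate, apc, year, baseline_year = 2011L,
                         trend_end_year = 2026L) {
  stopifnot(all(base_rate >= 0), all(year >= baseline_year))
  base_rate * (1 + apc)^pmin(year - baseline_year, trend_end_year - baseline_year)
}

#' Convert an annual event rate to an annual probability
#'
#' @param rate events per person-year (non-negative).
#' @return `1 - exp(-rate)`, in `[0, 1)`.
#' @export
rate_to_prob <- function(rate) {
  if (any(rate < 0)) stop("rate must be non-negative")
  1 - exp(-rate)
}

# competing-risk apportionment: total exit probability 1 - exp(-sum(rates)),
# split among causes in proportion to their rates. `rates` is a list of
# equal-length vectors; returns a list of per-cause probability vectors.
.competing_probs <- function(rates) {
  total <- Reduce(`+`, rates)
  p_exit <- 1 - exp(-total)
  share_denom <- ifelse(total > 0, total, 1)
  lapply(rates, function(r) p_exit * r / share_denom)
}

#' One-cycle transition probabilities for a stratum
#'
#' Builds the annual transition probability rows for one stratum and year.
#' Healthy-state exits use trended incidence (scaled by the scenario's
#' incidence multipliers) and background mortality; disease-state exits use
#' trended case fatality (to CVD death) and background mortality (to
#' other-cause death). Within a cycle, competing risks are resolved jointly:
#' total exit probability is `1 - exp(-sum(rates))`, apportioned among causes
#' in proportion to their rates, so each row sums to 1 by construction.
#' First-year disease occupants who survive move to the subsequent-year
#' state.
#'
#' @param stratum one-row data.frame with `sex`, `ethnicity`, `age_start`
#'   (the attained-age band of the people transitioning).
#' @param year calendar year of the cycle.
#' @param inputs a `salt_inputs` object.
#' @param multipliers optional data.frame from [incidence_multipliers()]
#'   (defaults to no intervention, i.e. multipliers of 1).
#' @return a 7 x 7 row-stochastic matrix over the states
#'   healthy, chd_year1, chd_later, stroke_year1, stroke_later, dead_cvd,
#'   dead_other.
#' @export
transition_probabilities <- function(stratum, year, inputs, multipliers = NULL) {
  epi <- inputs$epi
  i <- which(epi$sex == stratum$sex & epi$ethnicity == stratum$ethnicity &
               epi$age_start == stratum$age_start)
  if (length(i) != 1L)
    stop("no epidemiological rates for stratum ",
         paste(stratum$sex, stratum$ethnicity, stratum$age_start, sep = "/"))
  tr <- inputs$trend
  mult_chd <- mult_stroke <- 1
  if (!is.null(multipliers)) {
    j <- match(age_to_band_start(stratum$age_start, multipliers$age_start),
               multipliers$age_start)
    mult_chd <- multipliers$mult_chd[j]
    mult_stroke <- multipliers$mult_stroke[j]
  }
  bg_apc <- if (stratum$ethnicity == "maori")
    tr$background_mortality_apc_maori else tr$background_mortality_apc_non_maori
  inc_chd <- trended_rate(epi$inc_chd[i], tr$incidence_apc, year,
                          tr$baseline_year, tr$trend_end_year) * mult_chd
  inc_stroke <- trended_rate(epi$inc_stroke[i], tr$incidence_apc, year,
                             tr$baseline_year, tr$trend_end_year) * mult_stroke
  cf_chd <- trended_rate(epi$cf_chd[i], tr$case_fatality_apc, year,
                         tr$baseline_year, tr$trend_end_year)
  cf_stroke <- trended_rate(epi$cf_stroke[i], tr$case_fatality_apc, year,
                            tr$baseline_year, tr$trend_end_year)
  bg <- trended_rate(epi$bg_mort[i], bg_apc, year,
                     tr$baseline_year, tr$trend_end_year)

  P <- matrix(0, 7L, 7L, dimnames = list(SALT_STATES, SALT_STATES))
  h <- .competing_probs(list(chd = inc_chd, stroke = inc_stroke, other = bg))
  P["healthy", "chd_year1"] <- h$chd
  P["healthy", "stroke_year1"] <- h$stroke
  P["healthy", "dead_other"] <- h$other
  P["healthy", "healthy"] <- 1 - h$chd - h$stroke - h$other

  d_chd <- .competing_probs(list(cvd = cf_chd, other = bg))
  for (from in c("chd_year1", "chd_later")) {
    P[from, "dead_cvd"] <- d_chd$cvd
    P[from, "dead_other"] <- d_chd$other
    P[from, "chd_later"] <- 1 - d_chd$cvd - d_chd$other
  }
  d_str <- .competing_probs(list(cvd = cf_stroke, other = bg))
  for (from in c("stroke_year1", "stroke_later")) {
    P[from, "dead_cvd"] <- d_str$cvd
    P[from, "dead_other"] <- d_str$other
    P[from, "stroke_later"] <- 1 - d_str$cvd - d_str$other
  }
  P["dead_cvd", "dead_cvd"] <- 1
  P["dead_other", "dead_other"] <- 1
  P
}

# Expand the banded strata into single-year-of-age sub-cohorts, each carrying
# an equal share of its band's population. Rates are looked up by the band
# containing the attained age, so band values apply to every constituent age.
.subcohorts <- function(inputs, band_width = 5L) {
  strata <- inputs$strata
  reps <- rep(seq_len(nrow(strata)), each = band_width)
  offs <- rep(seq_len(band_width) - 1L, times = nrow(strata))
  pop <- inputs$population
  pk <- match(stratum_key(strata), stratum_key(pop))
  data.frame(stratum_row = reps,
             sex = strata$sex[reps], ethnicity = strata$ethnicity[reps],
             age_band_2011 = strata$age_band[reps],
             age_start_2011 = strata$age_start[reps],
             age0 = strata$age_start[reps] + offs,
             weight = pop$count[pk][reps] / band_width,
             stringsAsFactors = FALSE)
}

#' Run the closed-cohort simulation for one scenario
#'
#' Each five-year stratum is expanded into single-year-of-age sub-cohorts
#' that age one year per annual cycle from the baseline year until death or
#' age 100. State occupancy is recorded at the end of every cycle; rates are
#' looked up by the band containing the attained age, trended by calendar
#' year, and (for incidence from the healthy state) scaled by the scenario's
#' phase-in-aware multipliers. Baseline prevalent cases start in the
#' subsequent-year disease states. At the end of the age-99 cycle any
#' remaining alive occupancy is moved to other-cause death, so the cohort is
#' fully absorbed by age 100.
#'
#' @param inputs a `salt_inputs` object.
#' @param scenario a `salt_scenario` (e.g. from [builtin_scenarios()]).
#' @param max_age simulation hard stop (default 100).
#' @return an object of class `salt_trajectory`: occupancy array
#'   `[sub-cohort, state, year]`, the sub-cohort table, the cycle years, the
#'   scenario, and the inputs fingerprint.
#' @export
run_cohort <- function(inputs, scenario, max_age = 100L) {
  subs <- .subcohorts(inputs)
  band_starts <- sort(unique(inputs$strata$age_start))
  n <- nrow(subs)
  years <- seq.int(inputs$trend$baseline_year,
                   length.out = max_age - min(subs$age0))
  n_years <- length(years)
  tr <- inputs$trend

  # per-sub-cohort rate lookups (band of attained age, within sex/ethnicity)
  epi <- inputs$epi
  epi_key <- paste(epi$sex, epi$ethnicity, epi$age_start, sep = "/")
  bg_apc <- ifelse(subs$ethnicity == "maori",
                   tr$background_mortality_apc_maori,
                   tr$background_mortality_apc_non_maori)

  # initial occupancy: prevalent cases seed the subsequent-year states
  init_idx <- match(paste(subs$sex, subs$ethnicity,
                          age_to_band_start(subs$age0, band_starts), sep = "/"),
                    epi_key)
  occ <- matrix(0, n, 7L, dimnames = list(NULL, SALT_STATES))
  occ[, "chd_later"] <- epi$prev_chd[init_idx]
  occ[, "stroke_later"] <- epi$prev_stroke[init_idx]
  occ[, "healthy"] <- 1 - occ[, "chd_later"] - occ[, "stroke_later"]

  hrt <- hazard_ratio_table(inputs$hazard_ratios, band_starts)
  out <- array(NA_real_, c(n, 7L, n_years),
               dimnames = list(NULL, SALT_STATES, years))

  for (t in seq_len(n_years)) {
    year <- years[t]
    age <- subs$age0 + (t - 1L)
    active <- age < max_age
    if (any(active)) {
      a <- which(active)
      band <- age_to_band_start(age[a], band_starts)
      idx <- match(paste(subs$sex[a], subs$ethnicity[a], band, sep = "/"), epi_key)
      tf_inc <- (1 + tr$incidence_apc)^
        min(year - tr$baseline_year, tr$trend_end_year - tr$baseline_year)
      tf_cf <- (1 + tr$case_fatality_apc)^
        min(year - tr$baseline_year, tr$trend_end_year - tr$baseline_year)
      tf_bg <- (1 + bg_apc[a])^
        pmin(year - tr$baseline_year, tr$trend_end_year - tr$baseline_year)

      # scenario multipliers by sex and attained-age band
      mg <- ifelse(subs$sex[a] == "male",
                   sodium_reduction_mg(scenario, "male", year, inputs$sodium,
                                       tr$baseline_year),
                   sodium_reduction_mg(scenario, "female", year, inputs$sodium,
                                       tr$baseline_year))
      dsbp <- bp_reduction(mg_to_mmol(mg), band, inputs$bp_response)
      hj <- match(band, hrt$age_start)
      m_chd <- rate_multiplier(dsbp, hrt$hr_chd[hj])
      m_str <- rate_multiplier(dsbp, hrt$hr_stroke[hj])

      inc_chd <- epi$inc_chd[idx] * tf_inc * m_chd
      inc_str <- epi$inc_stroke[idx] * tf_inc * m_str
      cf_chd <- epi$cf_chd[idx] * tf_cf
      cf_str <- epi$cf_stroke[idx] * tf_cf
      bg <- epi$bg_mort[idx] * tf_bg

      h <- .competing_probs(list(chd = inc_chd, stroke = inc_str, other = bg))
      dc <- .competing_probs(list(cvd = cf_chd, other = bg))
      ds <- .competing_probs(list(cvd = cf_str, other = bg))

      H <- occ[a, "healthy"]
      C1 <- occ[a, "chd_year1"]; CL <- occ[a, "chd_later"]
      S1 <- occ[a, "stroke_year1"]; SL <- occ[a, "stroke_later"]
      chd_all <- C1 + CL; str_all <- S1 + SL

      occ[a, "healthy"] <- H * (1 - h$chd - h$stroke - h$other)
      occ[a, "chd_year1"] <- H * h$chd
      occ[a, "stroke_year1"] <- H * h$stroke
      occ[a, "chd_later"] <- chd_all * (1 - dc$cvd - dc$other)
      occ[a, "stroke_later"] <- str_all * (1 - ds$cvd - ds$other)
      occ[a, "dead_cvd"] <- occ[a, "dead_cvd"] + chd_all * dc$cvd + str_all * ds$cvd
      occ[a, "dead_other"] <- occ[a, "dead_other"] + H * h$other +
        chd_all * dc$other + str_all * ds$other

      # terminal absorption: survivors of the age-99 cycle reach the hard stop
      last <- a[age[a] == max_age - 1L]
      if (length(last)) {
        alive <- rowSums(occ[last, SALT_ALIVE_STATES, drop = FALSE])
        occ[last, "dead_other"] <- occ[last, "dead_other"] + alive
        occ[last, SALT_ALIVE_STATES] <- 0
      }
    }
    out[, , t] <- occ
  }

  structure(list(occupancy = out, subcohorts = subs, years = years,
                 scenario = scenario, fingerprint = inputs$fingerprint),
            class = "salt_trajectory")
}

#' @export
print.salt_trajectory <- function(x, ...) {
  n_people <- sum(x$subcohorts$weight)
  last <- x$occupancy[, , length(x$years)]
  dead <- sum((last[, "dead_cvd"] + last[, "dead_other"]) * x$subcohorts$weight)
  cat(sprintf("Cohort trajectory, scenario '%s'\n", x$scenario$name))
  cat(sprintf("  %d sub-cohorts (%s persons), cycles %d-%d\n",
              nrow(x$subcohorts), format(round(n_people), big.mark = ","),
              min(x$years), max(x$years)))
  cat(sprintf("  absorbed by final cycle: %.1f%% of cohort\n", 100 * dead / n_people))
  invisible(x)
}

#' Export a trajectory as a long-format data.frame
#'
#' @param trajectory a `salt_trajectory`.
#' @return data.frame with one row per sub-cohort, year and state:
#'   `sex, ethnicity, age_band_2011, age0, year, age, state, fraction`.
#' @export
trajectory_long <- function(trajectory) {
  subs <- trajectory$subcohorts
  years <- trajectory$years
  n <- nrow(subs); ny <- length(years)
  df <- data.frame(
    sex = rep(subs$sex, times = 7L * ny),
    ethnicity = rep(subs$ethnicity, times = 7L * ny),
    age_band_2011 = rep(subs$age_band_2011, times = 7L * ny),
    age0 = rep(subs$age0, times = 7L * ny),
    year = rep(rep(years, each = n * 7L)),
    state = rep(rep(SALT_STATES, each = n), times = ny),
    fraction = as.vector(trajectory$occupancy),
    stringsAsFactors = FALSE
  )
  df$age <- df$age0 + (df$year - years[1L])
  df[c("sex", "ethnicity", "age_band_2011", "age0", "year", "age",
       "state", "fraction")]
}
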