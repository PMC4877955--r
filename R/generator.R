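#' Default settings for the synthetic-input generator
#'
#' Anchor values are taken from published national figures for the 2011 New
#' Zealand adult (35+) population: baseline sodium intakes of 4013 mg/day for
#' men and 3115 mg/day for women (average adult 3544 mg/day), disability
#' weights of 0.081 for CHD and 0.226 for stroke, and 2011 health-system costs
#' for a 60-year-old woman of NZ$2381/year in the healthy state, NZ$16,258 /
#' NZ$5,395 for the first / subsequent years of CHD and NZ$20,553 / NZ$5,991
#' for stroke. Rate surfaces are Gompertz-like (log-rate linear in age) with
#' multiplicative ethnic and sex differentials; their levels and slopes are
#' plausible magnitudes for a developed-country 35+ population, not published
#' point estimates.
#'
#' @param total_population cohort size (persons aged 35+).
#' @param noise_sd standard deviation of the multiplicative log-normal
#'   perturbation applied to the epidemiological rate surfaces.
#' @return a list of generator settings, suitable for [generate_inputs()].
#' @export
generator_config <- function(total_population = 2300000, noise_sd = 0.05) {
  list(
    total_population = total_population,
    noise_sd = noise_sd,
    baseline_year = 2011L,
    # secular trends (annual percentage change), frozen after trend_end_year
    trend = list(
      incidence_apc = -0.020,
      case_fatality_apc = -0.020,
      background_mortality_apc_non_maori = -0.0175,
      background_mortality_apc_maori = -0.0225,
      trend_end_year = 2026L,
      baseline_year = 2011L
    ),
    # baseline daily sodium intake (mg/day) and source shares
    sodium = list(
      intake_male = 4013,
      intake_female = 3115,
      intake_average_adult = 3544,
      share_processed_food = 0.72,
      share_table_salt = 0.15,
      share_other = 0.13,
      share_bread = 0.206
    ),
    # disability weights with 95% CI bounds used for uncertainty sampling
    morbidity = list(
      dw_chd = 0.081, dw_chd_lo = 0.05, dw_chd_hi = 0.11,
      dw_stroke = 0.226, dw_stroke_lo = 0.11, dw_stroke_hi = 0.23,
      pyld_at_35 = 0.04, pyld_slope = 0.0022, pyld_maori_extra = 0.02
    ),
    # cost anchors (2011 NZ$, female 60-64 stratum) and age gradients
    costs = list(
      healthy_anchor = 2381, healthy_age_slope = 0.025, healthy_male_factor = 0.95,
      chd_first_anchor = 16258, chd_subsequent_anchor = 5395,
      stroke_first_anchor = 20553, stroke_subsequent_anchor = 5991,
      disease_age_slope = 0.01, anchor_age = 60L
    ),
    # Gompertz rate surfaces: rate(age) = level * exp(slope * (age - ref_age))
    epi = list(
      chd_inc_level = 5e-4, chd_inc_slope = 0.085, chd_inc_ref_age = 45,
      chd_inc_male_factor = 1.5, chd_inc_maori_factor = 1.8,
      stroke_inc_level = 3e-4, stroke_inc_slope = 0.095, stroke_inc_ref_age = 45,
      stroke_inc_male_factor = 1.2, stroke_inc_maori_factor = 1.7,
      chd_cf_level = 0.02, chd_cf_slope = 0.05, chd_cf_ref_age = 45,
      stroke_cf_level = 0.03, stroke_cf_slope = 0.05, stroke_cf_ref_age = 45,
      cf_male_factor = 1.1, cf_maori_factor = 1.3,
      bg_mort_level = 6e-4, bg_mort_slope = 0.092, bg_mort_ref_age = 35,
      bg_mort_male_factor = 1.4, bg_mort_maori_factor = 1.6,
      chd_duration = 8, stroke_duration = 6, prevalence_cap = 0.4
    ),
    # age-specific systolic BP response (mmHg per 100 mmol/day sodium change)
    bp_response = list(age_starts = c(30, 40, 50, 60),
                       sbp_per_100mmol = c(5.5, 6.6, 9.2, 10.3)),
    # hazard ratio per 20 mmHg systolic BP reduction: printed range endpoints,
    # interpolated log-linearly in age between 40 (youngest anchor) and 85
    hazard_ratios = list(chd_lo = 0.49, chd_hi = 0.67,
                         stroke_lo = 0.38, stroke_hi = 0.67,
                         anchor_young_age = 40, anchor_old_age = 85)
  )
}

# deterministic band-share schedule for the 2011 NZ 35+ age pyramid
.population_band_weights <- function() {
  w <- c(300, 310, 300, 280, 240, 215, 170, 135, 105, 80, 48, 20, 5)
  w / sum(w)
}

.gompertz <- function(age, level, slope, ref_age) level * exp(slope * (age - ref_age))

#' Generate a full synthetic model-input set
#'
#' Emulates the administrative tables the simulation consumes: per-stratum
#' CHD/stroke incidence, case fatality and prevalence, background (non-CVD)
#' mortality, prevalent-YLD morbidity, health-system cost schedules, the
#' population pyramid, secular-trend settings and the sodium baseline. Rate
#' surfaces are log-linear in age with a seeded multiplicative perturbation;
#' monotone-in-age and Maori >= non-Maori orderings are enforced after
#' perturbation, and all anchor values are reproduced exactly regardless of
#' the seed.
#'
#' @param seed integer; the generator is a pure function of `(seed, config)`.
#' @param config settings from [generator_config()].
#' @return an object of class `salt_inputs`.
#' @examples
#' inp <- generate_inputs(seed = 1)
#' subset(inp$costs, sex == "female" & age_band == "60-64")$healthy_annual_cost
#' @export
generate_inputs <- function(seed = 1L, config = generator_config()) {
  check_generator_config(config)
  strata <- enumerate_strata()
  n <- nrow(strata)
  ep <- config$epi

  # mid-band age drives the deterministic part of each rate surface
  mid_age <- strata$age_start + 2

  male <- strata$sex == "male"
  maori <- strata$ethnicity == "maori"

  base_surface <- function(level, slope, ref_age, male_factor, maori_factor) {
    .gompertz(mid_age, level, slope, ref_age) *
      ifelse(male, male_factor, 1) * ifelse(maori, maori_factor, 1)
  }

  inc_chd <- base_surface(ep$chd_inc_level, ep$chd_inc_slope, ep$chd_inc_ref_age,
                          ep$chd_inc_male_factor, ep$chd_inc_maori_factor)
  inc_stroke <- base_surface(ep$stroke_inc_level, ep$stroke_inc_slope,
                             ep$stroke_inc_ref_age,
                             ep$stroke_inc_male_factor, ep$stroke_inc_maori_factor)
  cf_chd <- base_surface(ep$chd_cf_level, ep$chd_cf_slope, ep$chd_cf_ref_age,
                         ep$cf_male_factor, ep$cf_maori_factor)
  cf_stroke <- base_surface(ep$stroke_cf_level, ep$stroke_cf_slope,
                            ep$stroke_cf_ref_age,
                            ep$cf_male_factor, ep$cf_maori_factor)
  bg_mort <- base_surface(ep$bg_mort_level, ep$bg_mort_slope, ep$bg_mort_ref_age,
                          ep$bg_mort_male_factor, ep$bg_mort_maori_factor)

  # seeded multiplicative perturbation on the rate surfaces only; anchors,
  # costs, morbidity and the population pyramid stay deterministic
  perturb <- with_local_seed(seed, {
    matrix(exp(stats::rnorm(n * 5L, mean = 0, sd = config$noise_sd)), ncol = 5L)
  })
  inc_chd <- inc_chd * perturb[, 1L]
  inc_stroke <- inc_stroke * perturb[, 2L]
  cf_chd <- cf_chd * perturb[, 3L]
  cf_stroke <- cf_stroke * perturb[, 4L]
  bg_mort <- bg_mort * perturb[, 5L]

  # restore the structural orderings the perturbation may break:
  # non-decreasing in age within sex x ethnicity, Maori >= non-Maori
  enforce <- function(x, monotone = TRUE) {
    for (s in SALT_SEXES) {
      if (monotone) {
        for (e in SALT_ETHNICITIES) {
          i <- which(strata$sex == s & strata$ethnicity == e)
          i <- i[order(strata$age_start[i])]
          x[i] <- cummax(x[i])
        }
      }
      im <- which(strata$sex == s & strata$ethnicity == "maori")
      inm <- which(strata$sex == s & strata$ethnicity == "non_maori")
      im <- im[order(strata$age_start[im])]
      inm <- inm[order(strata$age_start[inm])]
      x[im] <- pmax(x[im], x[inm])
    }
    x
  }
  inc_chd <- enforce(inc_chd)
  inc_stroke <- enforce(inc_stroke)
  cf_chd <- enforce(cf_chd)
  cf_stroke <- enforce(cf_stroke)
  bg_mort <- enforce(bg_mort)

  prev_chd <- pmin(ep$prevalence_cap, inc_chd * ep$chd_duration)
  prev_stroke <- pmin(ep$prevalence_cap, inc_stroke * ep$stroke_duration)

  mo <- config$morbidity
  pyld <- mo$pyld_at_35 + mo$pyld_slope * (mid_age - 35) +
    ifelse(maori, mo$pyld_maori_extra, 0)

  epi <- cbind(strata, data.frame(
    inc_chd = inc_chd, inc_stroke = inc_stroke,
    cf_chd = cf_chd, cf_stroke = cf_stroke,
    prev_chd = prev_chd, prev_stroke = prev_stroke,
    bg_mort = bg_mort, pyld = pyld,
    dw_chd = mo$dw_chd, dw_stroke = mo$dw_stroke
  ))

  # population pyramid: deterministic band schedule split by ethnicity and sex
  band_w <- .population_band_weights()
  names(band_w) <- band_label(SALT_BAND_STARTS)
  maori_share <- 0.12 * exp(-0.025 * (strata$age_start - 35))
  female_share <- pmin(0.65, 0.51 + 0.0016 * (strata$age_start - 35))
  eth_share <- ifelse(maori, maori_share, 1 - maori_share)
  sex_share <- ifelse(male, 1 - female_share, female_share)
  population <- cbind(strata[c("sex", "ethnicity", "age_band", "age_start")],
                      count = config$total_population *
                        band_w[strata$age_band] * eth_share * sex_share)
  rownames(population) <- NULL

  # cost schedules per sex x band, anchored exactly at the female 60-64 cell
  co <- config$costs
  cs <- unique(strata[c("sex", "age_band", "age_start")])
  cmale <- cs$sex == "male"
  age_d <- cs$age_start - co$anchor_age
  costs <- data.frame(
    sex = cs$sex, age_band = cs$age_band, age_start = cs$age_start,
    healthy_annual_cost = co$healthy_anchor * exp(co$healthy_age_slope * age_d) *
      ifelse(cmale, co$healthy_male_factor, 1),
    chd_first_year_cost = co$chd_first_anchor * exp(co$disease_age_slope * age_d),
    chd_subsequent_cost = co$chd_subsequent_anchor * exp(co$disease_age_slope * age_d),
    stroke_first_year_cost = co$stroke_first_anchor * exp(co$disease_age_slope * age_d),
    stroke_subsequent_cost = co$stroke_subsequent_anchor * exp(co$disease_age_slope * age_d),
    stringsAsFactors = FALSE
  )
  rownames(costs) <- NULL

  inputs <- structure(list(
    strata = strata,
    population = population,
    epi = epi,
    costs = costs,
    trend = config$trend,
    sodium = config$sodium,
    morbidity = mo,
    bp_response = config$bp_response,
    hazard_ratios = config$hazard_ratios,
    generator_seed = as.integer(seed)
  ), class = "salt_inputs")
  inputs$fingerprint <- input_fingerprint(inputs)
  inputs
}

#' @export
print.salt_inputs <- function(x, ...) {
  cat("Model inputs for a closed-cohort sodium-reduction simulation\n")
  cat(sprintf("  strata: %d (%d sexes x %d ethnicities x %d age bands)\n",
              nrow(x$strata), length(SALT_SEXES), length(SALT_ETHNICITIES),
              length(unique(x$strata$age_band))))
  cat(sprintf("  population: %s persons aged 35+\n",
              format(round(sum(x$population$count)), big.mark = ",")))
  cat(sprintf("  baseline year: %d; trends frozen after %d\n",
              x$trend$baseline_year, x$trend$trend_end_year))
  cat(sprintf("  sodium baseline: %g (men) / %g (women) mg/day\n",
              x$sodium$intake_male, x$sodium$intake_female))
  cat(sprintf("  generator seed: %d; fingerprint %s\n",
              x$generator_seed, x$fingerprint))
  invisible(x)
}

# evaluate expr under a private RNG state, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed))
  expr
}

check_generator_config <- function(config) {
  co <- config$costs
  if (co$chd_subsequent_anchor >= co$chd_first_anchor)
    stop("generator config invalid: chd_subsequent_anchor must be below chd_first_anchor")
  if (co$stroke_subsequent_anchor >= co$stroke_first_anchor)
    stop("generator config invalid: stroke_subsequent_anchor must be below stroke_first_anchor")
  so <- config$sodium
  if (abs(so$share_processed_food + so$share_table_salt + so$share_other - 1) > 1e-9)
    stop("generator config invalid: sodium source shares (share_processed_food, ",
         "share_table_salt, share_other) must sum to 1")
  if (so$share_bread > so$share_processed_food)
    stop("generator config invalid: share_bread cannot exceed share_processed_food")
  mo <- config$morbidity
  for (f in c("dw_chd", "dw_stroke"))
    if (mo[[f]] < 0 || mo[[f]] >= 1)
      stop("generator config invalid: ", f, " must lie in [0, 1)")
  invisible(TRUE)
}
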