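#' Define a sodium-reduction intervention scenario
#'
#' A scenario is characterised by the fraction of total daily sodium intake
#' removed at full implementation (for the average adult), the number of
#' equal annual phase-in steps, and a one-off implementation cost (the cost
#' of passing a law; default NZ$3,680,000 in 2011 dollars) charged
#' undiscounted in the cost year.
#'
#' @param name scenario identifier.
#' @param reduction_fraction fraction of daily sodium removed at full
#'   implementation, in `[0, 1)`.
#' @param phase_in_years number of equal annual steps (>= 1); 1 means full
#'   implementation in the baseline year.
#' @param one_off_cost NZ$ charged once at `cost_year`.
#' @param cost_year calendar year the one-off cost falls in.
#' @return an object of class `salt_scenario`.
#' @export
intervention_spec <- function(name, reduction_fraction, phase_in_years = 5L,
                              one_off_cost = 3680000, cost_year = 2011L) {
  stopifnot(is.character(name), length(name) == 1L)
  if (reduction_fraction < 0 || reduction_fraction >= 1)
    stop("reduction_fraction must lie in [0, 1)")
  if (phase_in_years < 1) stop("phase_in_years must be >= 1")
  if (one_off_cost < 0) stop("one_off_cost must be non-negative")
  structure(list(name = name,
                 reduction_fraction = reduction_fraction,
                 phase_in_years = as.integer(phase_in_years),
                 one_off_cost = one_off_cost,
                 cost_year = as.integer(cost_year)),
            class = "salt_scenario")
}

#' @export
print.salt_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %.1f%% sodium reduction, %d-year phase-in, one-off cost NZ$%s\n",
              x$name, 100 * x$reduction_fraction, x$phase_in_years,
              format(x$one_off_cost, big.mark = ",")))
  invisible(x)
}

#' Built-in intervention scenarios
#'
#' The four modelled interventions plus the do-nothing comparator:
#' \describe{
#'   \item{subst59}{59\% salt substitution in processed food and table salt:
#'     51.5\% sodium reduction, 5-year phase-in.}
#'   \item{subst25}{25\% salt substitution: 21.8\% reduction, 5-year phase-in.}
#'   \item{bread280}{maximum 280 mg sodium/100 g in bread: 7.9\% reduction,
#'     5-year phase-in.}
#'   \item{bread400}{maximum 400 mg sodium/100 g in bread: 2.3\% reduction,
#'     full implementation in the baseline year.}
#'   \item{do_nothing}{null comparator, zero reduction and zero cost.}
#' }
#'
#' @param name optional single scenario name; omit for the full named list.
#' @return a `salt_scenario`, or a named list of all five.
#' @export
builtin_scenarios <- function(name = NULL) {
  all <- list(
    subst59 = intervention_spec("subst59", 0.515, phase_in_years = 5L),
    subst25 = intervention_spec("subst25", 0.218, phase_in_years = 5L),
    bread280 = intervention_spec("bread280", 0.079, phase_in_years = 5L),
    bread400 = intervention_spec("bread400", 0.023, phase_in_years = 1L),
    do_nothing = intervention_spec("do_nothing", 0.0, phase_in_years = 1L,
                                   one_off_cost = 0)
  )
  if (is.null(name)) return(all)
  if (!name %in% names(all))
    stop("unknown scenario '", name, "'; built-ins are ",
         paste(names(all), collapse = ", "))
  all[[name]]
}

#' Phase-in fraction of an intervention in a calendar year
#'
#' Implementation ramps up in `phase_in_years` equal annual steps beginning
#' in the baseline year: step k applies for the whole of calendar year
#' `baseline_year + k - 1`, so the fraction in a year is
#' `min(1, (year - baseline_year + 1) / phase_in_years)`.
#'
#' @param spec a `salt_scenario`.
#' @param year calendar year (>= baseline).
#' @param baseline_year first implementation year (default 2011).
#' @return fraction in `[0, 1]`.
#' @examples
#' phase_in_fraction(builtin_scenarios("subst59"), 2011)  # 0.2
#' @export
phase_in_fraction <- function(spec, year, baseline_year = 2011L) {
  if (any(year < baseline_year))
    stop("year precedes the baseline year ", baseline_year)
  pmin(1, (year - baseline_year + 1) / spec$phase_in_years)
}

#' Sodium reduction delivered by a scenario, in mg/day
#'
#' The average-adult reduction fraction is rescaled to each sex by the ratio
#' of that sex's baseline intake to the average-adult intake, so the
#' reduction equals `reduction_fraction * sex intake * phase_in_fraction`.
#' `sex = "average"` uses the average-adult intake.
#'
#' @param spec a `salt_scenario`.
#' @param sex `"male"`, `"female"` or `"average"`.
#' @param year calendar year.
#' @param sodium sodium-baseline block of a `salt_inputs` object.
#' @param baseline_year first implementation year.
#' @return reduction in mg/day, never exceeding the sex's baseline intake.
#' @examples
#' so <- generator_config()$sodium
#' sodium_reduction_mg(builtin_scenarios("bread280"), "average", 2016, so)  # ~280
#' @export
sodium_reduction_mg <- function(spec, sex, year, sodium,
                                baseline_year = 2011L) {
  intake <- switch(sex,
                   male = sodium$intake_male,
                   female = sodium$intake_female,
                   average = sodium$intake_average_adult,
                   stop("sex must be 'male', 'female' or 'average'"))
  spec$reduction_fraction * intake * phase_in_fraction(spec, year, baseline_year)
}

#' Convert a sodium mass to moles
#'
#' @param mg sodium in mg/day (non-negative).
#' @return mmol/day (`mg / 23.0`, the molar mass of sodium).
#' @examples
#' round(mg_to_mmol(1824), 1)  # 79.3
#' @export
mg_to_mmol <- function(mg) {
  if (any(mg < 0)) stop("sodium mass must be non-negative")
  mg / 23.0
}

#' Bread-limit share arithmetic
#'
#' A legal maximum on sodium concentration in bread shifts bread's share of
#' total dietary sodium by the ratio of the post-law mean concentration to
#' the baseline mean concentration; the difference between old and new shares
#' is the absolute reduction fraction in total sodium intake.
#'
#' @param post_law_mg_per_100g assumed post-law mean concentration.
#' @param baseline_mg_per_100g baseline mean concentration (439 mg/100 g for
#'   New Zealand bread).
#' @param bread_share bread's baseline share of total sodium (0.206).
#' @return list with `new_share` and `absolute_reduction_fraction`.
#' @examples
#' bread_share_shift(270, 439, 0.206)  # new share 0.127, reduction 0.079
#' @export
bread_share_shift <- function(post_law_mg_per_100g, baseline_mg_per_100g,
                              bread_share = 0.206) {
  if (post_law_mg_per_100g <= 0 || baseline_mg_per_100g <= 0)
    stop("concentrations must be positive")
  if (post_law_mg_per_100g > baseline_mg_per_100g)
    stop("a maximum level cannot raise bread sodium above baseline")
  if (bread_share <= 0 || bread_share >= 1)
    stop("bread_share must lie in (0, 1)")
  new_share <- post_law_mg_per_100g / baseline_mg_per_100g * bread_share
  list(new_share = new_share,
       absolute_reduction_fraction = bread_share - new_share)
}
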