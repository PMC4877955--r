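#' Discounting
#'
#' Costs and health gains are discounted at a constant annual rate from the
#' reference (baseline) year: the factor for a calendar year is
#' `(1 + rate)^-(year - reference_year)`, so the baseline year itself is
#' undiscounted.
#'
#' @param rate annual discount rate as a fraction (default 0.03; scenario
#'   analyses use 0 and 0.06).
#' @param reference_year year with factor 1 (default 2011).
#' @return `discount_spec` returns a list; `discount_factor` the factor(s).
#' @examples
#' discount_factor(2021, discount_spec(0.03))  # 1.03^-10
#' @export
discount_spec <- function(rate = 0.03, reference_year = 2011L) {
  if (rate < 0) stop("discount rate must be non-negative")
  list(rate = rate, reference_year = as.integer(reference_year))
}

#' @param year calendar year(s) at or after the reference year.
#' @param spec a spec from [discount_spec()].
#' @rdname discount_spec
#' @export
discount_factor <- function(year, spec = discount_spec()) {
  if (any(year < spec$reference_year))
    stop("year precedes the discounting reference year")
  (1 + spec$rate)^(-(year - spec$reference_year))
}

#' Cost scale-up factors
#'
#' Administrative cost data miss some private expenditure and residential
#' care: all state costs are scaled by the public-share factor 1.2
#' (1 / 0.83, the public share of health spending), and costs at older ages
#' are additionally multiplied by 1.1, 1.2 and 1.3 for ages 65-74, 75-84 and
#' 85+ respectively.
#'
#' @return list with `public_share_factor` and `old_age_multipliers`.
#' @export
cost_scaleups <- function() {
  list(public_share_factor = 1.2,
       old_age_multipliers = c("65-74" = 1.1, "75-84" = 1.2, "85+" = 1.3))
}

.old_age_multiplier <- function(age, scaleups = cost_scaleups()) {
  m <- scaleups$old_age_multipliers
  ifelse(age >= 85, m[["85+"]],
         ifelse(age >= 75, m[["75-84"]],
                ifelse(age >= 65, m[["65-74"]], 1)))
}

#' Utility weight of a health state
#'
#' Healthy time is weighted `1 - pyld` (the stratum's prevalent-YLD
#' background morbidity decrement); time in a disease state additionally
#' subtracts that disease's disability weight; death weighs 0.
#'
#' @param state one of the seven model states.
#' @param pyld background morbidity decrement for the stratum.
#' @param dw_chd,dw_stroke disability weights for the stratum.
#' @return utility in `[0, 1]`.
#' @examples
#' utility_weight("chd_later", pyld = 0.05, dw_chd = 0.081)  # 0.869
#' @export
utility_weight <- function(state, pyld, dw_chd = 0.081, dw_stroke = 0.226) {
  u <- switch(state,
              healthy = 1 - pyld,
              chd_year1 = ,
              chd_later = 1 - pyld - dw_chd,
              stroke_year1 = ,
              stroke_later = 1 - pyld - dw_stroke,
              dead_cvd = ,
              dead_other = 0,
              stop("unknown state '", state, "'"))
  if (any(u < 0)) stop("utility weight below 0: pyld + disability weight exceeds 1")
  u
}

#' Annual health-system cost of a state
#'
#' Base costs come from the sex-by-age-band cost table: the healthy annual
#' cost for the healthy state, the first-year disease cost for the
#' first-year CHD/stroke states and the subsequent-year cost otherwise; the
#' dead states cost nothing. The base is multiplied by the public-share
#' factor and the old-age multiplier for the person's attained age.
#'
#' @param state one of the seven model states.
#' @param sex `"male"` or `"female"`.
#' @param age attained age (drives the band lookup and old-age multiplier).
#' @param costs cost table of a `salt_inputs` object.
#' @param scaleups from [cost_scaleups()].
#' @return NZ$ per person-year.
#' @examples
#' inp <- generate_inputs(1)
#' state_cost("healthy", "female", 60, inp$costs)  # 2381 * 1.2
#' @export
state_cost <- function(state, sex, age, costs, scaleups = cost_scaleups()) {
  if (state %in% SALT_DEAD_STATES) return(0)
  band <- age_to_band_start(age, sort(unique(costs$age_start)))
  i <- which(costs$sex == sex & costs$age_start == band)
  if (length(i) != 1L) stop("no cost cell for ", sex, " at age ", age)
  base <- switch(state,
                 healthy = costs$healthy_annual_cost[i],
                 chd_year1 = costs$chd_first_year_cost[i],
                 chd_later = costs$chd_subsequent_cost[i],
                 stroke_year1 = costs$stroke_first_year_cost[i],
                 stroke_later = costs$stroke_subsequent_cost[i],
                 stop("unknown state '", state, "'"))
  base * scaleups$public_share_factor * .old_age_multiplier(age, scaleups)
}

#' Accrue QALYs and costs over a trajectory
#'
#' Quality-adjusted life-years and health-system costs are accrued for the
#' occupancy recorded at the end of each annual cycle (full-year accrual, no
#' half-cycle correction), weighted by stratum utility and state cost, and
#' discounted to the reference year. The scenario's one-off intervention
#' cost is added to the total cost ledger undiscounted in its cost year
#' (which is the baseline year for the built-in scenarios, so discounting is
#' moot at any rate).
#'
#' @param trajectory a `salt_trajectory` from [run_cohort()].
#' @param inputs the same `salt_inputs` the trajectory was run on.
#' @param discount a [discount_spec()].
#' @param detail keep the per-sub-cohort, per-year ledger (default TRUE;
#'   turn off inside Monte Carlo loops where only totals are needed).
#' @return an object of class `salt_ledger` with `totals` (discounted and
#'   undiscounted QALYs and costs), the per-row `detail` data.frame, the
#'   scenario and the inputs fingerprint.
#' @export
accrue <- function(trajectory, inputs, discount = discount_spec(),
                   detail = TRUE) {
  if (!identical(trajectory$fingerprint, inputs$fingerprint))
    stop("trajectory was not produced from these inputs (fingerprint mismatch)")
  subs <- trajectory$subcohorts
  years <- trajectory$years
  n <- nrow(subs); ny <- length(years)

  age_mat <- outer(subs$age0, seq_len(ny) - 1L, `+`)       # age during cycle
  band_starts <- sort(unique(inputs$strata$age_start))
  band_vec <- age_to_band_start(as.vector(age_mat), band_starts)
  sex_vec <- rep(subs$sex, times = ny)
  eth_vec <- rep(subs$ethnicity, times = ny)

  epi <- inputs$epi
  eidx <- match(paste(sex_vec, eth_vec, band_vec, sep = "/"),
                paste(epi$sex, epi$ethnicity, epi$age_start, sep = "/"))
  pyld <- epi$pyld[eidx]
  u_h <- 1 - pyld
  u_c <- 1 - pyld - epi$dw_chd[eidx]
  u_s <- 1 - pyld - epi$dw_stroke[eidx]

  co <- inputs$costs
  cost_bands <- sort(unique(co$age_start))
  cidx <- match(paste(sex_vec, age_to_band_start(as.vector(age_mat), cost_bands),
                      sep = "/"),
                paste(co$sex, co$age_start, sep = "/"))
  su <- cost_scaleups()
  cmult <- su$public_share_factor * .old_age_multiplier(as.vector(age_mat), su)

  H <- as.vector(trajectory$occupancy[, "healthy", ])
  C1 <- as.vector(trajectory$occupancy[, "chd_year1", ])
  CL <- as.vector(trajectory$occupancy[, "chd_later", ])
  S1 <- as.vector(trajectory$occupancy[, "stroke_year1", ])
  SL <- as.vector(trajectory$occupancy[, "stroke_later", ])

  w <- rep(subs$weight, times = ny)
  alive <- (H + C1 + CL + S1 + SL) * w
  qalys <- (H * u_h + (C1 + CL) * u_c + (S1 + SL) * u_s) * w
  costs <- (H * co$healthy_annual_cost[cidx] +
              C1 * co$chd_first_year_cost[cidx] +
              CL * co$chd_subsequent_cost[cidx] +
              S1 * co$stroke_first_year_cost[cidx] +
              SL * co$stroke_subsequent_cost[cidx]) * cmult * w

  dfac <- rep(discount_factor(years, discount), each = n)
  one_off <- trajectory$scenario$one_off_cost

  totals <- list(
    qalys = sum(qalys), costs = sum(costs) + one_off,
    qalys_disc = sum(qalys * dfac), costs_disc = sum(costs * dfac) + one_off
  )
  detail_df <- NULL
  if (detail) {
    detail_df <- data.frame(
      sex = sex_vec, ethnicity = eth_vec,
      age_band_2011 = rep(subs$age_band_2011, times = ny),
      age0 = rep(subs$age0, times = ny),
      year = rep(years, each = n),
      age = as.vector(age_mat),
      alive = alive, qalys = qalys, costs = costs,
      qalys_disc = qalys * dfac, costs_disc = costs * dfac,
      stringsAsFactors = FALSE
    )
  }
  structure(list(totals = totals, detail = detail_df,
                 scenario = trajectory$scenario, discount = discount,
                 one_off_cost = one_off,
                 fingerprint = trajectory$fingerprint),
            class = "salt_ledger")
}

#' @export
print.salt_ledger <- function(x, ...) {
  cat(sprintf("Ledger for scenario '%s' (discount %.0f%%)\n",
              x$scenario$name, 100 * x$discount$rate))
  cat(sprintf("  QALYs: %s discounted (%s undiscounted)\n",
              format(round(x$totals$qalys_disc), big.mark = ","),
              format(round(x$totals$qalys), big.mark = ",")))
  cat(sprintf("  costs: NZ$%s discounted (incl. one-off NZ$%s)\n",
              format(round(x$totals$costs_disc), big.mark = ","),
              format(round(x$one_off_cost), big.mark = ",")))
  invisible(x)
}

#' Classify an incremental result
#'
#' `dominant` means more QALYs at lower cost; `dominated` means no more
#' QALYs at no lower cost (and not identical); an ICER (NZ$ per QALY) is
#' reported only when both the QALY gain and the cost are positive.
#'
#' @param delta_qalys,delta_costs incremental totals vs the comparator.
#' @return list with `classification` and `icer` (NA unless applicable).
#' @export
classify_incremental <- function(delta_qalys, delta_costs) {
  if (delta_qalys > 0 && delta_costs < 0)
    list(classification = "dominant", icer = NA_real_)
  else if (delta_qalys > 0 && delta_costs > 0)
    list(classification = "icer", icer = delta_costs / delta_qalys)
  else if (delta_qalys <= 0 && delta_costs >= 0 &&
           !(delta_qalys == 0 && delta_costs == 0))
    list(classification = "dominated", icer = NA_real_)
  else
    list(classification = "equivalent", icer = NA_real_)
}

#' Incremental result versus a comparator ledger
#'
#' @param scenario_ledger,comparator_ledger `salt_ledger`s accrued from the
#'   same inputs at the same discount rate (enforced by fingerprint).
#' @return an object of class `salt_incremental`: discounted and
#'   undiscounted QALY and cost deltas, the classification, and (when both
#'   ledgers carry detail) a per-row delta data.frame for decompositions.
#' @export
incremental <- function(scenario_ledger, comparator_ledger) {
  if (!identical(scenario_ledger$fingerprint, comparator_ledger$fingerprint))
    stop("ledgers come from different inputs (fingerprint mismatch)")
  if (!identical(scenario_ledger$discount, comparator_ledger$discount))
    stop("ledgers use different discount specifications")
  dq <- scenario_ledger$totals$qalys_disc - comparator_ledger$totals$qalys_disc
  dc <- scenario_ledger$totals$costs_disc - comparator_ledger$totals$costs_disc
  cls <- classify_incremental(dq, dc)
  delta_detail <- NULL
  if (!is.null(scenario_ledger$detail) && !is.null(comparator_ledger$detail)) {
    a <- scenario_ledger$detail; b <- comparator_ledger$detail
    stopifnot(nrow(a) == nrow(b))
    delta_detail <- a[c("sex", "ethnicity", "age_band_2011", "age0", "year", "age")]
    for (f in c("qalys", "costs", "qalys_disc", "costs_disc"))
      delta_detail[[f]] <- a[[f]] - b[[f]]
  }
  structure(list(
    scenario = scenario_ledger$scenario$name,
    delta_qalys = dq, delta_costs = dc,
    delta_qalys_undisc = scenario_ledger$totals$qalys - comparator_ledger$totals$qalys,
    delta_costs_undisc = scenario_ledger$totals$costs - comparator_ledger$totals$costs,
    classification = cls$classification, icer = cls$icer,
    one_off_cost = scenario_ledger$one_off_cost,
    discount = scenario_ledger$discount,
    delta_detail = delta_detail,
    fingerprint = scenario_ledger$fingerprint
  ), class = "salt_incremental")
}

#' @export
print.salt_incremental <- function(x, ...) {
  cat(sprintf("Incremental result, '%s' vs do-nothing\n", x$scenario))
  cat(sprintf("  delta QALYs (discounted): %s\n",
              format(round(x$delta_qalys), big.mark = ",")))
  cat(sprintf("  delta costs (discounted): NZ$%s\n",
              format(round(x$delta_costs), big.mark = ",")))
  lbl <- switch(x$classification,
                dominant = "dominant (more QALYs, cost-saving)",
                icer = sprintf("ICER NZ$%s per QALY", format(round(x$icer), big.mark = ",")),
                x$classification)
  cat("  classification:", lbl, "\n")
  invisible(x)
}

#' Per-adult incremental results for a population group
#'
#' Divides a group's incremental QALYs and costs by its 2011 population.
#' Group cost deltas include a population-proportional share of the
#' intervention's one-off cost (the total ledger carries it unapportioned).
#'
#' @param result a `salt_incremental` carrying detail.
#' @param population the population table of the inputs the result came from.
#' @param group one of `"all"`, `"maori"`, `"non_maori"`, `"male"`,
#'   `"female"`, `"under65"`, `"65plus"` (age at 2011), or a predicate
#'   `function(detail_rows) -> logical`.
#' @return list with `group`, `population`, `qalys_per_adult`,
#'   `cost_per_adult`.
#' @export
per_capita <- function(result, population, group = "all") {
  d <- result$delta_detail
  if (is.null(d)) stop("result carries no detail ledger; accrue with detail = TRUE")
  sel_fun <- if (is.function(group)) group else switch(
    group,
    all = function(d) rep(TRUE, nrow(d)),
    maori = function(d) d$ethnicity == "maori",
    non_maori = function(d) d$ethnicity == "non_maori",
    male = function(d) d$sex == "male",
    female = function(d) d$sex == "female",
    under65 = function(d) d$age0 < 65,
    `65plus` = function(d) d$age0 >= 65,
    stop("unknown group '", group, "'")
  )
  rows <- sel_fun(d)
  if (!any(rows)) stop("group filter selects no strata")
  # matching population: evaluate the same predicate on per-person rows
  pop_rows <- data.frame(sex = rep(population$sex, 1L),
                         ethnicity = population$ethnicity,
                         age0 = population$age_start,
                         age_band_2011 = population$age_band)
  psel <- sel_fun(pop_rows)
  group_pop <- sum(population$count[psel])
  total_pop <- sum(population$count)
  if (group_pop <= 0) stop("group has no population")
  dq <- sum(d$qalys_disc[rows])
  dc <- sum(d$costs_disc[rows]) + result$one_off_cost * group_pop / total_pop
  list(group = if (is.function(group)) "custom" else group,
       population = group_pop,
       qalys_per_adult = dq / group_pop,
       cost_per_adult = dc / group_pop)
}
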