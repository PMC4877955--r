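#' Probabilistic sensitivity analysis settings
#'
#' Parameter uncertainty follows the published distribution statements:
#' normal with SD equal to 10\% of the point estimate for the intervention
#' sodium reduction and for the age-specific hazard ratios (redrawn when a
#' draw leaves its support rather than clamped), gamma with SD equal to 10\%
#' of the mean for costs, and beta distributions moment-matched to the
#' printed 95\% CIs for the disability weights (CHD 0.05-0.11, stroke
#' 0.11-0.23).
#'
#' @param n_iterations Monte Carlo iterations (default 2000).
#' @param seed integer master seed; every draw is a deterministic function
#'   of `(seed, parameter, iteration)` via a counter-based substream, so
#'   adding a parameter does not perturb the other parameters' draws.
#' @param sd_frac_reduction,sd_frac_hr,sd_frac_cost SD as a fraction of the
#'   point estimate for the three 10\%-SD parameter families; set to 0 to
#'   freeze a family at its point estimate.
#' @param vary_dw sample disability weights (set FALSE to freeze).
#' @return an `uncertainty_spec` list.
#' @export
uncertainty_spec <- function(n_iterations = 2000L, seed = 1L,
                             sd_frac_reduction = 0.10, sd_frac_hr = 0.10,
                             sd_frac_cost = 0.10, vary_dw = TRUE) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (any(c(sd_frac_reduction, sd_frac_hr, sd_frac_cost) < 0))
    stop("SD fractions must be non-negative")
  structure(list(n_iterations = as.integer(n_iterations), seed = as.integer(seed),
                 sd_frac_reduction = sd_frac_reduction, sd_frac_hr = sd_frac_hr,
                 sd_frac_cost = sd_frac_cost, vary_dw = vary_dw),
            class = "uncertainty_spec")
}

# counter-based substream: a deterministic 31-bit seed from the master seed,
# a parameter label and the iteration counter (LCG-style string hash; all
# intermediates stay below 2^53 so the arithmetic is exact)
.substream_seed <- function(seed, param, iteration) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(paste0(param, "#", iteration)))
    h <- (h * 69069 + b + 1) %% 2147483647
  as.integer(h %% 2147483629) + 1L
}

.draw_sub <- function(seed, param, iteration, expr_fun) {
  with_local_seed(.substream_seed(seed, param, iteration), expr_fun())
}

# normal draw with resampling until inside (lo, hi)
.rnorm_trunc <- function(mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(mean)
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x > lo && x < hi) return(x)
  }
}

# beta moment-matched to a mean and SD
.rbeta_ms <- function(n, mean, sd) {
  v <- sd^2
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

#' Draw one iteration's parameter overlay
#'
#' Produces the sampled parameter set for iteration `iteration`: a perturbed
#' reduction fraction per scenario, a perturbed per-band hazard-ratio table,
#' gamma multipliers for the five cost components, and disability-weight
#' draws. Deterministic given `(spec$seed, iteration)`.
#'
#' @param spec an [uncertainty_spec()].
#' @param base_inputs the point-estimate `salt_inputs`.
#' @param scenarios named list of `salt_scenario`s being evaluated.
#' @param iteration iteration counter (1-based).
#' @return list with `reduction_fraction` (named per scenario), `hr_table`,
#'   `cost_multipliers`, `dw_chd`, `dw_stroke`.
#' @export
draw_parameters <- function(spec, base_inputs, scenarios, iteration) {
  seed <- spec$seed
  red <- vapply(scenarios, function(sc) {
    if (sc$reduction_fraction == 0) return(0)
    .draw_sub(seed, paste0("reduction/", sc$name), iteration, function()
      .rnorm_trunc(sc$reduction_fraction, spec$sd_frac_reduction * sc$reduction_fraction,
                   lo = 0, hi = 1))
  }, numeric(1L))

  hrt <- hazard_ratio_table(base_inputs$hazard_ratios)
  for (d in c("hr_chd", "hr_stroke")) {
    hrt[[d]] <- vapply(seq_len(nrow(hrt)), function(k)
      .draw_sub(seed, paste0(d, "/", hrt$age_start[k]), iteration, function()
        .rnorm_trunc(hrt[[d]][k], spec$sd_frac_hr * hrt[[d]][k], lo = 0, hi = 1)),
      numeric(1L))
  }

  comp <- c("healthy_annual_cost", "chd_first_year_cost", "chd_subsequent_cost",
            "stroke_first_year_cost", "stroke_subsequent_cost")
  cost_mult <- vapply(comp, function(cc) {
    if (spec$sd_frac_cost == 0) return(1)
    .draw_sub(seed, paste0("cost/", cc), iteration, function() {
      shape <- 1 / spec$sd_frac_cost^2           # mean 1, SD = sd_frac_cost
      stats::rgamma(1L, shape = shape, rate = shape)
    })
  }, numeric(1L))

  mo <- base_inputs$morbidity
  # the printed DW intervals are examples for one stratum whose central value
  # can differ from the all-population average; rescale the bounds to the
  # central estimate so the relative uncertainty is preserved, then draw a
  # moment-matched beta and resample outside the (rescaled) bounds
  dw_draw <- function(label, central, lo, hi) {
    if (!spec$vary_dw) return(central)
    mid <- (lo + hi) / 2
    scale <- central / mid
    sd <- central * (hi - lo) / (2 * stats::qnorm(0.975) * mid)
    .draw_sub(seed, label, iteration, function() {
      repeat {
        x <- .rbeta_ms(1L, central, sd)
        if (x > lo * scale && x < hi * scale) return(x)
      }
    })
  }
  list(reduction_fraction = red,
       hr_table = hrt,
       cost_multipliers = cost_mult,
       dw_chd = dw_draw("dw/chd", mo$dw_chd, mo$dw_chd_lo, mo$dw_chd_hi),
       dw_stroke = dw_draw("dw/stroke", mo$dw_stroke, mo$dw_stroke_lo, mo$dw_stroke_hi))
}

# apply an overlay to inputs/scenarios, returning modified copies
.apply_overlay <- function(inputs, scenarios, overlay) {
  inputs$hazard_ratios$table <- overlay$hr_table
  for (cc in names(overlay$cost_multipliers))
    inputs$costs[[cc]] <- inputs$costs[[cc]] * overlay$cost_multipliers[[cc]]
  inputs$epi$dw_chd <- overlay$dw_chd * inputs$epi$dw_chd / inputs$morbidity$dw_chd
  inputs$epi$dw_stroke <- overlay$dw_stroke * inputs$epi$dw_stroke / inputs$morbidity$dw_stroke
  scenarios <- lapply(scenarios, function(sc) {
    sc$reduction_fraction <- unname(overlay$reduction_fraction[sc$name])
    sc
  })
  list(inputs = inputs, scenarios = scenarios)
}

# empirical percentile with type-7 interpolation (checked in tests against
# an independent sort-based computation)
.percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(rep(x, length(p)))
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

#' Run the probabilistic sensitivity analysis
#'
#' For each Monte Carlo iteration the sampled parameter overlay is applied
#' to the inputs, the do-nothing comparator and every requested scenario are
#' re-run, and incremental discounted QALYs and costs are recorded. The
#' central estimate is the all-point-estimates run; the 95\% uncertainty
#' interval is the 2.5th-97.5th empirical percentile range of the draws.
#'
#' @param inputs point-estimate `salt_inputs`.
#' @param scenarios named list of `salt_scenario`s (do-nothing is always run
#'   as comparator and need not be listed).
#' @param spec an [uncertainty_spec()].
#' @param discount a [discount_spec()].
#' @return object of class `salt_psa`: `draws` (iteration x scenario deltas),
#'   `summary` (central estimates and intervals) and the settings used.
#' @export
run_psa <- function(inputs, scenarios = builtin_scenarios()[1:4],
                    spec = uncertainty_spec(), discount = discount_spec()) {
  if (spec$n_iterations < 40)
    warning("fewer than 40 iterations: 2.5/97.5 percentile estimates are unstable")
  scenarios <- scenarios[vapply(scenarios, function(s) s$name != "do_nothing",
                                logical(1L))]
  names(scenarios) <- vapply(scenarios, `[[`, character(1L), "name")
  comparator <- builtin_scenarios("do_nothing")

  run_once <- function(inp, scen_list) {
    comp_led <- accrue(run_cohort(inp, comparator), inp, discount, detail = FALSE)
    lapply(scen_list, function(sc) {
      led <- accrue(run_cohort(inp, sc), inp, discount, detail = FALSE)
      c(delta_qalys = led$totals$qalys_disc - comp_led$totals$qalys_disc,
        delta_costs = led$totals$costs_disc - comp_led$totals$costs_disc)
    })
  }

  central <- run_once(inputs, scenarios)

  draws <- vector("list", spec$n_iterations)
  for (it in seq_len(spec$n_iterations)) {
    ov <- draw_parameters(spec, inputs, scenarios, it)
    mod <- .apply_overlay(inputs, scenarios, ov)
    res <- run_once(mod$inputs, mod$scenarios)
    draws[[it]] <- data.frame(
      iteration = it,
      scenario = vapply(scenarios, `[[`, character(1L), "name"),
      delta_qalys = vapply(res, `[[`, numeric(1L), "delta_qalys"),
      delta_costs = vapply(res, `[[`, numeric(1L), "delta_costs"),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  draws <- do.call(rbind, draws)

  summ <- do.call(rbind, lapply(names(scenarios), function(nm) {
    d <- draws[draws$scenario == scenarios[[nm]]$name, ]
    data.frame(
      scenario = scenarios[[nm]]$name,
      delta_qalys = central[[nm]][["delta_qalys"]],
      delta_qalys_lo = .percentile(d$delta_qalys, 0.025),
      delta_qalys_hi = .percentile(d$delta_qalys, 0.975),
      delta_costs = central[[nm]][["delta_costs"]],
      delta_costs_lo = .percentile(d$delta_costs, 0.025),
      delta_costs_hi = .percentile(d$delta_costs, 0.975),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summ) <- NULL
  structure(list(draws = draws, summary = summ, spec = spec,
                 discount = discount, fingerprint = inputs$fingerprint),
            class = "salt_psa")
}

#' @export
print.salt_psa <- function(x, ...) {
  cat(sprintf("PSA: %d Monte Carlo iterations (seed %d)\n",
              x$spec$n_iterations, x$spec$seed))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s dQALY %s (%s to %s); dCost NZ$%sm (%s to %s)\n",
                s$scenario[i],
                format(signif(s$delta_qalys[i], 3L), big.mark = ","),
                format(signif(s$delta_qalys_lo[i], 3L), big.mark = ","),
                format(signif(s$delta_qalys_hi[i], 3L), big.mark = ","),
                format(signif(s$delta_costs[i] / 1e6, 3L), big.mark = ","),
                format(signif(s$delta_costs_lo[i] / 1e6, 3L), big.mark = ","),
                format(signif(s$delta_costs_hi[i] / 1e6, 3L), big.mark = ",")))
  invisible(x)
}
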