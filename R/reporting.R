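SALT_ACCRUAL_BAND_STARTS <- c(35, 45, 55, 65, 70, 75, 85, 95)
SALT_ACCRUAL_BAND_LABELS <- c("35-44", "45-54", "55-64", "65-69",
                              "70-74", "75-84", "85-94", "95+")

#' Decompose incremental QALYs by age at accrual and calendar window
#'
#' Bins the discounted QALY deltas of an incremental result by the age at
#' which they accrue (mixed-width bands 35-44 ... 85-94, 95+; note this is
#' attained age, not age at baseline) and by calendar window (decades by
#' default). Within each window, each band's share of the QALYs accruing to
#' people aged 45+ and 55+ is reported, the convention used for
#' working-age-impact summaries.
#'
#' @param result a `salt_incremental` carrying detail.
#' @param window_starts first calendar years of the windows (default decades
#'   from 2011 spanning the whole simulation).
#' @param window_width window length in years (default 10).
#' @return data.frame with `window`, `age_band`, `qalys`, `share_45plus`,
#'   `share_55plus` (shares in percent; NA for bands below the denominator
#'   cut).
#' @export
decompose_age_time <- function(result, window_starts = NULL, window_width = 10L) {
  d <- result$delta_detail
  if (is.null(d)) stop("result carries no detail ledger; accrue with detail = TRUE")
  if (is.null(window_starts))
    window_starts <- seq.int(min(d$year), max(d$year), by = window_width)
  if (any(diff(window_starts) < window_width))
    stop("calendar windows overlap: starts must be at least window_width apart")

  widx <- findInterval(d$year, window_starts)
  keep <- widx >= 1L & d$year <= window_starts[widx] + window_width - 1L
  dd <- d[keep, ]
  widx <- widx[keep]
  win_label <- sprintf("%d-%d", window_starts, window_starts + window_width - 1L)

  bidx <- findInterval(dd$age, SALT_ACCRUAL_BAND_STARTS)
  cells <- expand.grid(age_band = SALT_ACCRUAL_BAND_LABELS,
                       window = win_label,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(win_label[widx], SALT_ACCRUAL_BAND_LABELS[bidx], sep = "|")
  agg <- tapply(dd$qalys_disc, key, sum)
  cells$qalys <- as.numeric(agg[paste(cells$window, cells$age_band, sep = "|")])
  cells$qalys[is.na(cells$qalys)] <- 0

  age_start <- SALT_ACCRUAL_BAND_STARTS[match(cells$age_band, SALT_ACCRUAL_BAND_LABELS)]
  for (cut in c(45, 55)) {
    denom <- tapply(cells$qalys[age_start >= cut], cells$window[age_start >= cut], sum)
    share <- 100 * cells$qalys / as.numeric(denom[cells$window])
    share[age_start < cut] <- NA_real_
    cells[[paste0("share_", cut, "plus")]] <- share
  }
  cells[c("window", "age_band", "qalys", "share_45plus", "share_55plus")]
}

#' Share of a window's QALY gain accruing below an age cut
#'
#' @param result a `salt_incremental` carrying detail.
#' @param window_start,window_width calendar window (default the first
#'   decade, 2011-2020).
#' @param age_cut accrual-age cut; must fall on an accrual-band boundary
#'   (45, 55, 65, 70, 75, 85 or 95).
#' @return percentage of the window's total incremental discounted QALYs
#'   (all ages) accruing at ages strictly below the cut.
#' @export
early_window_shares <- function(result, window_start = 2011L,
                                window_width = 10L, age_cut = 65) {
  if (!age_cut %in% SALT_ACCRUAL_BAND_STARTS[-1L])
    stop("age_cut must fall on an accrual band boundary: ",
         paste(SALT_ACCRUAL_BAND_STARTS[-1L], collapse = ", "))
  d <- result$delta_detail
  if (is.null(d)) stop("result carries no detail ledger; accrue with detail = TRUE")
  inw <- d$year >= window_start & d$year <= window_start + window_width - 1L
  total <- sum(d$qalys_disc[inw])
  if (total == 0) stop("no QALY delta in the requested window")
  100 * sum(d$qalys_disc[inw & d$age < age_cut]) / total
}

#' Scenario league table
#'
#' Ranks incremental results by discounted QALY gain (descending; ties
#' broken by scenario name) and attaches the cost-effectiveness
#' classification and, when available, PSA uncertainty intervals.
#'
#' @param results list of `salt_incremental` objects run on identical inputs.
#' @param psa optional `salt_psa` whose summary rows are joined by scenario.
#' @return data.frame with one row per scenario.
#' @export
league_table <- function(results, psa = NULL) {
  if (length(results) == 0L)
    return(data.frame(scenario = character(0), delta_qalys = numeric(0),
                      delta_costs = numeric(0), classification = character(0),
                      icer = numeric(0), stringsAsFactors = FALSE))
  fps <- vapply(results, `[[`, character(1L), "fingerprint")
  if (length(unique(fps)) != 1L)
    stop("results come from different inputs (fingerprint mismatch)")
  tab <- data.frame(
    scenario = vapply(results, `[[`, character(1L), "scenario"),
    delta_qalys = vapply(results, `[[`, numeric(1L), "delta_qalys"),
    delta_costs = vapply(results, `[[`, numeric(1L), "delta_costs"),
    classification = vapply(results, `[[`, character(1L), "classification"),
    icer = vapply(results, `[[`, numeric(1L), "icer"),
    stringsAsFactors = FALSE
  )
  if (!is.null(psa)) {
    s <- psa$summary
    j <- match(tab$scenario, s$scenario)
    tab$delta_qalys_lo <- s$delta_qalys_lo[j]
    tab$delta_qalys_hi <- s$delta_qalys_hi[j]
    tab$delta_costs_lo <- s$delta_costs_lo[j]
    tab$delta_costs_hi <- s$delta_costs_hi[j]
  }
  tab <- tab[order(-tab$delta_qalys, tab$scenario), ]
  rownames(tab) <- NULL
  tab
}

#' Render a league table with report-style number formatting
#'
#' Thousands separators and 3 significant digits, as in published league
#' tables; the underlying data.frame keeps full precision.
#'
#' @param tab data.frame from [league_table()].
#' @return character matrix of formatted cells.
#' @export
format_league_table <- function(tab) {
  fmt <- function(x) ifelse(is.na(x), "-",
                            format(signif(x, 3L), big.mark = ",",
                                   scientific = FALSE, trim = TRUE))
  out <- cbind(scenario = tab$scenario,
               `QALYs gained` = fmt(tab$delta_qalys),
               `net cost (NZ$)` = fmt(tab$delta_costs),
               ICER = ifelse(tab$classification == "dominant", "Dominant",
                             ifelse(is.na(tab$icer), tab$classification,
                                    paste0("NZ$", fmt(tab$icer), " per QALY"))))
  out
}

#' Per-adult results by sociodemographic group
#'
#' Convenience wrapper around [per_capita()] for the standard reporting
#' axes: age at baseline (<65 / 65+), sex and ethnicity.
#'
#' @param result a `salt_incremental` carrying detail.
#' @param population the inputs' population table.
#' @return data.frame with one row per group.
#' @export
group_results <- function(result, population) {
  groups <- c("under65", "65plus", "female", "male", "maori", "non_maori")
  do.call(rbind, lapply(groups, function(g) {
    pc <- per_capita(result, population, g)
    data.frame(group = g, population = pc$population,
               cost_per_adult = pc$cost_per_adult,
               qalys_per_adult = pc$qalys_per_adult,
               stringsAsFactors = FALSE)
  }))
}

#' Bar chart of the age distribution of the health gain
#'
#' @param cells data.frame from [decompose_age_time()].
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the matrix plotted.
#' @export
plot_age_distribution <- function(cells, ...) {
  m <- tapply(cells$qalys, list(cells$window, cells$age_band), sum)
  m <- m[, SALT_ACCRUAL_BAND_LABELS, drop = FALSE]
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    xlab = "age when QALYs are gained",
                    ylab = "discounted QALYs gained", ...)
  invisible(m)
}
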