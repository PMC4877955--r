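#' Read and write model inputs
#'
#' Inputs are stored as two plain-text files in a directory: `inputs.csv`, a
#' long-format table (`sex, ethnicity, age_band, quantity, disease, value`)
#' holding every per-stratum quantity, and `inputs.json` holding the scalar
#' blocks (trend spec, sodium baseline, morbidity settings, blood-pressure
#' response, hazard-ratio settings, generator seed). Values are written with
#' 17 significant digits so the round trip is lossless. Cost rows, which vary
#' by sex and age band only, carry `ethnicity = "all"`.
#'
#' @param inputs a `salt_inputs` object.
#' @param path directory to write to (created if absent).
#' @return `write_inputs` returns `path` invisibly; `read_inputs` returns a
#'   `salt_inputs` object equal field-for-field to the one written.
#' @name inputs_io
NULL

.num_chr <- function(x) sprintf("%.17g", x)

.inputs_long_df <- function(inputs) {
  epi <- inputs$epi
  pop <- inputs$population
  costs <- inputs$costs
  row_block <- function(sex, eth, band, quantity, disease, value)
    data.frame(sex = sex, ethnicity = eth, age_band = band,
               quantity = quantity, disease = disease,
               value = value, stringsAsFactors = FALSE)
  blocks <- list(
    row_block(pop$sex, pop$ethnicity, pop$age_band, "population", "", pop$count),
    row_block(epi$sex, epi$ethnicity, epi$age_band, "incidence", "chd", epi$inc_chd),
    row_block(epi$sex, epi$ethnicity, epi$age_band, "incidence", "stroke", epi$inc_stroke),
    row_block(epi$sex, epi$ethnicity, epi$age_band, "case_fatality", "chd", epi$cf_chd),
    row_block(epi$sex, epi$ethnicity, epi$age_band, "case_fatality", "stroke", epi$cf_stroke),
    row_block(epi$sex, epi$ethnicity, epi$age_band, "prevalence", "chd", epi$prev_chd),
    row_block(epi$sex, epi$ethnicity, epi$age_band, "prevalence", "stroke", epi$prev_stroke),
    row_block(epi$sex, epi$ethnicity, epi$age_band, "background_mortality", "", epi$bg_mort),
    row_block(epi$sex, epi$ethnicity, epi$age_band, "pyld", "", epi$pyld),
    row_block(epi$sex, epi$ethnicity, epi$age_band, "disability_weight", "chd", epi$dw_chd),
    row_block(epi$sex, epi$ethnicity, epi$age_band, "disability_weight", "stroke", epi$dw_stroke),
    row_block(costs$sex, "all", costs$age_band, "healthy_annual_cost", "", costs$healthy_annual_cost),
    row_block(costs$sex, "all", costs$age_band, "first_year_cost", "chd", costs$chd_first_year_cost),
    row_block(costs$sex, "all", costs$age_band, "subsequent_year_cost", "chd", costs$chd_subsequent_cost),
    row_block(costs$sex, "all", costs$age_band, "first_year_cost", "stroke", costs$stroke_first_year_cost),
    row_block(costs$sex, "all", costs$age_band, "subsequent_year_cost", "stroke", costs$stroke_subsequent_cost)
  )
  do.call(rbind, blocks)
}

.inputs_json_list <- function(inputs) {
  list(format = "saltsim-inputs", format_version = 1L,
       generator_seed = inputs$generator_seed,
       trend = inputs$trend, sodium = inputs$sodium,
       morbidity = inputs$morbidity, bp_response = inputs$bp_response,
       hazard_ratios = inputs$hazard_ratios)
}

#' @rdname inputs_io
#' @export
write_inputs <- function(inputs, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  long <- .inputs_long_df(inputs)
  long$value <- .num_chr(long$value)
  utils::write.csv(long, file.path(path, "inputs.csv"), row.names = FALSE,
                   quote = FALSE)
  writeLines(jsonlite::toJSON(.inputs_json_list(inputs), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE),
             file.path(path, "inputs.json"))
  invisible(path)
}

#' Stable content fingerprint of a model-input set
#'
#' MD5 digest of the canonical on-disk serialization; used to refuse
#' incremental comparisons between ledgers produced from different inputs.
#'
#' @param inputs a `salt_inputs` object.
#' @return character MD5 string.
#' @export
input_fingerprint <- function(inputs) {
  long <- .inputs_long_df(inputs)
  txt <- c(apply(long, 1L, paste, collapse = ","),
           jsonlite::toJSON(.inputs_json_list(inputs), auto_unbox = TRUE, digits = NA))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' @rdname inputs_io
#' @export
read_inputs <- function(path) {
  csv_path <- file.path(path, "inputs.csv")
  json_path <- file.path(path, "inputs.json")
  for (p in c(csv_path, json_path))
    if (!file.exists(p)) stop("input file not found: ", p)

  long <- tryCatch(
    utils::read.csv(csv_path, stringsAsFactors = FALSE,
                    colClasses = c(value = "character")),
    error = function(e) stop("failed to parse ", csv_path, ": ",
                             conditionMessage(e), call. = FALSE))
  required <- c("sex", "ethnicity", "age_band", "quantity", "disease", "value")
  miss <- setdiff(required, names(long))
  if (length(miss))
    stop("malformed inputs.csv: missing column(s) ", paste(miss, collapse = ", "))
  unknown <- setdiff(names(long), required)
  if (length(unknown))
    warning("inputs.csv: ignoring unknown column(s) ",
            paste(unknown, collapse = ", "))
  long$value <- suppressWarnings(as.numeric(long$value))
  if (anyNA(long$value)) {
    bad <- which(is.na(long$value))[1L]
    stop(sprintf("malformed inputs.csv: non-numeric value at data row %d (%s/%s/%s %s)",
                 bad, long$sex[bad], long$ethnicity[bad], long$age_band[bad],
                 long$quantity[bad]))
  }
  long$disease[is.na(long$disease)] <- ""

  scal <- tryCatch(jsonlite::fromJSON(json_path, simplifyVector = TRUE),
                   error = function(e) stop("failed to parse ", json_path, ": ",
                                            conditionMessage(e), call. = FALSE))

  strata <- enumerate_strata()
  pick <- function(quantity, disease = "") {
    sel <- long[long$quantity == quantity & long$disease == disease, ]
    key <- paste(sel$sex, sel$ethnicity, sel$age_band, sep = "/")
    idx <- match(stratum_key(strata), key)
    if (anyNA(idx)) {
      missing_key <- stratum_key(strata)[which(is.na(idx))[1L]]
      stop(sprintf("inputs.csv: missing stratum %s for quantity '%s%s'",
                   missing_key, quantity,
                   if (nzchar(disease)) paste0(" (", disease, ")") else ""))
    }
    sel$value[idx]
  }
  epi <- cbind(strata, data.frame(
    inc_chd = pick("incidence", "chd"),
    inc_stroke = pick("incidence", "stroke"),
    cf_chd = pick("case_fatality", "chd"),
    cf_stroke = pick("case_fatality", "stroke"),
    prev_chd = pick("prevalence", "chd"),
    prev_stroke = pick("prevalence", "stroke"),
    bg_mort = pick("background_mortality"),
    pyld = pick("pyld"),
    dw_chd = pick("disability_weight", "chd"),
    dw_stroke = pick("disability_weight", "stroke")
  ))
  population <- cbind(strata[c("sex", "ethnicity", "age_band", "age_start")],
                      count = pick("population"))

  cs <- unique(strata[c("sex", "age_band", "age_start")])
  pick_cost <- function(quantity, disease = "") {
    sel <- long[long$quantity == quantity & long$disease == disease &
                  long$ethnicity == "all", ]
    key <- paste(sel$sex, sel$age_band, sep = "/")
    idx <- match(paste(cs$sex, cs$age_band, sep = "/"), key)
    if (anyNA(idx)) {
      missing_key <- paste(cs$sex, cs$age_band, sep = "/")[which(is.na(idx))[1L]]
      stop(sprintf("inputs.csv: missing cost cell %s for quantity '%s%s'",
                   missing_key, quantity,
                   if (nzchar(disease)) paste0(" (", disease, ")") else ""))
    }
    sel$value[idx]
  }
  costs <- data.frame(
    sex = cs$sex, age_band = cs$age_band, age_start = cs$age_start,
    healthy_annual_cost = pick_cost("healthy_annual_cost"),
    chd_first_year_cost = pick_cost("first_year_cost", "chd"),
    chd_subsequent_cost = pick_cost("subsequent_year_cost", "chd"),
    stroke_first_year_cost = pick_cost("first_year_cost", "stroke"),
    stroke_subsequent_cost = pick_cost("subsequent_year_cost", "stroke"),
    stringsAsFactors = FALSE
  )
  rownames(population) <- rownames(costs) <- NULL

  inputs <- structure(list(
    strata = strata, population = population, epi = epi, costs = costs,
    trend = scal$trend, sodium = scal$sodium, morbidity = scal$morbidity,
    bp_response = scal$bp_response, hazard_ratios = scal$hazard_ratios,
    generator_seed = as.integer(scal$generator_seed)
  ), class = "salt_inputs")
  inputs$fingerprint <- input_fingerprint(inputs)
  inputs
}
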