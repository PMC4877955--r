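test_that("stratum enumeration covers the full sex x ethnicity x age grid", {
  st <- enumerate_strata()
  expect_equal(nrow(st), 52L)
  expect_equal(nrow(unique(st)), 52L)
  expect_setequal(unique(st$age_start), seq(35, 95, by = 5))
  # bands are disjoint and ordered: mapping any single age is unambiguous
  expect_equal(age_to_band_start(35:99),
               rep(seq(35, 95, by = 5), each = 5))
})

test_that("generated inputs reproduce the cost and sodium anchors exactly", {
  inp <- default_inputs()
  anchor <- subset(inp$costs, sex == "female" & age_band == "60-64")
  expect_identical(anchor$healthy_annual_cost, 2381)
  expect_identical(anchor$chd_first_year_cost, 16258)
  expect_identical(anchor$chd_subsequent_cost, 5395)
  expect_identical(anchor$stroke_first_year_cost, 20553)
  expect_identical(anchor$stroke_subsequent_cost, 5991)
  expect_identical(inp$sodium$intake_male, 4013)
  expect_identical(inp$sodium$intake_female, 3115)
  expect_identical(inp$morbidity$dw_chd, 0.081)
  expect_identical(inp$morbidity$dw_stroke, 0.226)
})

test_that("generated cohort size is within 1% of 2.3 million", {
  total <- sum(default_inputs()$population$count)
  expect_lt(abs(total - 2300000) / 2300000, 0.01)
})

test_that("the generator is a pure function of (seed, config)", {
  a <- generate_inputs(seed = 7L)
  b <- generate_inputs(seed = 7L)
  expect_equal(a, b, tolerance = 0)
})

test_that("different seeds perturb only the rate surfaces, never the anchors", {
  a <- generate_inputs(seed = 1L)
  b <- generate_inputs(seed = 2L)
  rate_cols <- c("inc_chd", "inc_stroke", "cf_chd", "cf_stroke", "bg_mort")
  expect_false(isTRUE(all.equal(a$epi[rate_cols], b$epi[rate_cols])))
  expect_identical(a$costs, b$costs)
  expect_identical(a$population, b$population)
  expect_identical(a$sodium, b$sodium)
  expect_identical(a$morbidity, b$morbidity)
  expect_identical(a$epi$dw_chd, b$epi$dw_chd)
})

test_that("generated inputs satisfy every structural invariant", {
  for (seed in c(1L, 2L, 17L)) {
    expect_identical(validate_inputs(generate_inputs(seed)), character(0))
  }
})

test_that("incidence rises with age and is higher for Maori at every age", {
  epi <- default_inputs()$epi
  for (s in c("male", "female")) for (e in c("maori", "non_maori")) {
    sub <- epi[epi$sex == s & epi$ethnicity == e, ]
    sub <- sub[order(sub$age_start), ]
    expect_true(all(diff(sub$inc_chd) >= 0))
    expect_true(all(diff(sub$inc_stroke) >= 0))
    expect_true(all(diff(sub$bg_mort) >= 0))
  }
  for (s in c("male", "female")) {
    m <- epi[epi$sex == s & epi$ethnicity == "maori", ]
    nm <- epi[epi$sex == s & epi$ethnicity == "non_maori", ]
    m <- m[order(m$age_start), ]; nm <- nm[order(nm$age_start), ]
    expect_true(all(m$inc_chd >= nm$inc_chd))
    expect_true(all(m$inc_stroke >= nm$inc_stroke))
  }
})

test_that("validation pinpoints injected violations by table and stratum", {
  inp <- default_inputs()
  bad <- inp
  bad$epi$dw_stroke[5] <- 1.2
  v <- validate_inputs(bad)
  expect_true(all(grepl("^MorbidityTable", v)))
  expect_true(any(grepl("dw_stroke outside", v)))

  # swap one Maori/non-Maori CHD incidence pair so the ordering breaks
  bad <- inp
  i_m <- which(bad$epi$sex == "male" & bad$epi$ethnicity == "maori" &
                 bad$epi$age_start == 50)
  i_n <- which(bad$epi$sex == "male" & bad$epi$ethnicity == "non_maori" &
                 bad$epi$age_start == 50)
  tmp <- bad$epi$inc_chd[i_m]
  bad$epi$inc_chd[i_m] <- bad$epi$inc_chd[i_n]
  bad$epi$inc_chd[i_n] <- tmp
  v <- validate_inputs(bad)
  expect_true(any(grepl("inc_chd for maori below non_maori.*male/maori/50-54", v)))

  bad <- inp
  bad$costs$chd_subsequent_cost[1] <- bad$costs$chd_first_year_cost[1] + 1
  expect_match(validate_inputs(bad), "chd_first_year_cost not above")
})

test_that("an invalid generator config is rejected naming the field", {
  cfg <- generator_config()
  cfg$costs$chd_subsequent_anchor <- 20000
  expect_error(generate_inputs(1, cfg), "chd_subsequent_anchor")
  cfg <- generator_config()
  cfg$sodium$share_other <- 0.5
  expect_error(generate_inputs(1, cfg), "sum to 1")
})

test_that("write/read round-trips inputs losslessly", {
  inp <- default_inputs()
  d <- withr::local_tempdir()
  write_inputs(inp, d)
  back <- read_inputs(d)
  expect_equal(back[names(back) != "fingerprint"],
               inp[names(inp) != "fingerprint"], tolerance = 0)
  expect_identical(back$fingerprint, inp$fingerprint)
})

test_that("reading a file with a missing stratum names the stratum", {
  inp <- default_inputs()
  d <- withr::local_tempdir()
  write_inputs(inp, d)
  csv <- read.csv(file.path(d, "inputs.csv"), stringsAsFactors = FALSE,
                  colClasses = "character")
  drop <- which(csv$quantity == "incidence" & csv$disease == "chd" &
                  csv$sex == "female" & csv$ethnicity == "maori" &
                  csv$age_band == "40-44")
  write.csv(csv[-drop, ], file.path(d, "inputs.csv"), row.names = FALSE,
            quote = FALSE)
  expect_error(read_inputs(d), "female/maori/40-44")
})

test_that("unknown columns are tolerated with a warning", {
  inp <- default_inputs()
  d <- withr::local_tempdir()
  write_inputs(inp, d)
  csv <- read.csv(file.path(d, "inputs.csv"), stringsAsFactors = FALSE,
                  colClasses = "character")
  csv$note <- "x"
  write.csv(csv, file.path(d, "inputs.csv"), row.names = FALSE, quote = FALSE)
  expect_warning(back <- read_inputs(d), "unknown column")
  expect_equal(back$epi, inp$epi, tolerance = 0)
})

test_that("malformed numeric values fail with row context", {
  inp <- default_inputs()
  d <- withr::local_tempdir()
  write_inputs(inp, d)
  csv <- read.csv(file.path(d, "inputs.csv"), stringsAsFactors = FALSE,
                  colClasses = "character")
  csv$value[10] <- "oops"
  write.csv(csv, file.path(d, "inputs.csv"), row.names = FALSE, quote = FALSE)
  expect_error(read_inputs(d), "non-numeric value at data row 10")
})
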