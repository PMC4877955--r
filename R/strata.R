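#' Cohort stratification
#'
#' The cohort is stratified by sex (male/female), ethnicity (Maori/non-Maori)
#' and thirteen five-year age bands from 35-39 to 95-99, giving 2 x 2 x 13 = 52
#' strata. The band label carries its start age; a band's index age is that
#' start age.
#'
#' @name strata
NULL

SALT_SEXES <- c("male", "female")
SALT_ETHNICITIES <- c("maori", "non_maori")
SALT_BAND_STARTS <- seq(35L, 95L, by = 5L)
SALT_STATES <- c("healthy", "chd_year1", "chd_later",
                 "stroke_year1", "stroke_later", "dead_cvd", "dead_other")
SALT_ALIVE_STATES <- SALT_STATES[1:5]
SALT_DEAD_STATES <- c("dead_cvd", "dead_other")

#' Age-band labels
#'
#' @param starts integer vector of band start ages.
#' @param width band width in years (default 5).
#' @return character labels such as `"35-39"`.
#' @keywords internal
band_label <- function(starts, width = 5L) {
  sprintf("%d-%d", starts, starts + width - 1L)
}

#' Map an attained age to its five-year band start
#'
#' Ages beyond the oldest band are mapped to that band (the engine stops at
#' age 100, so in practice this caps at the 95-99 band).
#'
#' @param age numeric attained age(s).
#' @param band_starts sorted band start ages.
#' @return band start age for each input age.
#' @keywords internal
age_to_band_start <- function(age, band_starts = SALT_BAND_STARTS) {
  idx <- findInterval(age, band_starts)
  idx[idx < 1L] <- 1L
  idx[idx > length(band_starts)] <- length(band_starts)
  band_starts[idx]
}

#' Enumerate the cohort strata
#'
#' @param band_starts band start ages (default the full 35-99 range).
#' @return a data.frame with columns `sex`, `ethnicity`, `age_band`,
#'   `age_start`, one row per stratum, in a fixed canonical order.
#' @examples
#' nrow(enumerate_strata())  # 52
#' @export
enumerate_strata <- function(band_starts = SALT_BAND_STARTS) {
  g <- expand.grid(age_start = band_starts,
                   ethnicity = SALT_ETHNICITIES,
                   sex = SALT_SEXES,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(sex = g$sex, ethnicity = g$ethnicity,
             age_band = band_label(g$age_start), age_start = g$age_start,
             stringsAsFactors = FALSE)
}

#' Key strings for strata (used in violation and error messages)
#' @keywords internal
stratum_key <- function(df) {
  paste(df$sex, df$ethnicity, df$age_band, sep = "/")
}
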