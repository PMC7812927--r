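# Climate series: reading, validation, synthetic generation, PET fallback.

#' Read a daily climate series
#'
#' Expects delimited text with columns `date` (ISO), `precip_mm` and either
#' `et_mm` or `temp_C` (or both). When evapotranspiration is missing it is
#' derived from temperature with the Hamon-type fallback ([hamon_pet()]);
#' the result is flagged in the `pet_source` attribute.
#'
#' @param path file path (CSV with header).
#' @param lat site latitude in degrees, used only by the PET fallback.
#' @return data.frame: date (Date), precip_mm, et_mm, temp_C; strictly
#'   consecutive daily dates.
#' @export
read_climate <- function(path, lat = 51.3) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "precip_mm") %in% names(d)))
    stop("climate file needs columns date and precip_mm")
  d$date <- as.Date(d$date)
  if (anyNA(d$date)) stop("unparseable dates in climate file")
  gaps <- diff(as.integer(d$date))
  if (any(gaps != 1)) {
    bad <- which(gaps != 1)
    stop("climate series must be strictly daily; offending rows: ",
         paste(utils::head(bad + 1, 5), collapse = ", "))
  }
  if (any(d$precip_mm < 0)) stop("negative precipitation")
  pet_source <- "file"
  if (!"et_mm" %in% names(d)) {
    if (!"temp_C" %in% names(d))
      stop("climate file needs et_mm or temp_C")
    doy <- as.integer(format(d$date, "%j"))
    d$et_mm <- hamon_pet(d$temp_C, doy, lat)
    pet_source <- "hamon_fallback"
  }
  if (!"temp_C" %in% names(d)) d$temp_C <- NA_real_
  out <- d[, c("date", "precip_mm", "et_mm", "temp_C")]
  attr(out, "pet_source") <- pet_source
  out
}

#' Hamon-type daily potential evapotranspiration
#'
#' PET = 0.1651 (Ld/12) rho_sat, with Ld the daylength in hours and rho_sat
#' the saturated vapour density (g m^-3) at the daily temperature. A simple,
#' temperature-only stand-in used when measured or modelled
#' evapotranspiration is unavailable.
#'
#' @param temp_C daily mean temperature, degrees C.
#' @param doy day of year (1-366).
#' @param lat latitude, degrees.
#' @return PET, mm day^-1.
#' @export
hamon_pet <- function(temp_C, doy, lat = 51.3) {
  decl <- 0.4093 * sin(2 * pi * (284 + doy) / 365)
  lat_r <- lat * pi / 180
  cos_h <- pmin(1, pmax(-1, -tan(lat_r) * tan(decl)))
  Ld <- 24 / pi * acos(cos_h)
  es_hPa <- 6.108 * exp(17.27 * temp_C / (temp_C + 237.3))
  rho_sat <- 216.7 * es_hPa / (temp_C + 273.3)
  pmax(0, 0.1651 * (Ld / 12) * rho_sat)
}

#' Generate a synthetic daily climate series
#'
#' Sinusoidal annual temperature cycle with Gaussian day-to-day noise and a
#' Bernoulli-exponential rainfall process (wet days drawn independently,
#' wet-day amounts exponential so the expected annual total matches the
#' target). Evapotranspiration from the Hamon fallback. Defaults emulate a
#' temperate maritime (Belgian) climate. Fully reproducible given the seed.
#'
#' @param n_days length of the series.
#' @param start first date (ISO string or Date).
#' @param mean_T mean annual temperature, degrees C.
#' @param amp_T annual temperature amplitude (half peak-to-trough),
#'   degrees C.
#' @param annual_P target mean annual precipitation, mm.
#' @param wet_prob probability a day is wet.
#' @param sd_T day-to-day temperature noise, degrees C.
#' @param lat latitude for the PET daylength term.
#' @param seed RNG seed.
#' @return climate data.frame as from [read_climate()].
#' @export
synthetic_climate <- function(n_days, start = "1999-01-01", mean_T = 10,
                              amp_T = 7.5, annual_P = 850, wet_prob = 0.5,
                              sd_T = 1.5, lat = 51.3, seed = 1) {
  stopifnot(n_days >= 1, annual_P >= 0, wet_prob >= 0, wet_prob <= 1)
  dates <- as.Date(start) + seq_len(n_days) - 1
  doy <- as.integer(format(dates, "%j"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  temp <- mean_T - amp_T * cos(2 * pi * (doy - 15) / 365.25) +
    rnorm(n_days, 0, sd_T)
  wet <- rbinom(n_days, 1, wet_prob)
  amount <- if (wet_prob > 0) {
    rexp(n_days, rate = wet_prob * 365.25 / max(annual_P, 1e-12))
  } else numeric(n_days)
  data.frame(date = dates, precip_mm = wet * amount,
             et_mm = hamon_pet(temp, doy, lat), temp_C = temp)
}

#' Write a daily trace to delimited text
#'
#' @param trace an `sfw_trace` from [run_simulation()].
#' @param path output CSV path.
#' @export
write_daily_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
}
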