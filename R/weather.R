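## Photo-degree-day weather features and the per-observation weather window.
##
## The weather window is the weather half of an image-weather combo (IWC):
## a T x 6 matrix of daily (tmin, tmax, sunlight, rainfall, PDD, CPDD)
## covering `history_days` days before the imaging day, the imaging day
## itself, and `forecast_days` forecast days (default 90 + 1 + 6 = 97 rows).

WINDOW_COLUMNS <- c("tmin", "tmax", "sunlight", "rainfall", "pdd", "cpdd")

#' Forecast-condition sunlight factors
#'
#' Fraction of the monthly-climatology mean sunlight assigned to each
#' forecast condition category when measured sunlight is unavailable.
#'
#' @return Named numeric vector of factors.
#' @export
sunlight_condition_factors <- function() {
  c(sunny = 1.00, mostly_sunny = 0.75, mostly_cloudy = 0.50,
    cloudy = 0.25, shower = 0.00)
}

#' Daily photo-degree days (PDD)
#'
#' Half the diurnal temperature range multiplied by the sunlight duration:
#' `PDD = ((tmax - tmin) / 2) * sunlight`, in degree-hours. Vectorised.
#'
#' @param tmax Daily maximum temperature, degrees C.
#' @param tmin Daily minimum temperature, degrees C. Must satisfy
#'   `tmax >= tmin`.
#' @param sunlight Sunlight duration, hours, in `[0, 24]`.
#' @return Numeric vector of photo-degree days (degree-hours), `>= 0`.
#' @examples
#' compute_pdd(20, 10, 8) # 40
#' @export
compute_pdd <- function(tmax, tmin, sunlight) {
  abort_if(!is.numeric(tmax) || !is.numeric(tmin) || !is.numeric(sunlight),
           "tmax, tmin and sunlight must be numeric")
  abort_if(any(tmax < tmin), "tmax < tmin for at least one day (field: tmax/tmin)")
  abort_if(any(sunlight < 0), "negative sunlight duration (field: sunlight)")
  ((tmax - tmin) / 2) * sunlight
}

#' Cumulative photo-degree days (CPDD)
#'
#' Running sum of a daily PDD series: element k is the sum of the first k
#' daily values.
#'
#' @param pdd_series Non-empty numeric vector of daily PDD values.
#' @return Numeric vector of the same length, non-decreasing when the
#'   input is non-negative.
#' @examples
#' compute_cpdd(c(10, 20, 5)) # 10 30 35
#' @export
compute_cpdd <- function(pdd_series) {
  abort_if(length(pdd_series) == 0, "empty PDD series")
  abort_if(!is.numeric(pdd_series), "PDD series must be numeric")
  cumsum(pdd_series)
}

#' Estimate forecast-day sunlight from a condition category
#'
#' Bureau-style forecasts carry no sunlight duration; it is estimated as a
#' fixed fraction of the 20-year monthly mean sunlight: 100/75/50/25/0%
#' for sunny / mostly sunny / mostly cloudy / cloudy / shower.
#'
#' @param condition Character, one of `names(sunlight_condition_factors())`.
#' @param month Integer month 1-12.
#' @param clim Monthly climatology: numeric vector of 12 mean daily
#'   sunlight hours (January first), or a data frame with columns
#'   `month` and `mean_sunlight_h`.
#' @return Estimated sunlight duration in hours.
#' @examples
#' estimate_forecast_sunlight("mostly_sunny", 6, rep(8, 12)) # 6
#' @export
estimate_forecast_sunlight <- function(condition, month, clim) {
  fac <- sunlight_condition_factors()
  abort_if(!all(condition %in% names(fac)),
           "unknown forecast condition: ",
           paste(setdiff(condition, names(fac)), collapse = ", "))
  clim <- as_climatology(clim)
  abort_if(!all(month %in% 1:12), "month must be in 1..12")
  unname(fac[condition] * clim[month])
}

as_climatology <- function(clim) {
  if (is.data.frame(clim)) {
    abort_if(!all(c("month", "mean_sunlight_h") %in% names(clim)),
             "climatology needs columns month, mean_sunlight_h")
    abort_if(!setequal(clim$month, 1:12), "climatology must cover months 1..12")
    clim <- clim$mean_sunlight_h[order(clim$month)]
  }
  abort_if(length(clim) != 12, "climatology must have 12 monthly values")
  abort_if(any(!is.finite(clim)) || any(clim <= 0) || any(clim >= 24),
           "climatology values must lie in (0, 24)")
  as.numeric(clim)
}

#' Daily weather records
#'
#' Validating constructor for a daily weather table.
#'
#' @param date Calendar dates (coercible with `as.Date`).
#' @param tmin,tmax Daily temperature extremes, degrees C.
#' @param sunlight Sunlight hours; may be `NA` on forecast days.
#' @param rainfall Rainfall, mm.
#' @param condition Forecast condition category, or `"none"` for measured
#'   days.
#' @param is_forecast Logical flag per day.
#' @return A `data.frame` with class `daily_weather`, sorted by date.
#' @export
daily_weather <- function(date, tmin, tmax, sunlight, rainfall,
                          condition = "none", is_forecast = FALSE) {
  date <- as_date_strict(date)
  n <- length(date)
  df <- data.frame(
    date = date, tmin = as.numeric(tmin), tmax = as.numeric(tmax),
    sunlight = as.numeric(sunlight), rainfall = as.numeric(rainfall),
    condition = rep_len(as.character(condition), n),
    is_forecast = rep_len(as.logical(is_forecast), n)
  )
  abort_if(anyDuplicated(df$date) > 0, "duplicate dates in weather records: ",
           paste(df$date[duplicated(df$date)], collapse = ", "))
  abort_if(any(df$tmax < df$tmin), "tmax < tmin on ",
           paste(df$date[df$tmax < df$tmin], collapse = ", "))
  ok_sun <- is.na(df$sunlight) | (df$sunlight >= 0 & df$sunlight <= 24)
  abort_if(!all(ok_sun), "sunlight outside [0, 24] on ",
           paste(df$date[!ok_sun], collapse = ", "))
  abort_if(any(df$rainfall < 0, na.rm = TRUE), "negative rainfall")
  valid_cond <- c(names(sunlight_condition_factors()), "none")
  abort_if(!all(df$condition %in% valid_cond),
           "invalid condition token(s): ",
           paste(setdiff(df$condition, valid_cond), collapse = ", "))
  missing_sun <- is.na(df$sunlight)
  bad <- missing_sun & (!df$is_forecast | df$condition == "none")
  abort_if(any(bad),
           "days with absent sunlight must be forecast days with a condition: ",
           paste(df$date[bad], collapse = ", "))
  df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("daily_weather", "data.frame")
  df
}

#' Assemble the per-observation weather window
#'
#' Builds the T x 6 matrix (tmin, tmax, sunlight, rainfall, PDD, CPDD) for
#' one imaging date: `history_days` days of history, the imaging day, and
#' `forecast_days` forecast days. Forecast-day sunlight missing from the
#' records is estimated from the condition category and the monthly
#' climatology. CPDD is accumulated within the window (first row's CPDD is
#' its own PDD).
#'
#' @param records A `daily_weather` table covering the full required range.
#' @param imaging_date The observation date.
#' @param clim Monthly climatology (see [estimate_forecast_sunlight()]).
#' @param history_days,forecast_days Window extents; defaults 90 and 6.
#' @return Numeric matrix of dimension `(history_days + 1 + forecast_days) x 6`
#'   with attributes `imaging_row_index` (1-based row of the imaging day)
#'   and `dates`.
#' @export
build_weather_window <- function(records, imaging_date, clim,
                                 history_days = 90, forecast_days = 6) {
  abort_if(history_days < 0 || forecast_days < 0,
           "history_days and forecast_days must be >= 0")
  imaging_date <- as_date_strict(imaging_date, "imaging_date")
  abort_if(length(imaging_date) != 1, "imaging_date must be a single date")
  if (!inherits(records, "daily_weather")) {
    records <- daily_weather(records$date, records$tmin, records$tmax,
                             records$sunlight, records$rainfall,
                             records$condition %||% "none",
                             records$is_forecast %||% FALSE)
  }
  need <- seq(imaging_date - history_days, imaging_date + forecast_days, by = "day")
  hit <- match(need, records$date)
  abort_if(anyNA(hit), "weather records missing required date(s): ",
           paste(need[is.na(hit)], collapse = ", "))
  w <- records[hit, , drop = FALSE]

  sun <- w$sunlight
  fill <- which(is.na(sun))
  if (length(fill) > 0) {
    months <- as.integer(format(w$date[fill], "%m"))
    sun[fill] <- estimate_forecast_sunlight(w$condition[fill], months, clim)
  }
  pdd <- compute_pdd(w$tmax, w$tmin, sun)
  m <- cbind(tmin = w$tmin, tmax = w$tmax, sunlight = sun,
             rainfall = w$rainfall, pdd = pdd, cpdd = compute_cpdd(pdd))
  attr(m, "imaging_row_index") <- history_days + 1L
  attr(m, "dates") <- w$date
  m
}

#' Per-column normalisation statistics for weather windows
#'
#' Means and standard deviations of each of the 6 window columns pooled
#' over all rows of the supplied windows. Compute these on the training
#' split only and reuse them everywhere else.
#'
#' @param windows A list of weather-window matrices.
#' @return List with numeric vectors `mean` and `sd` (length 6).
#' @export
window_stats <- function(windows) {
  abort_if(length(windows) == 0, "no windows supplied")
  all <- do.call(rbind, lapply(windows, unclass))
  abort_if(ncol(all) != length(WINDOW_COLUMNS), "windows must have 6 columns")
  list(mean = colMeans(all),
       sd = apply(all, 2, stats::sd))
}

#' Z-score a weather window
#'
#' Per-column standardisation using precomputed statistics; columns with
#' zero standard deviation map to zero.
#'
#' @param window A weather-window matrix.
#' @param stats Output of [window_stats()].
#' @return Matrix of the same shape.
#' @export
normalize_window <- function(window, stats) {
  abort_if(ncol(window) != length(stats$mean) || length(stats$mean) != length(stats$sd),
           "stats/window column mismatch: window has ", ncol(window),
           " columns, stats ", length(stats$mean))
  sd <- ifelse(stats$sd > 0, stats$sd, Inf)   # sd = 0 -> column of zeros
  out <- sweep(sweep(unclass(window), 2, stats$mean, "-"), 2, sd, "/")
  attributes(out)$imaging_row_index <- attr(window, "imaging_row_index")
  out
}

#' Invert [normalize_window()]
#'
#' Exact inverse when all column standard deviations are positive.
#'
#' @inheritParams normalize_window
#' @return Matrix on the original scale.
#' @export
denormalize_window <- function(window, stats) {
  abort_if(ncol(window) != length(stats$mean),
           "stats/window column mismatch")
  sweep(sweep(unclass(window), 2, stats$sd, "*"), 2, stats$mean, "+")
}
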