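## Fully synthetic benchmark data: a Southern-Hemisphere seasonal weather
## simulator, a cumulative-photo-degree-day (CPDD) threshold flowering
## model with per-plant micro-environment variation, and a procedural
## wheat-head renderer whose exposed-head fraction tracks developmental
## progress. The synthetic world is governed by exactly the features the
## model consumes, so signal recovery is a fair end-to-end test.

#' Synthetic-benchmark configuration
#'
#' Defaults describe two sowing groups of an autumn-sown spring wheat in a
#' temperate Southern-Hemisphere climate: plants accumulate photo-degree
#' days from sowing and flower when their individual threshold
#' `theta ~ N(theta0, sigma_theta^2)` is reached; the head becomes visible
#' over the last `emergence_cpdd` degree-hours before anthesis, so image
#' appearance encodes the remaining heat-light requirement while the
#' weather series sets the rate at which it is consumed.
#'
#' @param n_plants Total plants, split evenly over sowing groups.
#' @param sowing_dates One date per sowing group.
#' @param tmax_mean,tmax_amp Seasonal mean and amplitude of daily maximum
#'   temperature (degrees C); warmest at `peak_doy`.
#' @param temp_range_mean,temp_range_sd Mean and spread of the diurnal
#'   range.
#' @param temp_noise_sd Day-to-day Gaussian noise on tmax.
#' @param peak_doy Day-of-year of the seasonal peak (mid-January summer).
#' @param sun_mean,sun_amp,sun_noise_sd Seasonal sunlight-hours curve and
#'   noise.
#' @param rain_prob,rain_scale Daily rain probability and exponential
#'   mean (mm).
#' @param theta0 Population CPDD flowering threshold (degree-hours from
#'   sowing).
#' @param sigma_theta Per-plant threshold standard deviation
#'   (micro-environment variation).
#' @param emergence_cpdd Degree-hours over which the head emerges; visible
#'   progress is `1 - remaining/emergence_cpdd`, clamped to `[0, 1]`.
#' @param obs_min_days,obs_max_days Observation window in days before
#'   anthesis.
#' @param images_per_day Images captured per plant per observation day.
#' @param image_size Rendered image side length (pixels).
#' @param image_noise_sd Additive Gaussian pixel noise.
#' @param blur_range Range of the per-image Gaussian blur sigma (pixels).
#' @param seed Master seed; every derived draw is a pure function of it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_plants = 120L,
                       sowing_dates = c("2023-05-01", "2023-05-31"),
                       tmax_mean = 21.5, tmax_amp = 9,
                       temp_range_mean = 8, temp_range_sd = 2,
                       temp_noise_sd = 1.5, peak_doy = 20,
                       sun_mean = 7.5, sun_amp = 4, sun_noise_sd = 1.8,
                       rain_prob = 0.35, rain_scale = 3,
                       theta0 = 2500, sigma_theta = 120,
                       emergence_cpdd = 480,
                       obs_min_days = 2L, obs_max_days = 24L,
                       images_per_day = 2L, image_size = 32L,
                       image_noise_sd = 0.04, blur_range = c(0, 1.2),
                       seed = 1L) {
  abort_if(n_plants < 2, "n_plants must be >= 2")
  abort_if(sigma_theta < 0, "sigma_theta must be >= 0")
  abort_if(theta0 <= 0 || emergence_cpdd <= 0, "thresholds must be > 0")
  abort_if(length(sowing_dates) < 1, "need at least one sowing group")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a daily weather series
#'
#' Seasonal sinusoids plus Gaussian noise for temperatures and sunlight
#' (`tmax > tmin` enforced by construction, sunlight clipped to `[0, 24]`),
#' Bernoulli-exponential rainfall. Every day also carries a forecast
#' condition category, assigned from the ratio of its sunlight to the
#' monthly climatology, so any day can later be masked into a forecast.
#'
#' @param config A [sim_config()].
#' @param start_date First simulated day.
#' @param n_days Number of days.
#' @param seed Seed (defaults to the config seed).
#' @return A `daily_weather` table.
#' @export
simulate_weather <- function(config, start_date, n_days, seed = config$seed) {
  abort_if(n_days < 1, "n_days must be >= 1")
  dates <- as_date_strict(start_date) + 0:(n_days - 1)
  doy <- as.integer(format(dates, "%j"))
  season <- cos(2 * pi * (doy - config$peak_doy) / 365)
  withr::with_seed(seed, {
    tmax <- config$tmax_mean + config$tmax_amp * season +
      stats::rnorm(n_days, 0, config$temp_noise_sd)
    range <- pmax(0.5, config$temp_range_mean +
                    stats::rnorm(n_days, 0, config$temp_range_sd))
    tmin <- tmax - range
    sun <- pmin(24, pmax(0, config$sun_mean + config$sun_amp * season +
                           stats::rnorm(n_days, 0, config$sun_noise_sd)))
    rain <- ifelse(stats::runif(n_days) < config$rain_prob,
                   stats::rexp(n_days, 1 / config$rain_scale), 0)
  })
  clim <- simulate_climatology(config)
  month <- as.integer(format(dates, "%m"))
  cond <- condition_from_ratio(sun / clim[month])
  daily_weather(dates, tmin, tmax, sun, rain, condition = cond,
                is_forecast = FALSE)
}

#' Monthly sunlight climatology of the simulated climate
#'
#' Deterministic monthly means of the noise-free seasonal sunlight curve,
#' standing in for a 20-year historical average.
#'
#' @param config A [sim_config()].
#' @return Numeric vector of 12 monthly mean sunlight hours.
#' @export
simulate_climatology <- function(config) {
  mid <- c(15, 46, 75, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  pmin(23.9, pmax(0.1, config$sun_mean +
                    config$sun_amp * cos(2 * pi * (mid - config$peak_doy) / 365)))
}

## nearest condition category for a sunlight/climatology ratio
condition_from_ratio <- function(ratio) {
  fac <- sunlight_condition_factors()
  names(fac)[apply(abs(outer(ratio, fac, "-")), 1, which.min)]
}

#' Assign CPDD-threshold phenology to simulated plants
#'
#' Draws per-plant thresholds `theta_i ~ N(theta0, sigma_theta^2)`
#' (truncated positive) and sets each plant's anthesis date to the first
#' day its CPDD accumulated since sowing reaches `theta_i`. Warmer and
#' sunnier spells advance flowering by construction.
#'
#' @param config A [sim_config()].
#' @param weather A `daily_weather` table covering sowing to anthesis for
#'   every group.
#' @param seed Seed (defaults to the config seed, offset).
#' @return `data.frame` with `plant_id`, `group`, `sowing_date`, `theta`,
#'   `anthesis_date`.
#' @export
assign_phenology <- function(config, weather, seed = config$seed + 1L) {
  n <- config$n_plants
  groups <- rep(seq_along(config$sowing_dates), length.out = n)
  sowing <- as_date_strict(config$sowing_dates)[groups]
  withr::with_seed(seed, {
    theta <- config$theta0 + config$sigma_theta * stats::rnorm(n)
    theta <- pmax(theta, config$theta0 * 0.1)
  })
  pdd <- compute_pdd(weather$tmax, weather$tmin, weather$sunlight)
  anthesis <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  for (i in seq_len(n)) {
    from <- which(weather$date == sowing[i])
    abort_if(length(from) == 0, "weather does not cover sowing date ",
             sowing[i])
    cp <- cumsum(pdd[from:length(pdd)])
    hit <- which(cp >= theta[i])
    abort_if(length(hit) == 0,
             "CPDD threshold never reached for plant ", i,
             " within the simulated window; simulate a longer series")
    anthesis[i] <- weather$date[from + hit[1] - 1]
  }
  data.frame(plant_id = sprintf("P%03d", seq_len(n)), group = groups,
             sowing_date = sowing, theta = theta, anthesis_date = anthesis)
}

## ---- procedural head rendering --------------------------------------------

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0.05) return(img)
  r <- max(1L, ceiling(2 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in (-r):r) {
      rows <- pmin(pmax(seq_len(n) + o, 1L), n)
      out <- out + k[o + r + 1L] * m[rows, , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

rotate_image <- function(img, degrees) {
  if (abs(degrees) < 0.1) return(img)
  th <- degrees * pi / 180
  s <- nrow(img)
  ctr <- (s + 1) / 2
  gy <- matrix(seq_len(s), s, s) - ctr
  gx <- matrix(seq_len(s), s, s, byrow = TRUE) - ctr
  sy <- cos(th) * gy - sin(th) * gx + ctr
  sx <- sin(th) * gy + cos(th) * gx + ctr
  y0 <- pmin(pmax(floor(sy), 1), s - 1); x0 <- pmin(pmax(floor(sx), 1), s - 1)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  at <- function(yy, xx) matrix(img[cbind(as.vector(yy), as.vector(xx))], s, s)
  at(y0, x0) * (1 - fy) * (1 - fx) + at(y0 + 1, x0) * fy * (1 - fx) +
    at(y0, x0 + 1) * (1 - fy) * fx + at(y0 + 1, x0 + 1) * fy * fx
}

#' Render a synthetic wheat-head image
#'
#' Procedural grayscale crop: textured background, a vertical sheath, and
#' a bright head ellipse whose exposed fraction equals `progress`
#' (0 = fully booted, 1 = fully emerged). Nuisance factors (rotation up to
#' +/-15 degrees, illumination gain, Gaussian noise and blur) are drawn
#' deterministically from `nuisance_seed`.
#'
#' @param progress Emergence fraction in `[0, 1]`.
#' @param nuisance_seed Seed for the nuisance draws.
#' @param size Image side length in pixels.
#' @param noise_sd Additive pixel-noise standard deviation.
#' @param blur_range Range of the blur sigma.
#' @return `size x size` matrix with values in `[0, 1]` and attribute
#'   `head_mask` (the pre-nuisance exposed-head mask).
#' @export
render_head_image <- function(progress, nuisance_seed = 0L, size = 32L,
                              noise_sd = 0.04, blur_range = c(0, 1.2)) {
  abort_if(progress < 0 || progress > 1, "progress must be in [0, 1]")
  s <- as.integer(size)
  withr::with_seed(nuisance_seed, {
    rot <- stats::runif(1, -15, 15)
    gain <- stats::runif(1, 0.85, 1.15)
    blur <- stats::runif(1, blur_range[1], blur_range[2])
    bg_phase <- stats::runif(2, 0, 2 * pi)
    noise <- matrix(stats::rnorm(s * s, 0, noise_sd), s, s)
    speckle <- matrix(stats::runif(s * s), s, s)
  })
  yy <- matrix(seq_len(s), s, s) / s          # 1 at bottom row
  xx <- matrix(seq_len(s), s, s, byrow = TRUE) / s
  img <- 0.30 + 0.04 * sin(6 * xx + bg_phase[1]) * cos(5 * yy + bg_phase[2])

  cx <- 0.5
  sheath <- abs(xx - cx) < 0.08 & yy > 0.42
  img[sheath] <- 0.46 + 0.03 * sin(20 * yy[sheath])

  ## head: ellipse from y_top (0.12) to the boot line (0.55); the exposed
  ## part grows upward from the boot with progress. The emergence line is
  ## anti-aliased (fractional pixel coverage) so appearance varies
  ## continuously with progress instead of jumping by whole pixel rows.
  y_top <- 0.12; y_boot <- 0.55
  y_expose <- y_boot - progress * (y_boot - y_top)
  in_head <- ((xx - cx) / 0.13)^2 +
    ((yy - (y_top + y_boot) / 2) / ((y_boot - y_top) / 2))^2 <= 1
  cover <- pmin(pmax((yy - y_expose) * s, 0), 1)        # edge over one pixel
  cover[!in_head | yy > y_boot] <- 0
  head_val <- 0.82 + 0.12 * (speckle - 0.5)
  img <- img * (1 - cover) + head_val * cover
  exposed <- cover > 0

  img <- rotate_image(img, rot)
  img <- gaussian_blur(img, blur)
  img <- img * gain + noise
  img <- pmin(pmax(img, 0), 1)
  attr(img, "head_mask") <- exposed
  img
}

## ---- dataset assembly ------------------------------------------------------

## Mask the days strictly after `imaging_date` as forecasts: sunlight
## becomes NA (to be re-estimated from the condition category), the
## forecast flag is set. Temperatures and rainfall stay as given.
forecastify <- function(records, imaging_date) {
  imaging_date <- as_date_strict(imaging_date)
  after <- records$date > imaging_date
  records$sunlight[after] <- NA_real_
  records$is_forecast[after] <- TRUE
  records
}

## deterministic per-image nuisance seed (kept below 2^31)
nuisance_seed_for <- function(seed, plant_idx, day_idx, img_idx) {
  (seed * 7L + plant_idx * 131L + day_idx * 17L + img_idx) %% 2000000011L
}

#' Build a complete in-memory synthetic IWC pool
#'
#' Simulates weather, assigns phenology, renders images for every plant
#' and observation day, and assembles the IWC pool with weather windows
#' (forecast days masked and re-estimated from condition categories, as in
#' deployment). The weather window is shared between all IWCs captured on
#' the same date.
#'
#' @param config A [sim_config()].
#' @param history_days,forecast_days Window extents.
#' @param phenology_seed Seed for the per-plant threshold draws; override
#'   to grow a second "field" of different plants under identical weather
#'   (anchor-transfer experiments).
#' @return List with `pool` (list of `iwc`), `weather`, `climatology`,
#'   `phenology`, `config`.
#' @export
build_iwc_pool <- function(config = sim_config(), history_days = 90,
                           forecast_days = 6,
                           phenology_seed = config$seed + 1L) {
  start <- min(as_date_strict(config$sowing_dates)) - history_days - 5
  horizon <- as.integer(max(as_date_strict(config$sowing_dates)) +
                          240 - start)
  weather <- simulate_weather(config, start, horizon)
  clim <- simulate_climatology(config)
  phen <- assign_phenology(config, weather, seed = phenology_seed)

  pdd <- compute_pdd(weather$tmax, weather$tmin, weather$sunlight)
  window_cache <- new.env(parent = emptyenv())
  get_window <- function(date) {
    key <- format(date)
    if (is.null(window_cache[[key]])) {
      window_cache[[key]] <- build_weather_window(
        forecastify(weather, date), date, clim,
        history_days = history_days, forecast_days = forecast_days)
    }
    window_cache[[key]]
  }

  pool <- list()
  for (i in seq_len(nrow(phen))) {
    sow_idx <- which(weather$date == phen$sowing_date[i])
    cp <- cumsum(pdd[sow_idx:length(pdd)])
    for (d in config$obs_max_days:config$obs_min_days) {
      date <- phen$anthesis_date[i] - d
      if (date < as.Date(weather$date[1]) + history_days) next
      cpdd_now <- cp[as.integer(date - phen$sowing_date[i]) + 1L]
      remaining <- phen$theta[i] - cpdd_now
      progress <- min(1, max(0, 1 - remaining / config$emergence_cpdd))
      win <- get_window(date)
      for (k in seq_len(config$images_per_day)) {
        img <- render_head_image(
          progress, nuisance_seed_for(config$seed, i, d, k),
          size = config$image_size, noise_sd = config$image_noise_sd,
          blur_range = config$blur_range)
        pool[[length(pool) + 1L]] <- iwc(
          image = img, weather = win, plant_id = phen$plant_id[i],
          capture_date = date, days_to_anthesis = d)
      }
    }
  }
  list(pool = pool, weather = weather, climatology = clim, phenology = phen,
       config = config)
}

#' Write a synthetic dataset to disk
#'
#' Emits PNG images, a manifest CSV (`plant_id,date,image_path,
#' days_to_anthesis`), the weather CSV, the climatology CSV, and a
#' ground-truth JSON (per-plant thresholds and anthesis dates, plus the
#' seed) under `out_dir`. Fully reproducible per seed; round-trips through
#' [load_iwc_dataset()].
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest `data.frame`.
#' @export
emit_dataset <- function(config = sim_config(), out_dir) {
  built <- build_iwc_pool(config)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  abort_if(!dir.exists(out_dir), "cannot create output directory ", out_dir)
  manifest <- NULL
  counters <- new.env(parent = emptyenv())
  for (x in built$pool) {
    key <- paste(x$plant_id, format(x$capture_date), sep = "_")
    counters[[key]] <- (counters[[key]] %||% 0L) + 1L
    rel <- file.path("images", paste0(key, "_", counters[[key]], ".png"))
    png::writePNG(x$image, file.path(out_dir, rel))
    manifest <- rbind(manifest, data.frame(
      plant_id = x$plant_id, date = format(x$capture_date),
      image_path = rel, days_to_anthesis = x$days_to_anthesis))
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  w <- built$weather
  utils::write.csv(
    data.frame(date = format(w$date), tmin_c = w$tmin, tmax_c = w$tmax,
               sunlight_h = w$sunlight, rain_mm = w$rainfall,
               condition = w$condition, is_forecast = w$is_forecast),
    file.path(out_dir, "weather.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(month = 1:12, mean_sunlight_h = built$climatology),
    file.path(out_dir, "climatology.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed,
         plants = data.frame(plant_id = built$phenology$plant_id,
                             group = built$phenology$group,
                             sowing_date = format(built$phenology$sowing_date),
                             theta = built$phenology$theta,
                             anthesis_date = format(built$phenology$anthesis_date))),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
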