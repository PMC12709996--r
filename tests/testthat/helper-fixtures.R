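# Shared fixtures, all generated in code.

# Small extractor/head specs so network tests run in milliseconds.
tiny_ext_spec <- function(image_size = 8L, ...) {
  extractor_spec(image_size = image_size, backbone_out_dim = 10L,
                 image_proj_dim = 6L, weather_hidden_dim = 6L,
                 out_dim = 4L, fusion_hidden_dim = 5L, ...)
}

# Deterministic daily weather covering `n_days` from `start`.
fixture_weather <- function(n_days = 120, start = "2023-04-01",
                            sunlight = NULL) {
  dates <- as.Date(start) + 0:(n_days - 1)
  tmax <- 18 + 4 * sin(seq_len(n_days) / 20)
  daily_weather(
    date = dates, tmin = tmax - 8, tmax = tmax,
    sunlight = sunlight %||% rep_len(c(6, 8, 10, 7), n_days),
    rainfall = rep_len(c(0, 0, 2.5, 0, 1), n_days))
}

fixture_clim <- function(mean_h = 8) rep(mean_h, 12)

# A metadata pool for the pair sampler: `plants` plants, observation days
# `days`, `per_day` images per plant and day.
fixture_pair_pool <- function(plants = 12, days = 2:10, per_day = 2) {
  expand <- expand.grid(plant = seq_len(plants), day = days,
                        img = seq_len(per_day))
  data.frame(plant_id = sprintf("P%02d", expand$plant),
             days_to_anthesis = expand$day)
}

# A tiny in-memory IWC pool compatible with tiny_ext_spec(): random 8x8
# images, 5-row weather windows shared by capture date.
fixture_iwc_pool <- function(n_plants = 6, days = 2:7, per_day = 2,
                             seed = 99, t_rows = 5) {
  withr::with_seed(seed, {
    pool <- list()
    anthesis <- as.Date("2023-09-20")
    # one weather window per calendar date, shared by all plants
    wins <- lapply(days, function(d) {
      matrix(rnorm(t_rows * 6), t_rows, 6,
             dimnames = list(NULL, c("tmin", "tmax", "sunlight",
                                     "rainfall", "pdd", "cpdd")))
    })
    for (p in seq_len(n_plants)) {
      for (d in days) {
        date <- anthesis - d
        win <- wins[[match(d, days)]]
        for (k in seq_len(per_day)) {
          img <- matrix(runif(64), 8, 8)
          # plant a weak signal so the image is informative about d
          img[1:3, 1:3] <- d / 10
          pool[[length(pool) + 1]] <- iwc(
            image = img, weather = win,
            plant_id = sprintf("P%02d", p), capture_date = date,
            days_to_anthesis = d)
        }
      }
    }
    pool
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
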