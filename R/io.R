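## Manifest / weather / climatology readers and the dataset loader.

#' Read an observation manifest
#'
#' CSV with header `plant_id,date,image_path,days_to_anthesis` (ISO
#' dates; `days_to_anthesis` may be blank in inference mode).
#'
#' @param path CSV path.
#' @return `data.frame` with typed columns; dates as `Date`,
#'   `days_to_anthesis` as integer with `NA` for absent labels.
#' @export
read_manifest <- function(path) {
  abort_if(!file.exists(path), "manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("plant_id", "date", "image_path", "days_to_anthesis")
  abort_if(!all(need %in% names(df)),
           "manifest missing column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0) return(df)
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  abort_if(length(bad) > 0, "unparsable date in manifest row(s) ",
           paste(bad, collapse = ", "))
  days_chr <- trimws(df$days_to_anthesis)
  days <- suppressWarnings(as.integer(days_chr))
  blank <- days_chr == "" | is.na(days_chr)
  days[blank] <- NA_integer_
  bad <- which(!blank & is.na(days))
  abort_if(length(bad) > 0, "unparsable days_to_anthesis in row(s) ",
           paste(bad, collapse = ", "))
  bad <- which(!is.na(days) & days < 0)
  abort_if(length(bad) > 0, "negative days_to_anthesis in row(s) ",
           paste(bad, collapse = ", "))
  data.frame(plant_id = df$plant_id, date = dates,
             image_path = df$image_path, days_to_anthesis = days)
}

#' Read a crop-box manifest
#'
#' CSV with header `image_path,x0,y0,x1,y1,plant_id,date`: externally
#' supplied wheat-head bounding boxes (half-open pixel coordinates, as
#' from any detector honouring the `detect(image) -> boxes` contract).
#'
#' @param path CSV path.
#' @return `data.frame` with typed columns.
#' @export
read_crop_manifest <- function(path) {
  abort_if(!file.exists(path), "crop manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "x0", "y0", "x1", "y1", "plant_id", "date")
  abort_if(!all(need %in% names(df)),
           "crop manifest missing column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "))
  df$date <- as.Date(df$date, format = "%Y-%m-%d")
  abort_if(anyNA(df$date), "unparsable date in crop manifest")
  bad <- which(df$x1 <= df$x0 | df$y1 <= df$y0)
  abort_if(length(bad) > 0, "degenerate crop box at row(s) ",
           paste(bad, collapse = ", "))
  df
}

#' Prepare head crops from raw stills and a crop manifest
#'
#' Reads each source image, extracts the manifest's head boxes, removes
#' crops smaller than `min_w x min_h`, and writes the surviving crops plus
#' an observation manifest (`plant_id,date,image_path,days_to_anthesis`,
#' labels blank) to `out_dir` — the image half of an IWC store.
#'
#' @param crops A crop manifest (`data.frame` or path for
#'   [read_crop_manifest()]).
#' @param src_dir Directory the manifest's `image_path`s are relative to.
#' @param out_dir Output directory.
#' @param min_w,min_h Quality filter thresholds (pixels).
#' @return Invisibly, the written observation manifest.
#' @export
prepare_crops <- function(crops, src_dir, out_dir, min_w = 20, min_h = 50) {
  if (!is.data.frame(crops)) crops <- read_crop_manifest(crops)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- NULL
  kept <- 0L
  for (i in seq_len(nrow(crops))) {
    img <- rgb_to_luminance(png::readPNG(file.path(src_dir,
                                                   crops$image_path[i])))
    cr <- crop_head(img, crops[i, c("x0", "y0", "x1", "y1")])
    surv <- suppressMessages(filter_small_crops(list(cr), min_w, min_h))
    if (length(surv) == 0) next
    kept <- kept + 1L
    rel <- file.path("images", sprintf("%s_%s_%03d.png", crops$plant_id[i],
                                       format(crops$date[i]), kept))
    png::writePNG(surv[[1]], file.path(out_dir, rel))
    manifest <- rbind(manifest, data.frame(
      plant_id = crops$plant_id[i], date = format(crops$date[i]),
      image_path = rel, days_to_anthesis = NA_integer_))
  }
  abort_if(is.null(manifest), "no crops survived the size filter")
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  message(kept, " of ", nrow(crops), " crops kept")
  invisible(manifest)
}

#' Read a daily weather CSV
#'
#' Columns `date,tmin_c,tmax_c,sunlight_h,rain_mm,condition,is_forecast`.
#' Rows are validated (duplicate dates, `tmax < tmin`, unknown condition
#' tokens are errors) and sorted by date.
#'
#' @param path CSV path.
#' @return A `daily_weather` table.
#' @export
read_weather_csv <- function(path) {
  abort_if(!file.exists(path), "weather file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin_c", "tmax_c", "sunlight_h", "rain_mm",
            "condition", "is_forecast")
  abort_if(!all(need %in% names(df)),
           "weather CSV missing column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "))
  dup <- which(duplicated(df$date))
  abort_if(length(dup) > 0, "duplicate weather date(s) at row(s) ",
           paste(dup, collapse = ", "))
  bad <- which(df$tmax_c < df$tmin_c)
  abort_if(length(bad) > 0, "tmax < tmin at weather row(s) ",
           paste(bad, collapse = ", "))
  daily_weather(df$date, df$tmin_c, df$tmax_c, df$sunlight_h, df$rain_mm,
                condition = df$condition,
                is_forecast = as.logical(df$is_forecast))
}

#' Read a monthly sunlight climatology CSV
#'
#' Columns `month,mean_sunlight_h`, all 12 months present.
#'
#' @param path CSV path.
#' @return Numeric vector of 12 monthly means (January first).
#' @export
read_climatology_csv <- function(path) {
  abort_if(!file.exists(path), "climatology file not found: ", path)
  as_climatology(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Load an emitted dataset back into an IWC pool
#'
#' Reads the manifest, images, weather and climatology written by
#' [emit_dataset()] (or prepared by hand in the same formats) and
#' reconstructs the IWC pool, masking post-imaging days as forecasts
#' exactly as at simulation time.
#'
#' @param dir Dataset directory.
#' @param history_days,forecast_days Window extents.
#' @return List with `pool`, `manifest`, `weather`, `climatology`.
#' @export
load_iwc_dataset <- function(dir, history_days = 90, forecast_days = 6) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  weather <- read_weather_csv(file.path(dir, "weather.csv"))
  clim <- read_climatology_csv(file.path(dir, "climatology.csv"))
  window_cache <- new.env(parent = emptyenv())
  pool <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    date <- manifest$date[i]
    key <- format(date)
    if (is.null(window_cache[[key]])) {
      window_cache[[key]] <- build_weather_window(
        forecastify(weather, date), date, clim,
        history_days = history_days, forecast_days = forecast_days)
    }
    img <- png::readPNG(file.path(dir, manifest$image_path[i]))
    pool[[i]] <- iwc(image = rgb_to_luminance(img),
                     weather = window_cache[[key]],
                     plant_id = manifest$plant_id[i], capture_date = date,
                     days_to_anthesis = manifest$days_to_anthesis[i])
  }
  list(pool = pool, manifest = manifest, weather = weather,
       climatology = clim)
}

#' Save / load a trained model
#'
#' Checkpoints are self-describing: they embed both specs, the window
#' statistics and the training report next to the raw and EMA parameters.
#'
#' @param model A `spikecast_model`.
#' @param path Destination file.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  abort_if(!inherits(model, "spikecast_model"), "not a spikecast_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  abort_if(!file.exists(path), "checkpoint not found: ", path)
  m <- readRDS(path)
  abort_if(!inherits(m, "spikecast_model"), "file is not a spikecast checkpoint")
  m
}
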