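## The image-weather combo (IWC) data model, pair labelling rules, and the
## quota-constrained random pair sampler that drives meta-learning.

#' Construct an image-weather combo (IWC)
#'
#' One observation of one plant: a head-image crop plus the weather window
#' around its capture date.
#'
#' @param image Image matrix (grayscale, values in `[0, 1]`).
#' @param weather Weather-window matrix from [build_weather_window()].
#' @param plant_id Plant identifier.
#' @param capture_date Observation date.
#' @param days_to_anthesis Non-negative integer; may be `NA` at inference.
#' @param window_key Optional key identifying the weather window; IWCs
#'   sharing a key share the window (used to avoid recomputing the weather
#'   encoder). Defaults to the capture date.
#' @return An object of class `iwc`.
#' @export
iwc <- function(image, weather, plant_id, capture_date,
                days_to_anthesis = NA_integer_, window_key = NULL) {
  capture_date <- as_date_strict(capture_date, "capture_date")
  if (!is.na(days_to_anthesis)) {
    abort_if(days_to_anthesis < 0, "days_to_anthesis must be >= 0, got ",
             days_to_anthesis)
  }
  structure(
    list(image = image, weather = weather, plant_id = as.character(plant_id),
         capture_date = capture_date,
         days_to_anthesis = as.integer(days_to_anthesis),
         window_key = as.character(window_key %||% format(capture_date))),
    class = "iwc")
}

#' @export
print.iwc <- function(x, ...) {
  cat("<iwc> plant", x$plant_id, "on", format(x$capture_date),
      if (!is.na(x$days_to_anthesis)) paste0("(", x$days_to_anthesis,
                                             " days to anthesis)") else "",
      "\n")
  invisible(x)
}

#' Metadata table of an IWC pool
#'
#' @param pool List of `iwc` objects.
#' @return `data.frame` with `plant_id`, `capture_date`, `days_to_anthesis`,
#'   `window_key`.
#' @export
pool_metadata <- function(pool) {
  abort_if(length(pool) == 0, "empty IWC pool")
  data.frame(
    plant_id = vapply(pool, function(x) x$plant_id, character(1)),
    capture_date = as.Date(vapply(pool, function(x) format(x$capture_date),
                                  character(1))),
    days_to_anthesis = vapply(pool, function(x) as.integer(x$days_to_anthesis),
                              integer(1)),
    window_key = vapply(pool, function(x) x$window_key, character(1))
  )
}

PAIR_LEVELS <- list(binary = c("negative", "positive"),
                    ternary = c("negative", "neutral", "positive"))

#' Binary pair label
#'
#' `negative` when the first IWC's days to anthesis is equal to or greater
#' than the second's; `positive` when it is smaller. Note the deliberate
#' asymmetry: ties are negative in both orders.
#'
#' @param d1,d2 Non-negative days to anthesis (vectorised).
#' @return Factor with levels `negative`, `positive`.
#' @export
binary_pair_label <- function(d1, d2) {
  abort_if(any(d1 < 0) || any(d2 < 0), "days to anthesis must be >= 0")
  factor(ifelse(d1 >= d2, "negative", "positive"), levels = PAIR_LEVELS$binary)
}

#' Ternary pair label
#'
#' With `diff = d1 - d2`: `positive` when `diff <= -2` (first flowers at
#' least two days sooner), `neutral` when `|diff| <= 1`, `negative` when
#' `diff >= 2`. The `diff = +2` case mirrors the positive side so the rule
#' is swap-symmetric.
#'
#' @inheritParams binary_pair_label
#' @return Factor with levels `negative`, `neutral`, `positive`.
#' @export
ternary_pair_label <- function(d1, d2) {
  abort_if(any(d1 < 0) || any(d2 < 0), "days to anthesis must be >= 0")
  diff <- d1 - d2
  factor(ifelse(diff >= 2, "negative", ifelse(diff <= -2, "positive", "neutral")),
         levels = PAIR_LEVELS$ternary)
}

#' Pair sampler configuration
#'
#' Defaults follow the meta-learning protocol: 24,000 training and 6,000
#' validation pairs per epoch; 80% of pairs juxtapose distinct
#' days-to-anthesis values and 95% distinct plant identifiers.
#'
#' @param n_train,n_val Pair counts per epoch.
#' @param distinct_day_frac Probability that a pair has distinct
#'   days-to-anthesis values.
#' @param distinct_id_frac Probability that a pair joins different plants.
#' @param seed Integer seed; the draw is a pure function of (pool, seed).
#' @param exact_quotas If `TRUE`, enforce quotas as exact counts instead of
#'   independent Bernoulli draws.
#' @return A list of class `pair_sampler_config`.
#' @export
pair_sampler_config <- function(n_train = 24000, n_val = 6000,
                                distinct_day_frac = 0.80,
                                distinct_id_frac = 0.95,
                                seed = 1L, exact_quotas = FALSE) {
  abort_if(n_train <= 0 || n_val <= 0, "pair counts must be positive")
  abort_if(distinct_day_frac < 0 || distinct_day_frac > 1 ||
           distinct_id_frac < 0 || distinct_id_frac > 1,
           "quota fractions must lie in [0, 1]")
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 distinct_day_frac = distinct_day_frac,
                 distinct_id_frac = distinct_id_frac,
                 seed = as.integer(seed), exact_quotas = exact_quotas),
            class = "pair_sampler_config")
}

## The four constraint buckets, keyed by (same_day, same_id).
bucket_name <- function(same_day, same_id) {
  paste0(ifelse(same_day, "same-day", "distinct-day"), "/",
         ifelse(same_id, "same-id", "distinct-id"))
}

#' Sample labelled IWC pairs under day/identity quotas
#'
#' Each pair is drawn by first deciding same-day vs distinct-day (with
#' probability `1 - distinct_day_frac` vs `distinct_day_frac`) and same-id
#' vs distinct-id (`1 - distinct_id_frac` vs `distinct_id_frac`)
#' independently, then drawing the first member uniformly among IWCs with
#' at least one admissible partner and the second uniformly among its
#' admissible partners. Labels follow the selected scheme's rule.
#'
#' @param pool List of `iwc` objects, or a metadata `data.frame` with
#'   columns `plant_id` and `days_to_anthesis`.
#' @param n Number of pairs to draw.
#' @param config A [pair_sampler_config()].
#' @param scheme `"binary"` or `"ternary"`.
#' @param seed Seed overriding `config$seed` (used internally for the
#'   validation stream).
#' @return `data.frame` with columns `first`, `second` (pool indices),
#'   `label`, `same_day`, `same_id`.
#' @export
sample_pairs <- function(pool, n = config$n_train, config = pair_sampler_config(),
                         scheme = c("binary", "ternary"), seed = config$seed) {
  scheme <- match.arg(scheme)
  meta <- if (is.data.frame(pool)) pool else pool_metadata(pool)
  abort_if(nrow(meta) == 0, "empty pool")
  abort_if(anyNA(meta$days_to_anthesis),
           "pair sampling needs days_to_anthesis for every IWC")
  day <- meta$days_to_anthesis
  id <- as.character(meta$plant_id)
  N <- nrow(meta)

  by_day <- split(seq_len(N), day)
  by_id <- split(seq_len(N), id)
  by_both <- split(seq_len(N), paste(day, id, sep = "\r"))
  n_dp <- lengths(by_both)[paste(day, id, sep = "\r")]
  n_d <- lengths(by_day)[as.character(day)]
  n_p <- lengths(by_id)[id]
  ## Number of admissible partners of each IWC, per bucket.
  partners <- list(
    "TRUE.TRUE"   = n_dp - 1,
    "TRUE.FALSE"  = n_d - n_dp,
    "FALSE.TRUE"  = n_p - n_dp,
    "FALSE.FALSE" = N - n_d - n_p + n_dp
  )
  firsts <- lapply(partners, function(ct) which(ct > 0))

  p_same_day <- 1 - config$distinct_day_frac
  p_same_id <- 1 - config$distinct_id_frac
  prob_bucket <- c("TRUE.TRUE" = p_same_day * p_same_id,
                   "TRUE.FALSE" = p_same_day * (1 - p_same_id),
                   "FALSE.TRUE" = (1 - p_same_day) * p_same_id,
                   "FALSE.FALSE" = (1 - p_same_day) * (1 - p_same_id))
  for (b in names(prob_bucket)) {
    sd_si <- as.logical(strsplit(b, ".", fixed = TRUE)[[1]])
    abort_if(prob_bucket[[b]] > 0 && length(firsts[[b]]) == 0,
             "quota bucket ", bucket_name(sd_si[1], sd_si[2]),
             " is unsatisfiable in this pool")
  }

  withr::with_seed(seed, {
    if (config$exact_quotas) {
      counts <- round(n * prob_bucket)
      counts[which.max(counts)] <- counts[which.max(counts)] + (n - sum(counts))
      lab <- sample(rep(names(prob_bucket), counts))
    } else {
      same_day_draw <- stats::runif(n) < p_same_day
      same_id_draw <- stats::runif(n) < p_same_id
      lab <- paste(same_day_draw, same_id_draw, sep = ".")
    }
    first <- integer(n); second <- integer(n)
    for (k in seq_len(n)) {
      b <- lab[k]
      cand <- firsts[[b]]
      i <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
      want_day <- startsWith(b, "TRUE")
      want_id <- endsWith(b, "TRUE")
      set <- if (want_day && want_id) {
        by_both[[paste(day[i], id[i], sep = "\r")]]
      } else if (want_day) {
        by_day[[as.character(day[i])]]
      } else if (want_id) {
        by_id[[id[i]]]
      } else {
        NULL
      }
      if (is.null(set)) {
        ## distinct-day/distinct-id: rejection sampling against the whole pool
        repeat {
          j <- sample.int(N, 1)
          if (day[j] != day[i] && id[j] != id[i]) break
        }
      } else {
        ok <- set[set != i]
        if (want_day && !want_id) ok <- ok[id[ok] != id[i]]
        if (!want_day && want_id) ok <- ok[day[ok] != day[i]]
        j <- if (length(ok) == 1) ok else ok[sample.int(length(ok), 1)]
      }
      first[k] <- i; second[k] <- j
    }
  })

  label <- if (scheme == "binary") binary_pair_label(day[first], day[second])
           else ternary_pair_label(day[first], day[second])
  out <- data.frame(first = first, second = second, label = label,
                    same_day = day[first] == day[second],
                    same_id = id[first] == id[second])
  attr(out, "scheme") <- scheme
  out
}

#' Fixed train/validation epoch pair sets
#'
#' Draws `n_train` training and `n_val` validation pairs from disjoint
#' random streams (`seed` and `seed + 1`). The same fixed sets are reused
#' every epoch.
#'
#' @inheritParams sample_pairs
#' @return List with elements `train` and `val` (pair tables).
#' @export
split_epoch_sets <- function(pool, config = pair_sampler_config(),
                             scheme = c("binary", "ternary")) {
  scheme <- match.arg(scheme)
  list(
    train = sample_pairs(pool, config$n_train, config, scheme,
                         seed = config$seed),
    val = sample_pairs(pool, config$n_val, config, scheme,
                       seed = config$seed + 1L)
  )
}
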