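## Anchor construction, within-n-days prediction, and the ten-cycle
## one-/five-shot evaluation protocol with F1 scoring.

#' F1 score from confusion counts
#'
#' `2 TP / (2 TP + FP + FN)`, the harmonic mean of precision and recall.
#'
#' @param tp,fp,fn Non-negative true-positive, false-positive and
#'   false-negative counts.
#' @return F1 in `[0, 1]`; 0 with a warning when all counts are zero.
#' @export
f1_score <- function(tp, fp, fn) {
  abort_if(tp < 0 || fp < 0 || fn < 0, "counts must be non-negative")
  denom <- 2 * tp + fp + fn
  if (denom == 0) {
    warning("F1 undefined for an all-zero confusion table; returning 0")
    return(0)
  }
  2 * tp / denom
}

#' Feature matrix for a whole IWC pool
#'
#' Extracts the fused feature vector of every IWC under the model's EMA
#' parameters and stored normalisation statistics. Useful to precompute
#' once when running several evaluation protocols over the same pool.
#'
#' @param pool List of `iwc` objects.
#' @param model A trained `spikecast_model`.
#' @return Numeric matrix, one row per IWC, `out_dim` columns.
#' @export
pool_features <- function(pool, model) {
  tc <- build_tensor_cache(pool, model$ext_spec, model$stats)
  features_for_slots(seq_along(pool), tc, model$ema$extractor, model$ext_spec)
}

#' Build an anchor from a support set
#'
#' The anchor is the elementwise mean of the extracted feature vectors of
#' a small support set of plants that are exactly `n` days from anthesis;
#' it is the comparison reference for all queries at critical day `n`.
#'
#' @param support List of `iwc` objects, all with `days_to_anthesis == n`.
#' @param model A trained `spikecast_model` (from [train_meta()]).
#' @param n The critical day the support set represents; inferred from the
#'   support when `NULL`.
#' @return Object of class `anchor` with fields `vector`, `n`,
#'   `support_size`.
#' @export
build_anchor <- function(support, model, n = NULL) {
  abort_if(length(support) == 0, "empty support set")
  days <- vapply(support, function(x) as.integer(x$days_to_anthesis), integer(1))
  abort_if(length(unique(days)) != 1,
           "support set mixes critical days: ", paste(unique(days), collapse = ", "))
  n <- as.integer(n %||% days[1])
  abort_if(days[1] != n, "support days_to_anthesis (", days[1],
           ") do not match n = ", n)
  feats <- pool_features(support, model)
  structure(list(vector = colMeans(feats), n = n,
                 support_size = length(support)),
            class = "anchor")
}

#' @export
print.anchor <- function(x, ...) {
  cat("<anchor> critical day n =", x$n, "from", x$support_size,
      "support images\n")
  invisible(x)
}

#' Predict whether a query plant flowers within n days
#'
#' Feeds (query feature, anchor vector) as (first, second) into the
#' comparative head. Binary scheme: the positive class means the query's
#' days to anthesis is below the anchor's `n`, i.e. anthesis within `n`
#' days; negative means more than `n` days. By the comparator's tie rule
#' (equal days are negative) a query exactly at the boundary falls on the
#' "not within" side. Ternary scheme: classes map to after / within one
#' day of / before the critical date.
#'
#' @param query An `iwc` (its `days_to_anthesis` may be `NA`).
#' @param anchor An [build_anchor()] result.
#' @param model A trained `spikecast_model`.
#' @return List with `decision` (`"within_n"`/`"beyond_n"` for binary;
#'   `"before"`/`"within_1day"`/`"after"` for ternary), `class`, `logits`.
#' @export
predict_within_n <- function(query, anchor, model) {
  qf <- extract_features(query, model$ema$extractor, model$ext_spec,
                         stats = model$stats)
  logits <- head_fwd(model$ema$head, model$head_spec, rbind(qf),
                     rbind(anchor$vector), keep_cache = FALSE)$logits[1, ]
  k <- which.max(logits)
  if (model$head_spec$n_classes == 2L) {
    cls <- PAIR_LEVELS$binary[k]
    decision <- if (cls == "positive") "within_n" else "beyond_n"
  } else {
    cls <- PAIR_LEVELS$ternary[k]
    decision <- c(negative = "after", neutral = "within_1day",
                  positive = "before")[[cls]]
  }
  list(decision = decision, class = cls, logits = as.numeric(logits))
}

#' Ten-cycle one-/five-shot evaluation protocol
#'
#' For each cycle, a fresh set of support plants (and their images) and a
#' disjoint query set are sampled; the same plant selection is reused
#' across all critical days within a cycle. Per critical day `n`, an
#' anchor is built from the support images at exactly `n` days to
#' anthesis and every query observation is classified against it; query
#' plants are scored per observation day by majority vote over that day's
#' images. Ground truth for the binary task is `days_to_anthesis <= n`
#' (`boundary = "inclusive"`, the default) or `< n` (`"strict"`).
#'
#' @param model A trained `spikecast_model`.
#' @param pool List of `iwc` objects to draw queries from.
#' @param critical_days Integer critical days (default 8, 10, 12, 14, 16).
#' @param shots Support plants per anchor (1 or 5).
#' @param cycles Number of evaluation cycles (default 10).
#' @param seed Base seed; cycle `c` uses `seed + c`.
#' @param images_per_support Images used per support plant (default 8, so
#'   a five-shot anchor uses up to 40 photos).
#' @param queries_per_plant Observation days sampled per query plant per
#'   cycle.
#' @param boundary Ground-truth rule at the exact boundary.
#' @param aggregate `"majority"` pools a plant-day's images by majority
#'   vote (ties fall to "not within", matching the comparator's tie rule);
#'   `"per_image"` scores each image separately.
#' @param anchor_pool Optional separate pool supplying the support sets
#'   (anchor transfer); defaults to `pool`.
#' @param features,anchor_features Optional precomputed [pool_features()]
#'   matrices for `pool` and `anchor_pool`, to avoid re-extracting when
#'   several protocols run over the same pools.
#' @return Object of class `cycle_report`: `per_cycle` (day, cycle,
#'   confusion counts, F1), `summary` (mean F1 per day over cycles), and
#'   the protocol settings.
#' @export
run_protocol <- function(model, pool, critical_days = c(8L, 10L, 12L, 14L, 16L),
                         shots = 5L, cycles = 10L, seed = 1L,
                         images_per_support = 8L, queries_per_plant = 5L,
                         boundary = c("inclusive", "strict"),
                         aggregate = c("majority", "per_image"),
                         anchor_pool = NULL, features = NULL,
                         anchor_features = NULL) {
  boundary <- match.arg(boundary)
  aggregate <- match.arg(aggregate)
  abort_if(!shots %in% c(1L, 5L), "shots must be 1 or 5")
  transfer <- !is.null(anchor_pool)
  anchor_pool <- anchor_pool %||% pool

  qmeta <- pool_metadata(pool)
  ameta <- pool_metadata(anchor_pool)
  abort_if(anyNA(qmeta$days_to_anthesis) || anyNA(ameta$days_to_anthesis),
           "protocol pools need days_to_anthesis for every IWC")

  ## plants eligible to anchor: observed at every critical day
  has_day <- table(ameta$plant_id, ameta$days_to_anthesis)
  need <- intersect(as.character(critical_days), colnames(has_day))
  abort_if(length(need) < length(critical_days),
           "anchor pool has no observations at day(s) ",
           paste(setdiff(as.character(critical_days), colnames(has_day)),
                 collapse = ", "), " (support bucket)")
  eligible <- rownames(has_day)[rowSums(has_day[, need, drop = FALSE] > 0) ==
                                  length(need)]
  abort_if(length(eligible) < shots,
           "only ", length(eligible), " plant(s) observed at all critical ",
           "days; ", shots, " needed (support bucket)")

  for (n in critical_days) {
    abort_if(!any(qmeta$days_to_anthesis <= n),
             "no queries on the within side for n = ", n, " (query bucket)")
    abort_if(!any(qmeta$days_to_anthesis > n),
             "no queries on the beyond side for n = ", n, " (query bucket)")
  }

  qfeat <- features %||% pool_features(pool, model)
  abort_if(nrow(qfeat) != length(pool), "features do not match the pool")
  afeat <- if (transfer) {
    anchor_features %||% pool_features(anchor_pool, model)
  } else qfeat

  qplants <- unique(qmeta$plant_id)
  res <- NULL
  for (cyc in seq_len(cycles)) {
    withr::with_seed(seed + cyc, {
      sup_plants <- sample(eligible, shots)
      ## queries never include support plants (no leakage within a cycle)
      cyc_queries <- setdiff(qplants, sup_plants)
      qsel <- NULL
      for (p in cyc_queries) {
        obs <- which(qmeta$plant_id == p)
        dates <- unique(qmeta$capture_date[obs])
        pick <- if (length(dates) > queries_per_plant) {
          sample(dates, queries_per_plant)
        } else dates
        qsel <- rbind(qsel, data.frame(plant = p, date = pick))
      }
      ## flatten the cycle's query observations once: image indices with
      ## their (plant, date) group and true days-to-anthesis
      gidx <- integer(0); grp <- integer(0); qdays <- integer(0)
      for (r in seq_len(nrow(qsel))) {
        img_idx <- which(qmeta$plant_id == qsel$plant[r] &
                           qmeta$capture_date == qsel$date[r])
        gidx <- c(gidx, img_idx)
        grp <- c(grp, rep(r, length(img_idx)))
        qdays[r] <- qmeta$days_to_anthesis[img_idx[1]]
      }
      V1 <- qfeat[gidx, , drop = FALSE]
      pos_level <- match("positive", PAIR_LEVELS[[
        if (model$head_spec$n_classes == 2L) "binary" else "ternary"]])
      for (n in critical_days) {
        sup_idx <- integer(0)
        for (p in sup_plants) {
          cand <- which(ameta$plant_id == p & ameta$days_to_anthesis == n)
          if (length(cand) > images_per_support) {
            cand <- sample(cand, images_per_support)
          }
          sup_idx <- c(sup_idx, cand)
        }
        anchor_vec <- colMeans(afeat[sup_idx, , drop = FALSE])
        V2 <- matrix(anchor_vec, nrow(V1), length(anchor_vec), byrow = TRUE)
        logits <- head_fwd(model$ema$head, model$head_spec, V1, V2,
                           keep_cache = FALSE)$logits
        pos <- max.col(logits, ties.method = "first") == pos_level
        truth_row <- if (boundary == "inclusive") qdays <= n else qdays < n
        if (aggregate == "majority") {
          dec_row <- tapply(pos, grp, mean) > 0.5   # ties fall to negative
          dec <- as.logical(dec_row); truth <- truth_row
        } else {
          dec <- pos; truth <- truth_row[grp]
        }
        tp <- sum(dec & truth); fp <- sum(dec & !truth)
        fn <- sum(!dec & truth); tn <- sum(!dec & !truth)
        res <- rbind(res, data.frame(day = n, cycle = cyc, tp = tp, fp = fp,
                                     fn = fn, tn = tn,
                                     f1 = f1_score(tp, fp, fn)))
      }
    })
  }
  summary <- stats::aggregate(f1 ~ day, data = res, FUN = mean)
  names(summary)[2] <- "mean_f1"
  structure(list(per_cycle = res, summary = summary,
                 settings = list(critical_days = critical_days, shots = shots,
                                 cycles = cycles, seed = seed,
                                 images_per_support = images_per_support,
                                 queries_per_plant = queries_per_plant,
                                 boundary = boundary, aggregate = aggregate,
                                 anchor_transfer = transfer)),
            class = "cycle_report")
}

#' @export
print.cycle_report <- function(x, ...) {
  s <- x$settings
  cat("<cycle_report> ", s$shots, "-shot, ", s$cycles, " cycles",
      if (s$anchor_transfer) ", transferred anchors" else "", "\n", sep = "")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  day %2d: mean F1 %.3f\n", x$summary$day[i],
                x$summary$mean_f1[i]))
  }
  cat(sprintf("  overall mean F1: %.3f\n", mean(x$summary$mean_f1)))
  invisible(x)
}
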