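## Meta-learning trainer: Adam with cosine-annealed learning rate, EMA of
## the parameters, label smoothing, and early stopping on validation F1.

#' Training configuration
#'
#' @param epochs_max Maximum epochs.
#' @param batch_size Pairs per optimisation step.
#' @param lr_max,lr_min Cosine-annealing endpoints.
#' @param label_smooth_eps Label-smoothing mass spread over wrong classes.
#' @param ema_decay Exponential-moving-average decay for the shadow
#'   parameters used at validation and inference.
#' @param patience Epochs without validation-F1 improvement before
#'   stopping.
#' @param seed Seed controlling initialisation and batch order.
#' @param scheme Pair-labelling scheme, `"binary"` or `"ternary"`.
#' @param weight_decay Decoupled weight decay (off by default).
#' @param amsgrad Use the AMSGrad second-moment maximum (off by default).
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs_max = 50L, batch_size = 32L,
                         lr_max = 1e-4, lr_min = 1e-6,
                         label_smooth_eps = 0.1, ema_decay = 0.999,
                         patience = 5L, seed = 1L,
                         scheme = c("binary", "ternary"),
                         weight_decay = 0, amsgrad = FALSE) {
  scheme <- match.arg(scheme)
  abort_if(label_smooth_eps < 0 || label_smooth_eps >= 1,
           "label_smooth_eps must be in [0, 1)")
  abort_if(ema_decay < 0 || ema_decay > 1, "ema_decay must be in [0, 1]")
  abort_if(patience < 1, "patience must be >= 1")
  abort_if(lr_min > lr_max, "lr_min must not exceed lr_max")
  structure(list(epochs_max = as.integer(epochs_max),
                 batch_size = as.integer(batch_size),
                 lr_max = lr_max, lr_min = lr_min,
                 label_smooth_eps = label_smooth_eps,
                 ema_decay = ema_decay, patience = as.integer(patience),
                 seed = as.integer(seed), scheme = scheme,
                 weight_decay = weight_decay, amsgrad = isTRUE(amsgrad)),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr_min + 0.5 (lr_max - lr_min)(1 + cos(pi t / T))`: starts at `lr_max`
#' (t = 0) and decays to `lr_min` (t = T).
#'
#' @param t Current step, `0 <= t <= T`.
#' @param T Total steps, `>= 1`.
#' @param lr_max,lr_min Schedule endpoints.
#' @return Learning rate at step `t`.
#' @export
cosine_lr <- function(t, T, lr_max, lr_min) {
  abort_if(T < 1, "T must be >= 1")
  abort_if(any(t < 0) || any(t > T), "t must lie in [0, T]")
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * t / T))
}

#' Exponential moving average of parameters
#'
#' `ema <- decay * ema + (1 - decay) * current`, elementwise over a
#' parameter tree.
#'
#' @param ema_params,current_params Shape-matched parameter trees.
#' @param decay Decay in `[0, 1]`; 0 copies current, 1 freezes the EMA.
#' @return Updated EMA tree.
#' @export
ema_update <- function(ema_params, current_params, decay) {
  abort_if(decay < 0 || decay > 1, "decay must be in [0, 1]")
  map2_params(ema_params, current_params,
              function(e, c) decay * e + (1 - decay) * c)
}

#' Label-smoothed cross-entropy
#'
#' Cross-entropy against a target putting `1 - eps` on the true class and
#' `eps / (n_classes - 1)` on each other class. `eps = 0` is standard
#' cross-entropy.
#'
#' @param scores Logit matrix (rows = samples) or a single logit vector.
#' @param true_class Integer class index (1-based), vectorised.
#' @param eps Smoothing mass in `[0, 1)`.
#' @param n_classes Number of classes.
#' @return Mean loss (scalar).
#' @export
smoothed_cross_entropy <- function(scores, true_class, eps = 0.1,
                                   n_classes = ncol(scores)) {
  if (is.null(dim(scores))) scores <- rbind(scores)
  abort_if(eps < 0 || eps >= 1, "eps must be in [0, 1)")
  abort_if(any(true_class < 1) || any(true_class > n_classes),
           "invalid class index")
  xent_smoothed(scores, as.integer(true_class), eps)$loss
}

## loss + gradient wrt logits (mean over the batch)
xent_smoothed <- function(logits, y, eps) {
  B <- nrow(logits); K <- ncol(logits)
  m <- apply(logits, 1, max)
  z <- logits - m
  lse <- log(rowSums(exp(z)))
  logp <- z - lse
  target <- matrix(eps / (K - 1), B, K)
  target[cbind(seq_len(B), y)] <- 1 - eps
  loss <- -sum(target * logp) / B
  p <- exp(logp)
  list(loss = loss, dlogits = (p - target) / B)
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params),
       vmax = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0, amsgrad = FALSE) {
  state$t <- state$t + 1L
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  vv <- state$v
  if (amsgrad) {
    state$vmax <- map2_params(state$vmax, state$v, pmax)
    vv <- state$vmax
  }
  upd <- map2_params(state$m, vv, function(m, v) {
    (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- map2_params(params, upd, function(p, u) p - lr * u)
  if (weight_decay > 0) {
    params <- map_params(params, function(p) p - lr * weight_decay * p)
  }
  list(params = params, state = state)
}

## ---- tensor cache ----------------------------------------------------------

## Pre-assembles the standardised image array, the normalised unique
## weather windows, and label/window indices for a pool, so batches are
## plain array slices.
build_tensor_cache <- function(pool, ext_spec, stats) {
  meta <- pool_metadata(pool)
  N <- nrow(meta)
  X <- array(0, c(N, ext_spec$image_size, ext_spec$image_size,
                  ext_spec$in_channels))
  for (i in seq_len(N)) X[i, , , 1] <- standardize_image(pool[[i]]$image, ext_spec)
  keys <- meta$window_key
  ukeys <- unique(keys)
  first_of <- match(ukeys, keys)
  T <- nrow(pool[[1]]$weather)
  W <- array(0, c(length(ukeys), T, ext_spec$window_cols))
  for (u in seq_along(ukeys)) {
    W[u, , ] <- normalize_window(pool[[first_of[u]]]$weather, stats)
  }
  if (ext_spec$weather_zeroed) W[] <- 0
  list(X = X, W = W, win_of = match(keys, ukeys), meta = meta)
}

## forward a set of pool slots through the extractor (no caches kept)
features_for_slots <- function(slots, tc, params, ext_spec, chunk = 256L) {
  out <- NULL
  for (start in seq(1L, length(slots), by = chunk)) {
    sl <- slots[start:min(start + chunk - 1L, length(slots))]
    keys <- tc$win_of[sl]
    u <- unique(keys)
    fw <- extractor_fwd(params, ext_spec,
                        tc$X[sl, , , , drop = FALSE],
                        tc$W[u, , , drop = FALSE],
                        match(keys, u), keep_cache = FALSE)
    out <- rbind(out, fw$feat)
  }
  out
}

pair_f1 <- function(pred, truth, scheme) {
  if (scheme == "binary") {
    f1_score(sum(pred == 2 & truth == 2), sum(pred == 2 & truth != 2),
             sum(pred != 2 & truth == 2))
  } else {
    mean(vapply(1:3, function(k) {
      f1_score(sum(pred == k & truth == k), sum(pred == k & truth != k),
               sum(pred != k & truth == k))
    }, numeric(1)))
  }
}

eval_pairs <- function(pairs, tc, params, head_params, ext_spec, head_spec,
                       eps) {
  B <- nrow(pairs)
  y <- as.integer(pairs$label)
  preds <- integer(B); loss_sum <- 0
  for (start in seq(1L, B, by = 128L)) {
    ix <- start:min(start + 127L, B)
    slots <- c(pairs$first[ix], pairs$second[ix])
    feat <- features_for_slots(slots, tc, params, ext_spec)
    nb <- length(ix)
    V1 <- feat[seq_len(nb), , drop = FALSE]
    V2 <- feat[nb + seq_len(nb), , drop = FALSE]
    logits <- head_fwd(head_params, head_spec, V1, V2, keep_cache = FALSE)$logits
    preds[ix] <- max.col(logits, ties.method = "first")
    loss_sum <- loss_sum + xent_smoothed(logits, y[ix], eps)$loss * nb
  }
  list(f1 = pair_f1(preds, y, attr(pairs, "scheme") %||%
                      if (head_spec$n_classes == 2L) "binary" else "ternary"),
       loss = loss_sum / B)
}

## ---- the training loop -----------------------------------------------------

#' Train the Siamese comparator by meta-learning on IWC pairs
#'
#' Iterates over fixed train/validation pair sets, optimising the shared
#' feature extractor and the comparative head jointly with Adam under a
#' cosine learning-rate schedule, maintaining an EMA copy of all
#' parameters. After each epoch the EMA parameters are scored on the
#' validation pairs (F1 of the positive class, macro-F1 for ternary);
#' training stops when that score fails to improve for `patience` epochs
#' or at `epochs_max`. Fully reproducible given (pool, pairs, config).
#'
#' @param pool List of `iwc` objects the pair tables index into.
#' @param pairs List with `train` and `val` pair tables
#'   (from [split_epoch_sets()]).
#' @param config A [train_config()].
#' @param ext_spec An [extractor_spec()].
#' @param head_spec A [comparative_spec()]; its `n_classes` must match the
#'   labelling scheme.
#' @param stats Window normalisation statistics; computed from the pool
#'   (the training split) when `NULL`.
#' @return List of class `spikecast_model`: `params`, `ema` (parameter
#'   trees with `extractor` and `head`), `ext_spec`, `head_spec`, `stats`,
#'   and `report` (per-epoch log, best epoch, stopping reason).
#' @export
train_meta <- function(pool, pairs, config = train_config(),
                       ext_spec = extractor_spec(),
                       head_spec = comparative_spec(
                         n_classes = if (config$scheme == "binary") 2L else 3L),
                       stats = NULL) {
  n_classes <- if (config$scheme == "binary") 2L else 3L
  abort_if(head_spec$n_classes != n_classes,
           "head has ", head_spec$n_classes, " classes but scheme ",
           config$scheme, " needs ", n_classes)
  abort_if(nrow(pairs$train) == 0 || nrow(pairs$val) == 0,
           "empty pair sets")
  stats <- stats %||% window_stats(lapply(pool, function(x) x$weather))
  tc <- build_tensor_cache(pool, ext_spec, stats)

  params <- list(extractor = init_extractor(ext_spec, seed = config$seed),
                 head = init_comparative(head_spec, seed = config$seed + 1L))
  ema <- params
  epoch_log <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric(), val_f1 = numeric())
  model <- function(reason) {
    structure(list(params = best_params, ema = best_ema,
                   ext_spec = ext_spec, head_spec = head_spec, stats = stats,
                   report = list(log = epoch_log, best_epoch = best_epoch,
                                 best_val_f1 = best_f1,
                                 stopping_reason = reason)),
              class = "spikecast_model")
  }
  best_params <- params; best_ema <- ema
  best_f1 <- -Inf; best_epoch <- 0L; bad_epochs <- 0L
  if (config$epochs_max == 0L) return(model("epochs_max reached"))

  y_train <- as.integer(pairs$train$label)
  n_pairs <- nrow(pairs$train)
  nbatch <- max(1L, n_pairs %/% config$batch_size)
  steps_total <- config$epochs_max * nbatch
  opt <- adam_init(params)
  step <- 0L
  reason <- "epochs_max reached"

  withr::with_seed(config$seed + 2L, {
    for (epoch in seq_len(config$epochs_max)) {
      ord <- sample.int(n_pairs)
      loss_sum <- 0
      for (bidx in seq_len(nbatch)) {
        take <- ord[((bidx - 1L) * config$batch_size + 1L):
                      min(bidx * config$batch_size, n_pairs)]
        nb <- length(take)
        slots <- c(pairs$train$first[take], pairs$train$second[take])
        keys <- tc$win_of[slots]
        u <- unique(keys)
        fw <- extractor_fwd(params$extractor, ext_spec,
                            tc$X[slots, , , , drop = FALSE],
                            tc$W[u, , , drop = FALSE], match(keys, u))
        V1 <- fw$feat[seq_len(nb), , drop = FALSE]
        V2 <- fw$feat[nb + seq_len(nb), , drop = FALSE]
        hf <- head_fwd(params$head, head_spec, V1, V2)
        ls <- xent_smoothed(hf$logits, y_train[take], config$label_smooth_eps)
        abort_if(!is.finite(ls$loss),
                 "training diverged: non-finite loss at epoch ", epoch,
                 ", step ", bidx)
        loss_sum <- loss_sum + ls$loss * nb
        hb <- head_bwd(ls$dlogits, params$head, head_spec, hf$cache)
        eg <- extractor_bwd(rbind(hb$dV1, hb$dV2), params$extractor,
                            ext_spec, fw)
        lr <- cosine_lr(step, steps_total, config$lr_max, config$lr_min)
        st <- adam_step(params, list(extractor = eg, head = hb$grads), opt,
                        lr, weight_decay = config$weight_decay,
                        amsgrad = config$amsgrad)
        params <- st$params; opt <- st$state
        ema <- ema_update(ema, params, config$ema_decay)
        step <- step + 1L
      }
      ev <- eval_pairs(pairs$val, tc, ema$extractor, ema$head, ext_spec,
                       head_spec, config$label_smooth_eps)
      epoch_log <- rbind(epoch_log, data.frame(
        epoch = epoch, train_loss = loss_sum / n_pairs,
        val_loss = ev$loss, val_f1 = ev$f1))
      if (ev$f1 > best_f1) {
        best_f1 <- ev$f1; best_epoch <- epoch
        best_params <- params; best_ema <- ema
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= config$patience) {
          reason <- paste0("early stopping: no val-F1 improvement for ",
                           config$patience, " epoch(s)")
          break
        }
      }
    }
  })
  model(reason)
}

#' @export
print.spikecast_model <- function(x, ...) {
  r <- x$report
  cat("<spikecast_model> ", x$ext_spec$backbone_name, " + ",
      x$head_spec$head_type, " head (", x$head_spec$n_classes, " classes)\n",
      "  epochs run: ", nrow(r$log), ", best epoch: ", r$best_epoch,
      " (val F1 ", sprintf("%.3f", r$best_val_f1), ")\n",
      "  stopping: ", r$stopping_reason, "\n", sep = "")
  invisible(x)
}
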