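# Trainer components and the meta-learning loop on a small separable
# fixture.

test_that("cosine schedule hits its endpoints and midpoint", {
  expect_equal(cosine_lr(0, 100, 1e-3, 1e-6), 1e-3)
  expect_equal(cosine_lr(100, 100, 1e-3, 1e-6), 1e-6)
  expect_equal(cosine_lr(50, 100, 1e-3, 1e-6), (1e-3 + 1e-6) / 2)
  # monotone decay in between
  lrs <- cosine_lr(0:20, 20, 1e-3, 1e-5)
  expect_true(all(diff(lrs) < 0))
  expect_error(cosine_lr(11, 10, 1e-3, 1e-6), "\\[0, T\\]")
})

test_that("EMA updates follow the decay rule over parameter trees", {
  a <- list(x = matrix(0, 2, 2), y = list(z = rep(0, 3)))
  b <- list(x = matrix(2, 2, 2), y = list(z = rep(2, 3)))
  expect_equal(ema_update(a, b, 0), b)                   # copies current
  expect_equal(ema_update(a, b, 1), a)                   # frozen
  half <- ema_update(a, b, 0.5)
  expect_equal(half$x, matrix(1, 2, 2))
  expect_equal(half$y$z, rep(1, 3))
  bad <- list(x = matrix(0, 3, 3), y = list(z = rep(0, 3)))
  expect_error(ema_update(a, bad, 0.5), "mismatch")
})

test_that("label smoothing reduces to cross-entropy and is normalised", {
  withr::with_seed(41, logits <- matrix(rnorm(12), 4, 3))
  y <- c(1L, 3L, 2L, 1L)
  # eps = 0: standard cross-entropy
  p <- exp(logits) / rowSums(exp(logits))
  expect_equal(smoothed_cross_entropy(logits, y, eps = 0),
               -mean(log(p[cbind(1:4, y)])))
  # uniform predictive distribution: loss = log(K) for any eps
  for (eps in c(0, 0.1, 0.4)) {
    expect_equal(smoothed_cross_entropy(matrix(0, 5, 3), rep(2L, 5), eps),
                 log(3))
  }
  # loss is bounded below by the entropy of the smoothed target
  eps <- 0.2
  target <- c(1 - eps, eps / 2, eps / 2)
  entropy <- -sum(target * log(target))
  withr::with_seed(42, {
    for (i in 1:20) {
      lg <- matrix(rnorm(3, sd = 3), 1, 3)
      expect_gte(smoothed_cross_entropy(lg, 1L, eps), entropy - 1e-12)
    }
  })
  expect_error(smoothed_cross_entropy(logits, 5L, 0.1), "class index")
})

test_that("one Adam/EMA step matches hand arithmetic", {
  ns <- asNamespace("spikecast")
  params <- list(w = c(1, 2))
  grads <- list(w = c(0.5, -0.5))
  st <- ns$adam_init(params)
  out <- ns$adam_step(params, grads, st, lr = 0.1)
  # first step of Adam moves each coordinate by ~lr * sign(g)
  expect_equal(out$params$w, c(1, 2) - 0.1 * c(1, -1), tolerance = 1e-6)
  expect_equal(ema_update(list(w = 0), list(w = 2), 0.5)$w, 1)
})

separable_fixture <- function() {
  # pairs whose label is determined by one weather feature: the CPDD
  # column encodes days-to-anthesis linearly; images are pure noise
  withr::with_seed(51, {
    pool <- list()
    anth <- as.Date("2023-09-20")
    for (d in 2:9) {
      win <- matrix(rnorm(5 * 6, sd = 0.1), 5, 6)
      win[, 6] <- 100 - 10 * d
      for (p in 1:6) {
        pool[[length(pool) + 1]] <- iwc(
          image = matrix(runif(64), 8, 8), weather = win,
          plant_id = sprintf("P%02d", p), capture_date = anth - d,
          days_to_anthesis = d)
      }
    }
  })
  # same-day/same-id bucket needs two images of one plant on one day
  c(pool, pool)
}

separable_spec <- function() {
  extractor_spec(image_size = 8L, backbone_out_dim = 16L,
                 image_proj_dim = 8L, weather_hidden_dim = 8L,
                 out_dim = 8L, fusion_hidden_dim = 8L)
}

test_that("meta-training learns a weather-separable fixture", {
  pool <- separable_fixture()
  sampler <- pair_sampler_config(n_train = 300, n_val = 120, seed = 52)
  pairs <- split_epoch_sets(pool, sampler, "binary")
  cfg <- train_config(epochs_max = 10, batch_size = 20, lr_max = 1e-2,
                      lr_min = 1e-4, patience = 10, seed = 53,
                      ema_decay = 0.8)
  spec <- separable_spec()
  hspec <- comparative_spec("fc", in_dim = 2L * spec$out_dim, n_classes = 2)
  m <- train_meta(pool, pairs, cfg, ext_spec = spec, head_spec = hspec)
  expect_s3_class(m, "spikecast_model")
  expect_gte(m$report$best_val_f1, 0.95)
  expect_lte(m$report$best_epoch, 10)
})

test_that("EMA suppresses the noise of fluctuating parameter iterates", {
  # stabilisation direction: for parameter iterates that bounce around an
  # optimum (as minibatch SGD iterates do), the EMA shadow stays closer
  # to the optimum than the raw iterates on average
  withr::with_seed(71, {
    target <- list(w = matrix(c(1, -2, 0.5, 3), 2, 2))
    ema <- list(w = target$w)
    dev_raw <- dev_ema <- numeric(200)
    for (t in 1:200) {
      current <- list(w = target$w + matrix(rnorm(4, sd = 0.3), 2, 2))
      ema <- ema_update(ema, current, 0.95)
      dev_raw[t] <- sqrt(mean((current$w - target$w)^2))
      dev_ema[t] <- sqrt(mean((ema$w - target$w)^2))
    }
  })
  expect_lt(mean(dev_ema[51:200]), 0.5 * mean(dev_raw[51:200]))
})

test_that("training bookkeeping: zero epochs, reproducibility, stopping", {
  pool <- fixture_iwc_pool()
  sampler <- pair_sampler_config(n_train = 40, n_val = 20, seed = 61)
  pairs <- split_epoch_sets(pool, sampler, "binary")
  spec <- tiny_ext_spec()
  hspec <- comparative_spec("fc", in_dim = 2L * spec$out_dim, n_classes = 2)

  # epochs_max = 0: initial parameters, empty log
  cfg0 <- train_config(epochs_max = 0, seed = 62)
  m0 <- train_meta(pool, pairs, cfg0, ext_spec = spec, head_spec = hspec)
  expect_equal(nrow(m0$report$log), 0)
  expect_equal(m0$params$extractor, init_extractor(spec, seed = 62))

  # frozen learning rate (lr = 0) with patience 1 stops after exactly 2
  # epochs: the first sets the best score, the second cannot improve it
  cfg1 <- train_config(epochs_max = 10, batch_size = 20, lr_max = 0,
                       lr_min = 0, patience = 1, seed = 63)
  m1 <- train_meta(pool, pairs, cfg1, ext_spec = spec, head_spec = hspec)
  expect_equal(nrow(m1$report$log), 2)
  expect_match(m1$report$stopping_reason, "early stopping")

  # same seed + same pairs: bit-identical report and parameters
  cfg2 <- train_config(epochs_max = 2, batch_size = 20, lr_max = 1e-3,
                       patience = 5, seed = 64)
  ma <- train_meta(pool, pairs, cfg2, ext_spec = spec, head_spec = hspec)
  mb <- train_meta(pool, pairs, cfg2, ext_spec = spec, head_spec = hspec)
  expect_identical(ma$report$log, mb$report$log)
  expect_identical(ma$ema, mb$ema)
  # the head/scheme consistency contract
  h3 <- comparative_spec("fc", in_dim = 2L * spec$out_dim, n_classes = 3)
  expect_error(train_meta(pool, pairs, cfg2, ext_spec = spec,
                          head_spec = h3), "classes")
})
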