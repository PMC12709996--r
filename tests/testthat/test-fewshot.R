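# Anchors, the F1 oracle, and the ten-cycle protocol bookkeeping. These
# tests use an untrained tiny model: the protocol's sampling, leakage and
# determinism properties do not depend on predictive skill.

tiny_model <- function(pool, seed = 1) {
  spec <- tiny_ext_spec()
  hspec <- comparative_spec("fc", in_dim = 2L * spec$out_dim, n_classes = 2)
  params <- list(extractor = init_extractor(spec, seed),
                 head = init_comparative(hspec, seed + 1L))
  structure(list(params = params, ema = params, ext_spec = spec,
                 head_spec = hspec,
                 stats = window_stats(lapply(pool, function(x) x$weather))),
            class = "spikecast_model")
}

test_that("F1 matches the harmonic-mean formula on random tables", {
  expect_equal(f1_score(7, 0, 0), 1)
  expect_equal(f1_score(0, 3, 2), 0)
  expect_equal(f1_score(2, 1, 1), 2 / 3, tolerance = 1e-4)
  expect_warning(z <- f1_score(0, 0, 0), "undefined")
  expect_equal(z, 0)
  expect_error(f1_score(-1, 0, 0), "non-negative")
  # equals 2PR/(P+R) from precision and recall on 1000 random tables
  withr::with_seed(81, {
    for (i in 1:1000) {
      tp <- sample(1:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
      p <- tp / (tp + fp); r <- tp / (tp + fn)
      expect_equal(f1_score(tp, fp, fn), 2 * p * r / (p + r))
    }
  })
})

test_that("anchors are permutation-invariant means of support features", {
  pool <- fixture_iwc_pool(n_plants = 4, days = c(6, 8), per_day = 3)
  model <- tiny_model(pool)
  meta <- pool_metadata(pool)
  support <- pool[meta$days_to_anthesis == 8][1:6]
  a <- build_anchor(support, model)
  expect_s3_class(a, "anchor")
  expect_equal(a$n, 8L)
  expect_equal(a$support_size, 6L)
  # mean identity: support of one IWC replicated gives that IWC's feature
  one <- build_anchor(support[c(1, 1, 1)], model)
  fv <- extract_features(support[[1]], model$ema$extractor, model$ext_spec,
                         stats = model$stats)
  expect_equal(one$vector, fv, tolerance = 1e-12)
  # permutation invariance
  b <- build_anchor(rev(support), model)
  expect_equal(a$vector, b$vector, tolerance = 1e-12)
  # two-vector arithmetic oracle
  two <- build_anchor(support[1:2], model)
  f2 <- extract_features(support[[2]], model$ema$extractor, model$ext_spec,
                         stats = model$stats)
  expect_equal(two$vector, (fv + f2) / 2, tolerance = 1e-12)
  # linearity: anchor of concatenated supports is the size-weighted mean
  s1 <- support[1:2]; s2 <- support[3:6]
  a1 <- build_anchor(s1, model); a2 <- build_anchor(s2, model)
  all6 <- build_anchor(c(s1, s2), model)
  expect_equal(all6$vector, (2 * a1$vector + 4 * a2$vector) / 6,
               tolerance = 1e-12)
  expect_error(build_anchor(list(), model), "empty")
  expect_error(build_anchor(pool[c(1, length(pool))], model), "mixes")
})

test_that("predict_within_n returns a decision for both schemes", {
  pool <- fixture_iwc_pool(n_plants = 4, days = c(4, 8), per_day = 2)
  model <- tiny_model(pool)
  meta <- pool_metadata(pool)
  anchor <- build_anchor(pool[meta$days_to_anthesis == 8], model)
  out <- predict_within_n(pool[[1]], anchor, model)
  expect_true(out$decision %in% c("within_n", "beyond_n"))
  expect_length(out$logits, 2)
})

test_that("the protocol is deterministic, leak-free and sized correctly", {
  pool <- fixture_iwc_pool(n_plants = 10, days = 2:9, per_day = 2)
  model <- tiny_model(pool)
  days <- c(4L, 6L, 8L)
  r1 <- run_protocol(model, pool, critical_days = days, shots = 5,
                     cycles = 3, seed = 5, queries_per_plant = 3)
  r2 <- run_protocol(model, pool, critical_days = days, shots = 5,
                     cycles = 3, seed = 5, queries_per_plant = 3)
  expect_identical(r1$per_cycle, r2$per_cycle)     # same seed, same report
  expect_equal(nrow(r1$per_cycle), 3 * length(days))
  expect_equal(sort(unique(r1$per_cycle$day)), days)
  expect_true(all(r1$per_cycle$f1 >= 0 & r1$per_cycle$f1 <= 1))
  expect_equal(nrow(r1$summary), length(days))
  # every query decision is counted: confusion cells sum to the number of
  # scored plant-days, constant across critical days within a cycle
  tot <- with(r1$per_cycle, tp + fp + fn + tn)
  expect_true(all(tapply(tot, r1$per_cycle$cycle, function(x) {
    length(unique(x)) == 1
  })))
  # a different seed draws different supports
  r3 <- run_protocol(model, pool, critical_days = days, shots = 5,
                     cycles = 3, seed = 99, queries_per_plant = 3)
  expect_false(identical(r1$per_cycle, r3$per_cycle))
})

test_that("the protocol fails loudly when a bucket cannot be filled", {
  pool <- fixture_iwc_pool(n_plants = 3, days = 2:9, per_day = 2)
  model <- tiny_model(pool)
  expect_error(run_protocol(model, pool, critical_days = c(4L, 6L),
                            shots = 5, cycles = 2, seed = 1),
               "support bucket")
  # a critical day nobody was observed at
  expect_error(run_protocol(model, pool, critical_days = c(4L, 20L),
                            shots = 1, cycles = 2, seed = 1),
               "day")
})

test_that("an oracle comparator drives protocol F1 to 1", {
  # replace the trained head by an oracle that reads the planted image
  # signal (mean of the image corner encodes days/10) so the protocol's
  # plumbing, not the model, is what is under test
  pool <- fixture_iwc_pool(n_plants = 8, days = 2:9, per_day = 2)
  spec <- extractor_spec(backbone_name = "custom", image_size = 8L,
                         backbone_out_dim = 4L, image_proj_dim = 4L,
                         weather_hidden_dim = 4L, out_dim = 4L,
                         fusion_hidden_dim = 2L,
                         custom_backbone = function(img) {
                           # the fixture plants days/10 in the image corner;
                           # +10 keeps the signal on the ReLU-active side
                           rep(mean(img[1:3, 1:3, 1]) + 10, 4)
                         })
  params <- init_extractor(spec, 1)
  # identity wiring: the feature vector's first component carries the
  # backbone mean through projection and fusion; weather contributes 0
  params$proj$W[] <- 0; params$proj$W[1, 1] <- 1; params$proj$b[] <- 0
  params$gru$Wx[] <- 0; params$gru$Wh[] <- 0; params$gru$Wn[] <- 0
  params$gru$b[] <- 0
  params$fus1$W[] <- 0; params$fus1$W[1, 1] <- 1; params$fus1$b[] <- 0
  params$fus2$W[] <- 0; params$fus2$W[1, 1] <- 1; params$fus2$b[] <- 0
  hspec <- comparative_spec("fc", in_dim = 8L, n_classes = 2)
  hp <- init_comparative(hspec, 1)
  # oracle head: positive iff v1[1] < v2[1] (first flowers sooner), with
  # ties falling to negative, matching the comparator's tie rule
  hp$l1$W[] <- 0; hp$l1$b[] <- 0
  hp$l1$W[1, 1] <- -1; hp$l1$W[5, 1] <- 1    # relu(v2 - v1)
  hp$l1$W[1, 2] <- 1; hp$l1$W[5, 2] <- -1    # relu(v1 - v2)
  hp$l2$W[] <- 0; hp$l2$b[] <- 0
  hp$l2$W[1, 1] <- 1; hp$l2$W[2, 2] <- 1
  hp$l3$W <- matrix(c(1, -1), 2, 1); hp$l3$b <- 0
  hp$cls$W <- matrix(c(0, 10), 1, 2); hp$cls$b <- c(1, 0)
  model <- structure(list(params = list(extractor = params, head = hp),
                          ema = list(extractor = params, head = hp),
                          ext_spec = spec, head_spec = hspec,
                          stats = list(mean = rep(0, 6), sd = rep(1, 6))),
                     class = "spikecast_model")
  # the planted signal makes "first flowers sooner" perfectly separable,
  # away from the exact boundary day where the tie rule bites
  r <- run_protocol(model, pool, critical_days = c(5L), shots = 5,
                    cycles = 1, seed = 3, queries_per_plant = 8,
                    boundary = "strict")
  expect_equal(r$summary$mean_f1, 1)
})

test_that("anchor transfer runs against a second pool without retraining", {
  poolA <- fixture_iwc_pool(n_plants = 8, days = 2:9, per_day = 2, seed = 99)
  poolB <- fixture_iwc_pool(n_plants = 8, days = 2:9, per_day = 2, seed = 77)
  model <- tiny_model(poolA)
  r <- run_protocol(model, poolB, critical_days = c(4L, 6L), shots = 5,
                    cycles = 2, seed = 9, queries_per_plant = 3,
                    anchor_pool = poolA)
  expect_true(r$settings$anchor_transfer)
  expect_equal(nrow(r$summary), 2)
})
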