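# Shape contracts, determinism and gradient correctness of the Siamese
# extractor and the two comparative heads.

test_that("default specs carry the published architecture constants", {
  spec <- extractor_spec()
  expect_equal(spec$backbone_out_dim, 1000L)
  expect_equal(spec$image_proj_dim, 512L)
  expect_equal(spec$weather_hidden_dim, 512L)
  expect_equal(spec$fused_dim, 1024L)
  expect_equal(spec$out_dim, 256L)
  hspec <- comparative_spec("tf")
  expect_equal(hspec$in_dim, 512L)
  expect_equal(hspec$attn_heads, 4L)
  expect_equal(hspec$model_dim %/% hspec$attn_heads, 64L)
  expect_error(extractor_spec(out_dim = 2000), "smaller")
  expect_error(comparative_spec(n_classes = 5), "2 or 3")
})

test_that("the shape contract chain holds end to end on the tiny spec", {
  spec <- tiny_ext_spec()
  params <- init_extractor(spec, seed = 1)
  withr::with_seed(2, {
    img <- matrix(runif(64), 8, 8)
    win <- matrix(rnorm(30), 5, 6)
  })
  iv <- image_branch(img, params, spec)
  expect_length(iv, spec$image_proj_dim)
  wv <- weather_branch(win, params, spec)
  expect_length(wv, spec$weather_hidden_dim)
  x <- iwc(img, win, "P1", "2023-09-01", 5)
  fv <- extract_features(x, params, spec)
  expect_length(fv, spec$out_dim)
  expect_true(all(is.finite(fv)))
  # Siamese sharing: the same parameters give identical features for
  # identical inputs, on repeated evaluation (bit-stable inference)
  expect_identical(fv, extract_features(x, params, spec))
  expect_identical(iv, image_branch(img, params, spec))

  for (ht in c("fc", "tf")) {
    for (k in c(2L, 3L)) {
      hspec <- comparative_spec(ht, in_dim = 2L * spec$out_dim, n_classes = k)
      hp <- init_comparative(hspec, seed = 3)
      scores <- if (ht == "fc") compare_fc(fv, wv[1:4] * 0 + fv, hp, hspec)
                else compare_tf(fv, fv * 0.5, hp, hspec)
      expect_length(scores, k)
      expect_true(all(is.finite(scores)))
    }
  }
})

test_that("a zero image through a zero-initialised projection gives zeros", {
  spec <- tiny_ext_spec()
  params <- init_extractor(spec, seed = 1)
  params$proj$W[] <- 0
  params$proj$b[] <- 0
  iv <- image_branch(matrix(0, 8, 8) + spec$image_norm_mean, params, spec)
  expect_equal(iv, rep(0, spec$image_proj_dim))
})

test_that("a custom backbone must honour the 1000-d output contract", {
  bad <- extractor_spec(backbone_name = "custom", image_size = 8,
                        custom_backbone = function(img) rnorm(7))
  params <- init_extractor(bad, seed = 1)
  x <- iwc(matrix(0.5, 8, 8), matrix(0, 5, 6), "P1", "2023-09-01", 5)
  expect_error(extract_features(x, params, bad), "contract requires")
  good <- extractor_spec(backbone_name = "custom", image_size = 8,
                         backbone_out_dim = 12L,
                         custom_backbone = function(img) rep(1, 12))
  gp <- init_extractor(good, seed = 1)
  expect_length(extract_features(x, gp, good), good$out_dim)
})

test_that("the weather branch is order-sensitive and single-step exact", {
  spec <- tiny_ext_spec()
  params <- init_extractor(spec, seed = 4)
  withr::with_seed(5, win <- matrix(rnorm(30), 5, 6))
  fwd <- weather_branch(win, params, spec)
  rev <- weather_branch(win[5:1, ], params, spec)
  expect_gt(max(abs(fwd - rev)), 1e-8)
  # a single-row window equals one recurrence step from the zero state
  one <- weather_branch(win[1, , drop = FALSE], params, spec)
  H <- spec$weather_hidden_dim
  ax <- as.numeric(win[1, ] %*% params$gru$Wx) + params$gru$b
  r <- 1 / (1 + exp(-ax[1:H]))
  z <- 1 / (1 + exp(-ax[H + 1:H]))
  n <- tanh(ax[2 * H + 1:H])
  expect_equal(one, (1 - z) * n, tolerance = 1e-12)
})

test_that("TF-head pooling is token-order invariant only for equal tokens", {
  spec <- tiny_ext_spec()
  hspec <- comparative_spec("tf", in_dim = 2L * spec$out_dim, n_classes = 2)
  hp <- init_comparative(hspec, seed = 6)
  withr::with_seed(7, {
    v1 <- rnorm(spec$out_dim)
    v2 <- rnorm(spec$out_dim)
  })
  # with v1 = v2 the two token paths coincide, so swapping cannot matter
  expect_equal(compare_tf(v1, v1, hp, hspec), compare_tf(v1, v1, hp, hspec))
  # generally the ordering carries first-vs-second semantics
  expect_gt(max(abs(compare_tf(v1, v2, hp, hspec) -
                      compare_tf(v2, v1, hp, hspec))), 1e-8)
})

test_that("analytic gradients agree with finite differences", {
  # end-to-end pair loss through CNN, GRU, fusion and both heads
  ns <- asNamespace("spikecast")
  spec <- tiny_ext_spec()
  B <- 2
  withr::with_seed(31, {
    Ximg <- array(rnorm(B * 2 * 64), c(B * 2, 8, 8, 1))
    Xwin <- array(rnorm(2 * 4 * 6), c(2, 4, 6))
  })
  win_index <- c(1L, 2L, 2L, 1L)
  y <- c(1L, 2L)
  for (ht in c("fc", "tf")) {
    hspec <- comparative_spec(ht, in_dim = 8, n_classes = 2)
    params <- list(extractor = init_extractor(spec, 1),
                   head = init_comparative(hspec, 2))
    lossfun <- function(p) {
      fw <- ns$extractor_fwd(p$extractor, spec, Ximg, Xwin, win_index)
      hf <- ns$head_fwd(p$head, hspec, fw$feat[1:B, , drop = FALSE],
                        fw$feat[B + 1:B, , drop = FALSE])
      list(fw = fw, hf = hf,
           ls = ns$xent_smoothed(hf$logits, y, 0.1))
    }
    r <- lossfun(params)
    hb <- ns$head_bwd(r$ls$dlogits, params$head, hspec, r$hf$cache)
    eg <- ns$extractor_bwd(rbind(hb$dV1, hb$dV2), params$extractor, spec,
                           r$fw)
    grads <- list(extractor = eg, head = hb$grads)
    paths <- list(c("extractor", "cnn", "conv1", "W"),
                  c("extractor", "cnn", "fc", "b"),
                  c("extractor", "gru", "Wh"),
                  c("extractor", "gru", "Wn"),
                  c("extractor", "proj", "W"),
                  c("extractor", "fus1", "W"),
                  c("head", names(grads$head)[1], "W"),
                  c("head", "cls", "b"))
    withr::with_seed(32, {
      for (path in paths) {
        leaf <- params[[path]]
        g <- grads[[path]]
        for (i in sample(length(leaf), min(3, length(leaf)))) {
          # eps small enough not to cross ReLU kinks of this fixture
          eps <- 1e-6
          pp <- params; pp[[path]][i] <- leaf[i] + eps
          lp <- lossfun(pp)$ls$loss
          pp <- params; pp[[path]][i] <- leaf[i] - eps
          lm <- lossfun(pp)$ls$loss
          num <- (lp - lm) / (2 * eps)
          expect_equal(g[i], num, tolerance = 1e-3,
                       label = paste0(ht, ":", paste(path, collapse = "$"),
                                      "[", i, "]"))
        }
      }
    })
  }
})
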