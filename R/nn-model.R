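## The Siamese feature extractor (image branch + weather branch + fusion)
## and the two comparative heads (FC and TF). Shape contract:
## image -> 1000 -> 512, weather T x 6 -> 512, concat 1024 -> 512 -> 256
## per IWC; head input 2 x 256 = 512 -> n_classes.

#' Feature-extractor specification
#'
#' Dimensions and backbone choice for the shared (Siamese) feature
#' extractor. The fused dimension is always
#' `image_proj_dim + weather_hidden_dim` and the output must be smaller.
#'
#' @param backbone_name `"tiny_cnn"` (the bundled 3-conv-block backbone) or
#'   `"custom"` (supply `custom_backbone`, any function mapping an image to
#'   a `backbone_out_dim` vector, e.g. an adapter around a pretrained
#'   model; it is used forward-only).
#' @param backbone_out_dim Backbone output width; 1000 by the
#'   ImageNet-classifier-head convention.
#' @param image_proj_dim Image feature width after the projection layer.
#' @param weather_hidden_dim GRU hidden-state width.
#' @param out_dim Final per-IWC feature width.
#' @param image_size Input image side length in pixels (tiny_cnn: must be
#'   divisible by 8).
#' @param in_channels Image channels (1 = grayscale).
#' @param window_cols Weather-window column count (6).
#' @param fusion_hidden_dim Width of the first fusion layer.
#' @param weather_zeroed If `TRUE` the weather input is replaced by zeros
#'   (ablation mode).
#' @param custom_backbone Optional function for `backbone_name = "custom"`.
#' @param image_norm_mean,image_norm_sd Image standardisation constants.
#' @return List of class `extractor_spec` with derived field `fused_dim`.
#' @export
extractor_spec <- function(backbone_name = c("tiny_cnn", "custom"),
                           backbone_out_dim = 1000L,
                           image_proj_dim = 512L,
                           weather_hidden_dim = 512L,
                           out_dim = 256L,
                           image_size = 32L,
                           in_channels = 1L,
                           window_cols = 6L,
                           fusion_hidden_dim = NULL,
                           weather_zeroed = FALSE,
                           custom_backbone = NULL,
                           image_norm_mean = 0.5,
                           image_norm_sd = 0.25) {
  backbone_name <- match.arg(backbone_name)
  fused_dim <- image_proj_dim + weather_hidden_dim
  abort_if(out_dim >= fused_dim, "out_dim must be smaller than fused_dim")
  if (backbone_name == "tiny_cnn") {
    abort_if(image_size %% 8L != 0L, "tiny_cnn needs image_size divisible by 8")
  }
  if (backbone_name == "custom") {
    abort_if(!is.function(custom_backbone),
             "custom backbone requires a function(image) -> backbone_out_dim vector")
  }
  structure(list(
    backbone_name = backbone_name,
    backbone_out_dim = as.integer(backbone_out_dim),
    image_proj_dim = as.integer(image_proj_dim),
    weather_hidden_dim = as.integer(weather_hidden_dim),
    fused_dim = as.integer(fused_dim),
    out_dim = as.integer(out_dim),
    image_size = as.integer(image_size),
    in_channels = as.integer(in_channels),
    window_cols = as.integer(window_cols),
    fusion_hidden_dim = as.integer(fusion_hidden_dim %||% (fused_dim / 2)),
    weather_zeroed = isTRUE(weather_zeroed),
    custom_backbone = custom_backbone,
    image_norm_mean = image_norm_mean,
    image_norm_sd = image_norm_sd
  ), class = "extractor_spec")
}

TINY_CNN_CHANNELS <- c(8L, 16L, 32L)

#' Initialise feature-extractor parameters
#'
#' Glorot-uniform weights, zero biases; deterministic per seed.
#'
#' @param spec An [extractor_spec()].
#' @param seed Integer seed.
#' @return Named parameter tree (nested list of matrices/vectors).
#' @export
init_extractor <- function(spec, seed = 1L) {
  withr::with_seed(seed, {
    p <- list()
    if (spec$backbone_name == "tiny_cnn") {
      ch <- c(spec$in_channels, TINY_CNN_CHANNELS)
      flat <- (spec$image_size %/% 8L)^2 * TINY_CNN_CHANNELS[3]
      p$cnn <- list(conv1 = conv_init(ch[1], ch[2]),
                    conv2 = conv_init(ch[2], ch[3]),
                    conv3 = conv_init(ch[3], ch[4]),
                    fc = dense_init(flat, spec$backbone_out_dim))
    }
    p$proj <- dense_init(spec$backbone_out_dim, spec$image_proj_dim)
    p$gru <- gru_init(spec$window_cols, spec$weather_hidden_dim)
    p$fus1 <- dense_init(spec$fused_dim, spec$fusion_hidden_dim)
    p$fus2 <- dense_init(spec$fusion_hidden_dim, spec$out_dim)
    p
  })
}

#' Comparative-head specification
#'
#' @param head_type `"fc"` (four fully connected layers with halving
#'   widths, then a classifier) or `"tf"` (a single transformer block over
#'   the two feature vectors as tokens, 1-D max pooling over the flattened
#'   block output, then a dense classifier; no embedding layer, no
#'   positional encoding).
#' @param in_dim Head input width: twice the extractor's `out_dim`.
#' @param n_classes 2 (binary) or 3 (ternary).
#' @param fc_layers Number of FC layers before the classifier counts the
#'   classifier itself (4 total).
#' @param attn_heads Attention heads in the TF block.
#' @param ff_mult Feed-forward inner width as a multiple of the model dim.
#' @return List of class `comparative_spec`.
#' @export
comparative_spec <- function(head_type = c("fc", "tf"), in_dim = 512L,
                             n_classes = 2L, fc_layers = 4L, attn_heads = 4L,
                             ff_mult = 4L) {
  head_type <- match.arg(head_type)
  abort_if(in_dim %% 2L != 0L, "in_dim must be even (two stacked features)")
  abort_if(head_type == "fc" && in_dim < 8L,
           "the fc head's halving widths need in_dim >= 8")
  abort_if(!n_classes %in% c(2L, 3L), "n_classes must be 2 or 3")
  model_dim <- in_dim %/% 2L
  abort_if(head_type == "tf" && model_dim %% attn_heads != 0L,
           "model dim ", model_dim, " not divisible by ", attn_heads, " heads")
  structure(list(head_type = head_type, in_dim = as.integer(in_dim),
                 model_dim = as.integer(model_dim),
                 n_classes = as.integer(n_classes),
                 fc_layers = as.integer(fc_layers),
                 attn_heads = as.integer(attn_heads),
                 ff_mult = as.integer(ff_mult)),
            class = "comparative_spec")
}

#' Initialise comparative-head parameters
#'
#' @param spec A [comparative_spec()].
#' @param seed Integer seed.
#' @return Named parameter tree.
#' @export
init_comparative <- function(spec, seed = 1L) {
  withr::with_seed(seed, {
    if (spec$head_type == "fc") {
      d <- spec$in_dim
      list(l1 = dense_init(d, d %/% 2L),
           l2 = dense_init(d %/% 2L, d %/% 4L),
           l3 = dense_init(d %/% 4L, d %/% 8L),
           cls = dense_init(d %/% 8L, spec$n_classes))
    } else {
      d <- spec$model_dim
      list(q = dense_init(d, d), k = dense_init(d, d), v = dense_init(d, d),
           o = dense_init(d, d),
           ff1 = dense_init(d, spec$ff_mult * d),
           ff2 = dense_init(spec$ff_mult * d, d),
           cls = dense_init(d, spec$n_classes))
    }
  })
}

## ---- batched extractor forward/backward -----------------------------------

## Ximg: (B, s, s, C) already standardised; Xwin: (U, T, 6) already
## normalised (zeroed if spec$weather_zeroed); win_index: length-B map into
## the U unique windows.
extractor_fwd <- function(params, spec, Ximg, Xwin, win_index,
                          keep_cache = TRUE) {
  B <- dim(Ximg)[1]
  cache <- list(win_index = win_index, B = B)

  if (spec$backbone_name == "tiny_cnn") {
    c1 <- conv_fwd(Ximg, params$cnn$conv1); a1 <- relu(c1$Y)
    p1 <- avgpool_fwd(a1)
    c2 <- conv_fwd(p1, params$cnn$conv2); a2 <- relu(c2$Y)
    p2 <- avgpool_fwd(a2)
    c3 <- conv_fwd(p2, params$cnn$conv3); a3 <- relu(c3$Y)
    p3 <- avgpool_fwd(a3)
    flat <- p3; dim(flat) <- c(B, length(p3) / B)
    backbone <- dense_fwd(flat, params$cnn$fc)
    if (keep_cache) {
      cache$cnn <- list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3, a3 = a3,
                        p1 = p1, p2 = p2, flat = flat)
    }
  } else {
    backbone <- t(apply(Ximg, 1, function(im) {
      v <- spec$custom_backbone(array(im, dim(Ximg)[-1]))
      abort_if(length(v) != spec$backbone_out_dim,
               "backbone output has ", length(v), " dims, contract requires ",
               spec$backbone_out_dim)
      as.numeric(v)
    }))
  }
  abort_if(ncol(backbone) != spec$backbone_out_dim,
           "backbone output has ", ncol(backbone), " dims, contract requires ",
           spec$backbone_out_dim)

  proj_pre <- dense_fwd(backbone, params$proj)
  img_feat <- relu(proj_pre)                       # (B, image_proj_dim)

  if (spec$weather_zeroed) Xwin[] <- 0
  gf <- gru_fwd(Xwin, params$gru, keep_cache = keep_cache)
  wf_feat <- gf$h[win_index, , drop = FALSE]       # (B, weather_hidden_dim)

  fused <- cbind(img_feat, wf_feat)                # (B, 1024)
  h1_pre <- dense_fwd(fused, params$fus1)
  h1 <- relu(h1_pre)
  feat <- dense_fwd(h1, params$fus2)               # (B, out_dim)

  if (keep_cache) {
    cache$backbone <- backbone; cache$img_feat <- img_feat
    cache$gru <- gf; cache$wf_feat <- wf_feat
    cache$fused <- fused; cache$h1 <- h1
  }
  list(feat = feat, fused = fused, img_feat = img_feat, wf_feat = wf_feat,
       cache = cache)
}

extractor_bwd <- function(dfeat, params, spec, fw) {
  cache <- fw$cache
  B <- cache$B
  g <- list()

  d2 <- dense_bwd(dfeat, cache$h1, params$fus2)
  g$fus2 <- list(W = d2$dW, b = d2$db)
  dh1 <- relu_bwd(d2$dX, cache$h1)
  d1 <- dense_bwd(dh1, cache$fused, params$fus1)
  g$fus1 <- list(W = d1$dW, b = d1$db)
  dimg <- d1$dX[, seq_len(spec$image_proj_dim), drop = FALSE]
  dwf <- d1$dX[, spec$image_proj_dim + seq_len(spec$weather_hidden_dim),
               drop = FALSE]

  ## weather branch: aggregate per unique window, then back through time
  dhU <- rowsum(dwf, group = cache$win_index, reorder = FALSE)
  ## rowsum orders groups by first appearance with reorder = FALSE; build
  ## the aggregation explicitly to stay aligned with the unique windows.
  U <- cache$gru$U
  dhu <- matrix(0, U, spec$weather_hidden_dim)
  grp <- as.integer(rownames(dhU))
  dhu[grp, ] <- dhU
  if (spec$weather_zeroed) {
    gb <- zeros_like(params$gru)
    names(gb) <- names(params$gru)
    g$gru <- gb
  } else {
    gb <- gru_bwd(dhu, params$gru, cache$gru)
    g$gru <- list(Wx = gb$dWx, Wh = gb$dWh, Wn = gb$dWn, b = gb$db)
  }

  dproj_pre <- relu_bwd(dimg, cache$img_feat)
  dp <- dense_bwd(dproj_pre, cache$backbone, params$proj)
  g$proj <- list(W = dp$dW, b = dp$db)

  if (spec$backbone_name == "tiny_cnn") {
    s <- spec$image_size
    dfc <- dense_bwd(dp$dX, cache$cnn$flat, params$cnn$fc)
    dflat <- dfc$dX
    dim(dflat) <- c(B, s %/% 8L, s %/% 8L, TINY_CNN_CHANNELS[3])
    dp3 <- avgpool_bwd(dflat, s %/% 4L)
    da3 <- relu_bwd(dp3, cache$cnn$a3)
    d3 <- conv_bwd(da3, params$cnn$conv3, cache$cnn$c3$M, B, s %/% 4L,
                   TINY_CNN_CHANNELS[2])
    dp2 <- avgpool_bwd(d3$dX, s %/% 2L)
    da2 <- relu_bwd(dp2, cache$cnn$a2)
    d2c <- conv_bwd(da2, params$cnn$conv2, cache$cnn$c2$M, B, s %/% 2L,
                    TINY_CNN_CHANNELS[1])
    dp1 <- avgpool_bwd(d2c$dX, s)
    da1 <- relu_bwd(dp1, cache$cnn$a1)
    d1c <- conv_bwd(da1, params$cnn$conv1, cache$cnn$c1$M, B, s,
                    spec$in_channels)
    g$cnn <- list(conv1 = list(W = d1c$dW, b = d1c$db),
                  conv2 = list(W = d2c$dW, b = d2c$db),
                  conv3 = list(W = d3$dW, b = d3$db),
                  fc = list(W = dfc$dW, b = dfc$db))
  }
  g[names(params)]
}

## ---- comparative heads -----------------------------------------------------

head_fwd <- function(params, spec, V1, V2, keep_cache = TRUE) {
  if (spec$head_type == "fc") {
    X <- cbind(V1, V2)
    h1 <- relu(dense_fwd(X, params$l1))
    h2 <- relu(dense_fwd(h1, params$l2))
    h3 <- relu(dense_fwd(h2, params$l3))
    logits <- dense_fwd(h3, params$cls)
    cache <- if (keep_cache) list(X = X, h1 = h1, h2 = h2, h3 = h3) else NULL
    return(list(logits = logits, cache = cache))
  }
  ## TF head: the two feature vectors are the two tokens.
  d <- spec$model_dim; nh <- spec$attn_heads; dh <- d %/% nh
  sc <- 1 / sqrt(dh)
  q1 <- dense_fwd(V1, params$q); q2 <- dense_fwd(V2, params$q)
  k1 <- dense_fwd(V1, params$k); k2 <- dense_fwd(V2, params$k)
  w1 <- dense_fwd(V1, params$v); w2 <- dense_fwd(V2, params$v)
  B <- nrow(V1)
  o1 <- matrix(0, B, d); o2 <- matrix(0, B, d)
  A <- vector("list", nh)
  for (h in seq_len(nh)) {
    ix <- (h - 1L) * dh + seq_len(dh)
    s11 <- rowSums(q1[, ix, drop = FALSE] * k1[, ix, drop = FALSE]) * sc
    s12 <- rowSums(q1[, ix, drop = FALSE] * k2[, ix, drop = FALSE]) * sc
    s21 <- rowSums(q2[, ix, drop = FALSE] * k1[, ix, drop = FALSE]) * sc
    s22 <- rowSums(q2[, ix, drop = FALSE] * k2[, ix, drop = FALSE]) * sc
    m1 <- pmax(s11, s12); e11 <- exp(s11 - m1); e12 <- exp(s12 - m1)
    a11 <- e11 / (e11 + e12); a12 <- 1 - a11
    m2 <- pmax(s21, s22); e21 <- exp(s21 - m2); e22 <- exp(s22 - m2)
    a21 <- e21 / (e21 + e22); a22 <- 1 - a21
    o1[, ix] <- a11 * w1[, ix, drop = FALSE] + a12 * w2[, ix, drop = FALSE]
    o2[, ix] <- a21 * w1[, ix, drop = FALSE] + a22 * w2[, ix, drop = FALSE]
    A[[h]] <- list(a11 = a11, a12 = a12, a21 = a21, a22 = a22)
  }
  attn1 <- dense_fwd(o1, params$o); attn2 <- dense_fwd(o2, params$o)
  u1 <- V1 + attn1; u2 <- V2 + attn2
  f1h <- relu(dense_fwd(u1, params$ff1)); f1 <- dense_fwd(f1h, params$ff2)
  f2h <- relu(dense_fwd(u2, params$ff1)); f2 <- dense_fwd(f2h, params$ff2)
  y1 <- u1 + f1; y2 <- u2 + f2
  ## 1-D max pooling (window 2, stride 2) along the flattened token
  ## sequence [y1, y2]: halves the dimensionality while preserving token
  ## order, so the head keeps the first-vs-second semantics of the pair
  Y <- cbind(y1, y2)
  odd <- seq(1L, 2L * d, 2L)
  mask1 <- Y[, odd, drop = FALSE] >= Y[, odd + 1L, drop = FALSE]
  m <- pmax(Y[, odd, drop = FALSE], Y[, odd + 1L, drop = FALSE])
  logits <- dense_fwd(m, params$cls)
  cache <- if (keep_cache) {
    list(V1 = V1, V2 = V2, q1 = q1, q2 = q2, k1 = k1, k2 = k2,
         w1 = w1, w2 = w2, A = A, o1 = o1, o2 = o2,
         u1 = u1, u2 = u2, f1h = f1h, f2h = f2h, mask1 = mask1, m = m)
  } else NULL
  list(logits = logits, cache = cache)
}

head_bwd <- function(dlogits, params, spec, cache) {
  if (spec$head_type == "fc") {
    dc <- dense_bwd(dlogits, cache$h3, params$cls)
    d3 <- dense_bwd(relu_bwd(dc$dX, cache$h3), cache$h2, params$l3)
    d2 <- dense_bwd(relu_bwd(d3$dX, cache$h2), cache$h1, params$l2)
    d1 <- dense_bwd(relu_bwd(d2$dX, cache$h1), cache$X, params$l1)
    half <- ncol(cache$X) %/% 2L
    return(list(
      grads = list(l1 = list(W = d1$dW, b = d1$db),
                   l2 = list(W = d2$dW, b = d2$db),
                   l3 = list(W = d3$dW, b = d3$db),
                   cls = list(W = dc$dW, b = dc$db)),
      dV1 = d1$dX[, seq_len(half), drop = FALSE],
      dV2 = d1$dX[, half + seq_len(half), drop = FALSE]))
  }
  d <- spec$model_dim; nh <- spec$attn_heads; dh <- d %/% nh
  sc <- 1 / sqrt(dh)
  dc <- dense_bwd(dlogits, cache$m, params$cls)
  dY <- matrix(0, nrow(dc$dX), 2L * d)
  odd <- seq(1L, 2L * d, 2L)
  dY[, odd] <- dc$dX * cache$mask1
  dY[, odd + 1L] <- dc$dX * (!cache$mask1)
  dy1 <- dY[, seq_len(d), drop = FALSE]
  dy2 <- dY[, d + seq_len(d), drop = FALSE]
  ## feed-forward (shared weights across tokens)
  b2a <- dense_bwd(dy1, cache$f1h, params$ff2)
  b2b <- dense_bwd(dy2, cache$f2h, params$ff2)
  df1h <- relu_bwd(b2a$dX, cache$f1h); df2h <- relu_bwd(b2b$dX, cache$f2h)
  b1a <- dense_bwd(df1h, cache$u1, params$ff1)
  b1b <- dense_bwd(df2h, cache$u2, params$ff1)
  du1 <- dy1 + b1a$dX; du2 <- dy2 + b1b$dX
  ## attention output projection
  boa <- dense_bwd(du1, cache$o1, params$o)
  bob <- dense_bwd(du2, cache$o2, params$o)
  do1 <- boa$dX; do2 <- bob$dX
  dq1 <- matrix(0, nrow(do1), d); dq2 <- dq1
  dk1 <- dq1; dk2 <- dq1; dw1 <- dq1; dw2 <- dq1
  for (h in seq_len(nh)) {
    ix <- (h - 1L) * dh + seq_len(dh)
    a <- cache$A[[h]]
    w1h <- cache$w1[, ix, drop = FALSE]; w2h <- cache$w2[, ix, drop = FALSE]
    do1h <- do1[, ix, drop = FALSE]; do2h <- do2[, ix, drop = FALSE]
    dw1[, ix] <- a$a11 * do1h + a$a21 * do2h
    dw2[, ix] <- a$a12 * do1h + a$a22 * do2h
    da11 <- rowSums(do1h * w1h); da12 <- rowSums(do1h * w2h)
    da21 <- rowSums(do2h * w1h); da22 <- rowSums(do2h * w2h)
    dot1 <- a$a11 * da11 + a$a12 * da12
    dot2 <- a$a21 * da21 + a$a22 * da22
    ds11 <- a$a11 * (da11 - dot1); ds12 <- a$a12 * (da12 - dot1)
    ds21 <- a$a21 * (da21 - dot2); ds22 <- a$a22 * (da22 - dot2)
    q1h <- cache$q1[, ix, drop = FALSE]; q2h <- cache$q2[, ix, drop = FALSE]
    k1h <- cache$k1[, ix, drop = FALSE]; k2h <- cache$k2[, ix, drop = FALSE]
    dq1[, ix] <- sc * (ds11 * k1h + ds12 * k2h)
    dq2[, ix] <- sc * (ds21 * k1h + ds22 * k2h)
    dk1[, ix] <- sc * (ds11 * q1h + ds21 * q2h)
    dk2[, ix] <- sc * (ds12 * q1h + ds22 * q2h)
  }
  bq1 <- dense_bwd(dq1, cache$V1, params$q); bq2 <- dense_bwd(dq2, cache$V2, params$q)
  bk1 <- dense_bwd(dk1, cache$V1, params$k); bk2 <- dense_bwd(dk2, cache$V2, params$k)
  bv1 <- dense_bwd(dw1, cache$V1, params$v); bv2 <- dense_bwd(dw2, cache$V2, params$v)
  dV1 <- du1 + bq1$dX + bk1$dX + bv1$dX
  dV2 <- du2 + bq2$dX + bk2$dX + bv2$dX
  list(
    grads = list(
      q = list(W = bq1$dW + bq2$dW, b = bq1$db + bq2$db),
      k = list(W = bk1$dW + bk2$dW, b = bk1$db + bk2$db),
      v = list(W = bv1$dW + bv2$dW, b = bv1$db + bv2$db),
      o = list(W = boa$dW + bob$dW, b = boa$db + bob$db),
      ff1 = list(W = b1a$dW + b1b$dW, b = b1a$db + b1b$db),
      ff2 = list(W = b2a$dW + b2b$dW, b = b2a$db + b2b$db),
      cls = list(W = dc$dW, b = dc$db)),
    dV1 = dV1, dV2 = dV2)
}

## ---- user-facing single-observation operations ----------------------------

standardize_image <- function(image, spec) {
  img <- rgb_to_luminance(image)
  if (nrow(img) != spec$image_size || ncol(img) != spec$image_size) {
    img <- resize_image(img, spec$image_size)
  }
  (img - spec$image_norm_mean) / spec$image_norm_sd
}

image_tensor <- function(images, spec) {
  B <- length(images)
  X <- array(0, c(B, spec$image_size, spec$image_size, spec$in_channels))
  for (b in seq_len(B)) X[b, , , 1] <- standardize_image(images[[b]], spec)
  X
}

#' Image branch of the feature extractor
#'
#' Backbone to a `backbone_out_dim` vector, then a trainable affine
#' projection with ReLU down to `image_proj_dim` (512 by default).
#'
#' @param image Image matrix (resized/standardised internally).
#' @param params Extractor parameters from [init_extractor()].
#' @param spec The matching [extractor_spec()].
#' @return Numeric vector of length `spec$image_proj_dim`.
#' @export
image_branch <- function(image, params, spec) {
  X <- image_tensor(list(image), spec)
  fw <- extractor_fwd(params, spec, X,
                      array(0, c(1L, 1L, spec$window_cols)), 1L,
                      keep_cache = FALSE)
  as.numeric(fw$img_feat[1, ])
}

#' Weather branch of the feature extractor
#'
#' A gated recurrent encoder consumes the (already normalised) window rows
#' oldest to newest; the final hidden state is the weather feature.
#'
#' @param window Normalised weather-window matrix (T x 6).
#' @param params,spec As in [image_branch()].
#' @return Numeric vector of length `spec$weather_hidden_dim`.
#' @export
weather_branch <- function(window, params, spec) {
  abort_if(ncol(window) != spec$window_cols,
           "window has ", ncol(window), " columns, expected ", spec$window_cols)
  Xw <- array(0, c(1L, nrow(window), ncol(window)))
  Xw[1, , ] <- unclass(window)
  if (spec$weather_zeroed) Xw[] <- 0
  as.numeric(gru_fwd(Xw, params$gru, keep_cache = FALSE)$h[1, ])
}

#' Extract the fused per-IWC feature vector
#'
#' Concatenates the image and weather features (1024), then two fully
#' connected layers with an interposed ReLU reduce to `out_dim` (256).
#' Both members of a pair are processed with the same parameters
#' (Siamese weight sharing).
#'
#' @param x An `iwc` object.
#' @param params,spec As in [image_branch()].
#' @param stats Window normalisation statistics ([window_stats()]), or
#'   `NULL` if `x$weather` is already normalised.
#' @return Numeric vector of length `spec$out_dim`.
#' @export
extract_features <- function(x, params, spec, stats = NULL) {
  win <- if (is.null(stats)) unclass(x$weather) else normalize_window(x$weather, stats)
  X <- image_tensor(list(x$image), spec)
  Xw <- array(0, c(1L, nrow(win), ncol(win)))
  Xw[1, , ] <- win
  fw <- extractor_fwd(params, spec, X, Xw, 1L, keep_cache = FALSE)
  as.numeric(fw$feat[1, ])
}

#' Compare two feature vectors with the FC head
#'
#' The vectors are stacked to a 512-d input and passed through four fully
#' connected layers with halving widths and ReLU between, ending in a
#' classifier over `n_classes`.
#'
#' @param v1,v2 Feature vectors of length `spec$in_dim / 2`.
#' @param params Head parameters from [init_comparative()].
#' @param spec The matching [comparative_spec()] with `head_type = "fc"`.
#' @return Numeric vector of `n_classes` scores (logits).
#' @export
compare_fc <- function(v1, v2, params, spec) {
  abort_if(spec$head_type != "fc", "spec is not an fc head")
  check_head_dims(v1, v2, spec)
  as.numeric(head_fwd(params, spec, rbind(v1), rbind(v2),
                      keep_cache = FALSE)$logits[1, ])
}

#' Compare two feature vectors with the TF head
#'
#' The two vectors form a 2-token sequence (no embedding layer, no
#' positional encoding); one transformer block (multi-head self-attention
#' with residual, feed-forward with residual), then 1-D max pooling
#' (window 2, stride 2) along the flattened two-token output reduces
#' 512 to 256 before the dense classifier. Pooling along the feature
#' axis, rather than across tokens, keeps the head order-sensitive: a
#' cross-token pool would be permutation-invariant and could not express
#' the asymmetric "first flowers sooner" relation.
#'
#' @inheritParams compare_fc
#' @export
compare_tf <- function(v1, v2, params, spec) {
  abort_if(spec$head_type != "tf", "spec is not a tf head")
  check_head_dims(v1, v2, spec)
  as.numeric(head_fwd(params, spec, rbind(v1), rbind(v2),
                      keep_cache = FALSE)$logits[1, ])
}

check_head_dims <- function(v1, v2, spec) {
  abort_if(length(v1) != spec$model_dim || length(v2) != spec$model_dim,
           "feature vectors must have length ", spec$model_dim,
           " (got ", length(v1), ", ", length(v2), ")")
}
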