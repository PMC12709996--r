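## Matrix-algebra neural-network primitives with explicit forward/backward
## passes. Batches are stored with the batch index first: images as
## (B, H, W, C) arrays, feature matrices as (B, d). All layers are pure
## functions of (input, params).

glorot_init <- function(din, dout) {
  lim <- sqrt(6 / (din + dout))
  matrix(stats::runif(din * dout, -lim, lim), din, dout)
}

dense_init <- function(din, dout) {
  list(W = glorot_init(din, dout), b = numeric(dout))
}

add_bias <- function(Y, b) Y + rep(b, each = nrow(Y))

dense_fwd <- function(X, p) add_bias(X %*% p$W, p$b)

dense_bwd <- function(dY, X, p) {
  list(dW = crossprod(X, dY), db = colSums(dY), dX = tcrossprod(dY, p$W))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(dY, Y) dY * (Y > 0)

## ---- 3x3 same-padding convolution via im2col ------------------------------

## Geometry (gather indices and the sparse scatter matrix for the backward
## pass) depends only on the spatial size; cache it per size.
.geom_cache <- new.env(parent = emptyenv())

conv_geom <- function(s) {
  key <- as.character(s)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  sp <- s + 2L
  i <- rep(seq_len(s), s)           # row index, column-major positions
  j <- rep(seq_len(s), each = s)    # col index
  idx <- matrix(0L, s * s, 9L)
  t <- 0L
  for (dj in -1:1) for (di in -1:1) {
    t <- t + 1L
    idx[, t] <- (i + 1L + di) + (j + dj) * sp
  }
  S <- Matrix::sparseMatrix(i = as.vector(idx), j = seq_len(s * s * 9L),
                            x = 1, dims = c(sp * sp, s * s * 9L))
  g <- list(s = s, sp = sp, s2 = s * s, idx_vec = as.vector(idx), S = S)
  .geom_cache[[key]] <- g
  g
}

conv_init <- function(cin, cout) {
  list(W = glorot_init(9L * cin, cout), b = numeric(cout))
}

## X: (B, s, s, C) -> list(Y = (B, s, s, Cout), M = im2col matrix cache)
conv_fwd <- function(X, p) {
  d <- dim(X); B <- d[1]; s <- d[2]; C <- d[4]
  g <- conv_geom(s)
  Xp <- array(0, c(B, g$sp, g$sp, C))
  Xp[, 2:(g$sp - 1L), 2:(g$sp - 1L), ] <- X
  dim(Xp) <- c(B, g$sp * g$sp, C)
  M <- Xp[, g$idx_vec, , drop = FALSE]
  dim(M) <- c(B * g$s2, 9L * C)
  Y <- add_bias(M %*% p$W, p$b)
  cout <- ncol(p$W)
  dim(Y) <- c(B, s, s, cout)
  list(Y = Y, M = M)
}

conv_bwd <- function(dY, p, M, B, s, C) {
  g <- conv_geom(s)
  cout <- ncol(p$W)
  dim(dY) <- c(B * g$s2, cout)
  dW <- crossprod(M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, p$W)                 # (B*s2, 9C)
  dim(dM) <- c(B, g$s2, 9L, C)
  dM <- aperm(dM, c(2, 3, 1, 4))
  dim(dM) <- c(g$s2 * 9L, B * C)
  dXp <- as.matrix(g$S %*% dM)              # (sp^2, B*C)
  dim(dXp) <- c(g$sp * g$sp, B, C)
  dXp <- aperm(dXp, c(2, 1, 3))
  dim(dXp) <- c(B, g$sp, g$sp, C)
  dX <- dXp[, 2:(g$sp - 1L), 2:(g$sp - 1L), , drop = FALSE]
  list(dW = dW, db = db, dX = dX)
}

## ---- 2x2 average pooling --------------------------------------------------

avgpool_fwd <- function(X) {
  s <- dim(X)[2]
  o <- seq(1L, s, 2L); e <- o + 1L
  0.25 * (X[, o, o, , drop = FALSE] + X[, e, o, , drop = FALSE] +
          X[, o, e, , drop = FALSE] + X[, e, e, , drop = FALSE])
}

avgpool_bwd <- function(dY, s) {
  d <- dim(dY)
  dX <- array(0, c(d[1], s, s, d[4]))
  o <- seq(1L, s, 2L); e <- o + 1L
  q <- 0.25 * dY
  dX[, o, o, ] <- q; dX[, e, o, ] <- q; dX[, o, e, ] <- q; dX[, e, e, ] <- q
  dX
}

## ---- Gated recurrent unit -------------------------------------------------

## Gate layout along columns: [reset | update | candidate], each `hidden`
## wide. Original-GRU convention: r = s(Wr x + Ur h + br),
## z = s(Wz x + Uz h + bz), n = tanh(Wn x + Un (r * h) + bn),
## h_t = (1 - z) * n + z * h_{t-1}. All biases are additive, so they are
## folded into the input projection, which is computed for every step in
## one matrix product up front. The recurrent weights are split into the
## [r|z] block and the candidate block so the reset gating stays a cheap
## elementwise product.

gru_init <- function(din, hidden) {
  list(Wx = glorot_init(din, 3L * hidden),
       Wh = glorot_init(hidden, 2L * hidden),   # [r | z] recurrent block
       Wn = glorot_init(hidden, hidden),        # candidate recurrent block
       b = numeric(3L * hidden))
}

## X: (U, T, din); returns final hidden state (U, hidden) and caches as
## flat (U*T, .) matrices (rows: unit fastest, then time).
gru_fwd <- function(X, p, keep_cache = TRUE) {
  d <- dim(X); U <- d[1]; T <- d[2]
  H <- ncol(p$Wn)
  X2 <- X; dim(X2) <- c(U * T, d[3])
  AX <- add_bias(X2 %*% p$Wx, p$b)
  h <- matrix(0, U, H)
  iH <- seq_len(H)
  cache <- if (keep_cache) {
    list(rz = matrix(0, U * T, 2L * H), n = matrix(0, U * T, H),
         rh = matrix(0, U * T, H), hprev = matrix(0, U * T, H))
  } else NULL
  for (t in seq_len(T)) {
    rows <- ((t - 1L) * U + 1L):(t * U)
    rz <- sigmoid(AX[rows, c(iH, H + iH), drop = FALSE] + h %*% p$Wh)
    r <- rz[, iH, drop = FALSE]
    z <- rz[, H + iH, drop = FALSE]
    rh <- r * h
    n <- tanh(AX[rows, 2L * H + iH, drop = FALSE] + rh %*% p$Wn)
    if (keep_cache) {
      cache$rz[rows, ] <- rz; cache$n[rows, ] <- n
      cache$rh[rows, ] <- rh; cache$hprev[rows, ] <- h
    }
    h <- (1 - z) * n + z * h
  }
  list(h = h, cache = cache, X2 = X2, U = U, T = T, H = H)
}

gru_bwd <- function(dh, p, fw) {
  U <- fw$U; T <- fw$T; H <- fw$H
  cache <- fw$cache
  iH <- seq_len(H)
  dAX <- matrix(0, U * T, 3L * H)
  for (t in rev(seq_len(T))) {
    rows <- ((t - 1L) * U + 1L):(t * U)
    r <- cache$rz[rows, iH, drop = FALSE]
    z <- cache$rz[rows, H + iH, drop = FALSE]
    n <- cache$n[rows, , drop = FALSE]
    hprev <- cache$hprev[rows, , drop = FALSE]
    dn_pre <- (dh * (1 - z)) * (1 - n * n)
    drh <- tcrossprod(dn_pre, p$Wn)
    dr_pre <- (drh * hprev) * r * (1 - r)
    dz_pre <- (dh * (hprev - n)) * z * (1 - z)
    drz <- cbind(dr_pre, dz_pre)
    dAX[rows, ] <- cbind(drz, dn_pre)
    dh <- dh * z + drh * r + tcrossprod(drz, p$Wh)
  }
  list(dWx = crossprod(fw$X2, dAX),
       dWh = crossprod(cache$hprev, dAX[, c(iH, H + iH), drop = FALSE]),
       dWn = crossprod(cache$rh, dAX[, 2L * H + iH, drop = FALSE]),
       db = colSums(dAX))
}
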