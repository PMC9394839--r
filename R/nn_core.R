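# Internal neural-network primitives: batched 1-D convolution blocks
# (conv -> ReLU -> max-pool), a GRU cell, scalar output heads, and an Adam
# optimizer. Forward passes cache what the analytic backward passes need;
# everything operates on base-R arrays so results are deterministic for a
# fixed seed and batch order.
#
# Array conventions: a window batch is an array (B, L, C) -- batch, length,
# channels; feature matrices are (B, F); GRU gate order follows the PyTorch
# convention (reset, update, new).

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- conv block -------------------------------------------------------------

im2col <- function(X, k) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  P <- L - k + 1L
  M <- matrix(0, B * P, k * C)
  col <- 0L
  for (c in seq_len(C)) {
    for (j in seq_len(k)) {
      col <- col + 1L
      M[, col] <- as.vector(X[, j:(j + P - 1L), c])
    }
  }
  M
}

conv_forward <- function(X, W, b) {
  d <- dim(X); B <- d[1]; C_out <- length(b)
  k <- nrow(W) / d[3]
  P <- d[2] - k + 1L
  M <- im2col(X, k)
  Y <- M %*% W
  Y <- sweep(Y, 2L, b, `+`)
  dim(Y) <- c(B, P, C_out)
  list(Y = Y, cache = list(M = M, dimX = d, k = k))
}

conv_backward <- function(dY, W, cache) {
  d <- dim(dY); B <- d[1]; P <- d[2]; C_out <- d[3]
  dYm <- dY; dim(dYm) <- c(B * P, C_out)
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, W)
  dX <- array(0, cache$dimX)
  col <- 0L
  for (c in seq_len(cache$dimX[3])) {
    for (j in seq_len(cache$k)) {
      col <- col + 1L
      dX[, j:(j + P - 1L), c] <- dX[, j:(j + P - 1L), c] +
        matrix(dM[, col], B, P)
    }
  }
  list(dX = dX, dW = dW, db = db)
}

relu_forward <- function(X) {
  mask <- X > 0
  list(Y = X * mask, mask = mask)
}

maxpool_forward <- function(X, pool) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  P2 <- L %/% pool
  Xr <- X[, seq_len(P2 * pool), , drop = FALSE]
  dim(Xr) <- c(B, pool, P2, C)
  M <- Xr[, 1L, , , drop = FALSE]
  if (pool > 1L) {
    for (q in 2:pool) M <- pmax(M, Xr[, q, , , drop = FALSE])
  }
  dim(M) <- c(B, P2, C)
  list(Y = M, cache = list(Xr = Xr, pool = pool, dimX = d, P2 = P2))
}

maxpool_backward <- function(dY, cache) {
  d <- dim(dY); B <- d[1]; P2 <- d[2]; C <- d[3]
  pool <- cache$pool
  dXr <- array(0, c(B, pool, P2, C))
  M <- dY; dim(M) <- c(B, 1L, P2, C)
  Mfull <- array(M, c(B, 1L, P2, C))
  used <- array(FALSE, c(B, 1L, P2, C))
  maxv <- cache$Xr[, 1L, , , drop = FALSE]
  if (pool > 1L) {
    for (q in 2:pool) maxv <- pmax(maxv, cache$Xr[, q, , , drop = FALSE])
  }
  for (q in seq_len(pool)) {
    sel <- (cache$Xr[, q, , , drop = FALSE] == maxv) & !used
    used <- used | sel
    dXr[, q, , ] <- Mfull * sel
  }
  dX <- array(0, cache$dimX)
  dim(dXr) <- c(B, pool * P2, C)
  dX[, seq_len(pool * P2), ] <- dXr
  dX
}

# Full conv stack over one window batch: (B, W, C_in) -> features (B, F).
# `pools` carries the per-block pooling widths (not trainable).
conv_stack_forward <- function(X, params, pools) {
  caches <- vector("list", length(params))
  for (i in seq_along(params)) {
    cf <- conv_forward(X, params[[i]]$W, params[[i]]$b)
    rf <- relu_forward(cf$Y)
    pf <- maxpool_forward(rf$Y, pools[i])
    caches[[i]] <- list(conv = cf$cache, mask = rf$mask, pool = pf$cache)
    X <- pf$Y
  }
  d <- dim(X)
  feat <- X; dim(feat) <- c(d[1], d[2] * d[3])
  list(feat = feat, out_dim = d, caches = caches)
}

conv_stack_backward <- function(dfeat, params, fwd) {
  dX <- dfeat; dim(dX) <- fwd$out_dim
  grads <- vector("list", length(params))
  for (i in rev(seq_along(params))) {
    cc <- fwd$caches[[i]]
    dX <- maxpool_backward(dX, cc$pool)
    dX <- dX * cc$mask
    cb <- conv_backward(dX, params[[i]]$W, cc$conv)
    grads[[i]] <- list(dW = cb$dW, db = cb$db)
    dX <- cb$dX
  }
  list(dX = dX, grads = grads)
}

# ---- GRU cell ---------------------------------------------------------------

# x: (B, In); h: (B, H). Weights: W_ih (In, 3H), W_hh (H, 3H), biases 3H.
gru_forward <- function(x, h, p) {
  H <- ncol(h)
  gi <- sweep(x %*% p$W_ih, 2L, p$b_ih, `+`)
  gh <- sweep(h %*% p$W_hh, 2L, p$b_hh, `+`)
  ir <- gi[, 1:H, drop = FALSE];        hr <- gh[, 1:H, drop = FALSE]
  iz <- gi[, H + 1:H, drop = FALSE];    hz <- gh[, H + 1:H, drop = FALSE]
  inn <- gi[, 2 * H + 1:H, drop = FALSE]; hn <- gh[, 2 * H + 1:H, drop = FALSE]
  r <- sigmoid(ir + hr)
  z <- sigmoid(iz + hz)
  n <- tanh(inn + r * hn)
  h_new <- (1 - z) * n + z * h
  list(h = h_new, cache = list(x = x, h_prev = h, r = r, z = z, n = n, hn = hn))
}

gru_backward <- function(dh_new, p, cache) {
  r <- cache$r; z <- cache$z; n <- cache$n
  dn <- dh_new * (1 - z)
  dz <- dh_new * (cache$h_prev - n)
  dh <- dh_new * z
  da_n <- dn * (1 - n^2)
  dr <- da_n * cache$hn
  dhn <- da_n * r
  da_r <- dr * r * (1 - r)
  da_z <- dz * z * (1 - z)
  dgi <- cbind(da_r, da_z, da_n)
  dgh <- cbind(da_r, da_z, dhn)
  list(
    dx = tcrossprod(dgi, p$W_ih),
    dh = dh + tcrossprod(dgh, p$W_hh),
    dW_ih = crossprod(cache$x, dgi),
    dW_hh = crossprod(cache$h_prev, dgh),
    db_ih = colSums(dgi),
    db_hh = colSums(dgh)
  )
}

# ---- heads and losses -------------------------------------------------------

head_forward <- function(h, p, kind) {
  lin <- drop(h %*% p$W + p$b)
  out <- if (kind == "classifier") sigmoid(lin) else pmin(pmax(lin, 0), 1)
  list(out = out, lin = lin)
}

# Returns loss and gradient w.r.t. the linear pre-activation. BCE pairs with
# the sigmoid head; MSE with the (straight-through) clipped linear head.
head_loss_grad <- function(fwd, target, kind) {
  B <- length(target)
  if (kind == "classifier") {
    p <- pmin(pmax(fwd$out, 1e-12), 1 - 1e-12)
    loss <- -mean(target * log(p) + (1 - target) * log(1 - p))
    dlin <- (fwd$out - target) / B
  } else {
    loss <- mean((fwd$out - target)^2)
    dlin <- 2 * (fwd$out - target) / B
  }
  list(loss = loss, dlin = dlin)
}

head_backward <- function(dlin, h, p) {
  dlin <- matrix(dlin, ncol = 1L)
  list(dh = tcrossprod(dlin, p$W), dW = crossprod(h, dlin),
       db = sum(dlin))
}

# ---- parameter plumbing -----------------------------------------------------

zeros_like_params <- function(params) {
  rapply(params, function(x) if (is.numeric(x)) x * 0 else x, how = "replace")
}

# Flatten numeric leaves of the nested parameter list (fixed traversal order).
flatten_params <- function(params) {
  unlist(rapply(params, function(x) as.numeric(x), how = "unlist"))
}

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = zeros_like_params(params), v = zeros_like_params(params))
}

# Applies one Adam update; params and grads must share structure.
adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1t <- 1 - opt$beta1^opt$t
  b2t <- 1 - opt$beta2^opt$t
  walk <- function(p, g, m, v) {
    if (is.numeric(p)) {
      m <- opt$beta1 * m + (1 - opt$beta1) * g
      v <- opt$beta2 * v + (1 - opt$beta2) * g^2
      p <- p - opt$lr * (m / b1t) / (sqrt(v / b2t) + opt$eps)
      list(p = p, m = m, v = v)
    } else {
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      list(p = p, m = m, v = v)
    }
  }
  r <- walk(params, grads, opt$m, opt$v)
  opt$m <- r$m; opt$v <- r$v
  list(opt = opt, params = r$p)
}

# Structure-preserving addition of two gradient sets.
add_grads <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  for (i in seq_along(a)) a[[i]] <- add_grads(a[[i]], b[[i]])
  a
}
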