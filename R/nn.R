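# Network engine: forward/backward passes for the 1D convolutional blocks
# and dense head. All heavy lifting is either a BLAS matrix product
# (convolution via im2col) or one of the compiled kernels in src/; batches
# are column-major arrays (n, length, channels) so the reshapes between the
# two are bare `dim<-` assignments. Convolutions carry no bias: every
# convolution is immediately followed by batch normalization, whose shift
# absorbs it.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

conv_forward <- function(X, layer) {
  d <- dim(X)
  k <- layer$spec$kernel_size; s <- layer$spec$stride
  Lo <- (d[2L] - k) %/% s + 1L
  Xc <- cpp_im2col(X, d[1L], d[2L], d[3L], k, s)
  Y <- Xc %*% layer$W
  dim(Y) <- c(d[1L], Lo, ncol(layer$W))
  list(Y = Y, Xc = Xc, dims = d, k = k, s = s, Lo = Lo)
}

conv_backward <- function(dY, layer, cache) {
  d <- cache$dims
  dim(dY) <- c(d[1L] * cache$Lo, ncol(layer$W))
  dW <- crossprod(cache$Xc, dY)
  dXc <- tcrossprod(dY, layer$W)
  dX <- cpp_col2im(dXc, d[1L], d[2L], d[3L], cache$k, cache$s)
  list(dX = dX, dW = dW)
}

bn_forward <- function(X, layer, training) {
  d <- dim(X)
  m <- d[1L] * d[2L]
  Xm <- X
  dim(Xm) <- c(m, d[3L])
  if (training) {
    st <- cpp_colstats(Xm)
    mu <- st$mean; v <- st$var
  } else {
    mu <- layer$run_mean; v <- layer$run_var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  ap <- cpp_bn_apply(Xm, mu, invstd, layer$gamma, layer$beta)
  Y <- ap$y
  dim(Y) <- d
  list(Y = Y, xhat = ap$xhat, invstd = invstd, mu = mu, v = v, d = d)
}

bn_backward <- function(dY, layer, cache) {
  d <- cache$d
  dim(dY) <- c(d[1L] * d[2L], d[3L])
  bk <- cpp_bn_backward(dY, cache$xhat, layer$gamma, cache$invstd)
  dX <- bk$dX
  dim(dX) <- d
  list(dX = dX, dgamma = bk$dgamma, dbeta = bk$dbeta)
}

maxpool_forward <- function(X, pool) {
  d <- dim(X)
  out <- cpp_maxpool(X, d[1L], d[2L], d[3L], pool)
  c(out, list(dims = d, pool = pool))
}

maxpool_backward <- function(dY, cache) {
  d <- cache$dims
  cpp_maxpool_backward(dY, cache$amax, d[1L], d[2L], d[3L], cache$pool)
}

avgpool_forward <- function(X, pool) {
  d <- dim(X); n <- d[1L]; L <- d[2L]; C <- d[3L]
  Lo <- L %/% pool
  Xt <- X[, seq_len(Lo * pool), , drop = FALSE]
  dim(Xt) <- c(n, pool, Lo, C)
  Y <- array(0, c(n, Lo, C))
  for (r in seq_len(pool)) {
    slab <- Xt[, r, , , drop = TRUE]
    dim(slab) <- c(n, Lo, C)
    Y <- Y + slab
  }
  list(Y = Y / pool, n = n, L = L, Lo = Lo, C = C, pool = pool)
}

avgpool_backward <- function(dY, cache) {
  n <- cache$n; Lo <- cache$Lo; C <- cache$C; pool <- cache$pool
  dXt <- array(0, c(n, pool, Lo, C))
  for (r in seq_len(pool)) dXt[, r, , ] <- dY / pool
  dim(dXt) <- c(n, pool * Lo, C)
  if (pool * Lo < cache$L) {
    dX <- array(0, c(n, cache$L, C))
    dX[, seq_len(pool * Lo), ] <- dXt
    dX
  } else {
    dXt
  }
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

model_forward <- function(model, X, training = FALSE) {
  caches <- vector("list", length(model$blocks))
  for (b in seq_along(model$blocks)) {
    layer <- model$blocks[[b]]
    cv <- conv_forward(X, layer)
    bn <- bn_forward(cv$Y, layer, training)
    mp <- maxpool_forward(bn$Y, layer$spec$pool_size)
    X <- mp$Y * (mp$Y > 0)
    caches[[b]] <- list(conv = cv, bn = bn, mp = mp, pooled = mp$Y)
  }
  ap <- avgpool_forward(X, model$config$avg_pool_size)
  flat <- ap$Y
  dim(flat) <- c(dim(flat)[1L], dim(flat)[2L] * dim(flat)[3L])
  if (training && model$config$dropout_rate > 0) {
    keep <- 1 - model$config$dropout_rate
    drop_mask <- matrix(stats::runif(length(flat)) < keep, nrow(flat)) / keep
    flat_d <- flat * drop_mask
  } else {
    drop_mask <- NULL
    flat_d <- flat
  }
  logits <- flat_d %*% model$dense$W +
    rep(model$dense$b, each = nrow(flat_d))
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits, caches = caches, avg = ap,
       flat = flat, flat_d = flat_d, drop_mask = drop_mask)
}

# cross-entropy gradient through the whole network; returns grads mirroring
# the parameter structure plus the batch loss (data term + L2 on dense W)
model_backward <- function(model, fwd, y_onehot) {
  n <- nrow(y_onehot)
  eps <- 1e-12
  data_loss <- -sum(y_onehot * log(fwd$probs + eps)) / n
  l2 <- model$config$l2_penalty
  loss <- data_loss + l2 * sum(model$dense$W^2)
  dlogits <- (fwd$probs - y_onehot) / n
  g_dense <- list(W = crossprod(fwd$flat_d, dlogits) + 2 * l2 * model$dense$W,
                  b = colSums(dlogits))
  dflat <- tcrossprod(dlogits, model$dense$W)
  if (!is.null(fwd$drop_mask)) dflat <- dflat * fwd$drop_mask
  ap <- fwd$avg
  dim(dflat) <- c(ap$n, ap$Lo, ap$C)
  dX <- avgpool_backward(dflat, ap)
  g_blocks <- vector("list", length(model$blocks))
  for (b in rev(seq_along(model$blocks))) {
    cache <- fwd$caches[[b]]
    dX <- cpp_relu_backward(dX, cache$pooled)
    dX <- maxpool_backward(dX, cache$mp)
    bn <- bn_backward(dX, model$blocks[[b]], cache$bn)
    cv <- conv_backward(bn$dX, model$blocks[[b]], cache$conv)
    g_blocks[[b]] <- list(W = cv$dW, gamma = bn$dgamma, beta = bn$dbeta)
    dX <- cv$dX
  }
  list(blocks = g_blocks, dense = g_dense, loss = loss)
}

adam_init <- function(model) {
  zero_like <- function(x) array(0, dim = if (is.null(dim(x))) length(x)
                                 else dim(x))
  pair <- function(x) list(m = zero_like(x), v = zero_like(x))
  list(t = 0L,
       blocks = lapply(model$blocks, function(l)
         list(W = pair(l$W), gamma = pair(l$gamma), beta = pair(l$beta))),
       dense = list(W = pair(model$dense$W), b = pair(model$dense$b)))
}

adam_update1 <- function(param, grad, slot, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  slot$m <- beta1 * slot$m + (1 - beta1) * grad
  slot$v <- beta2 * slot$v + (1 - beta2) * grad * grad
  mhat <- slot$m / (1 - beta1^t)
  vhat <- slot$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), slot = slot)
}

adam_step <- function(model, grads, state, lr) {
  state$t <- state$t + 1L
  t <- state$t
  for (b in seq_along(model$blocks)) {
    for (nm in c("W", "gamma", "beta")) {
      up <- adam_update1(model$blocks[[b]][[nm]], grads$blocks[[b]][[nm]],
                         state$blocks[[b]][[nm]], lr, t)
      model$blocks[[b]][[nm]] <- up$param
      state$blocks[[b]][[nm]] <- up$slot
    }
  }
  for (nm in c("W", "b")) {
    up <- adam_update1(model$dense[[nm]], grads$dense[[nm]],
                       state$dense[[nm]], lr, t)
    model$dense[[nm]] <- up$param
    state$dense[[nm]] <- up$slot
  }
  list(model = model, state = state)
}

update_running_stats <- function(model, fwd) {
  for (b in seq_along(model$blocks)) {
    bn <- fwd$caches[[b]]$bn
    model$blocks[[b]]$run_mean <- BN_MOMENTUM * model$blocks[[b]]$run_mean +
      (1 - BN_MOMENTUM) * bn$mu
    model$blocks[[b]]$run_var <- BN_MOMENTUM * model$blocks[[b]]$run_var +
      (1 - BN_MOMENTUM) * bn$v
  }
  model
}

# segment matrix (n x seg_len, raw ADC rows) -> network input array
segments_to_input <- function(samples, cfg) {
  X <- if (cfg$input_units == "mv") adc_to_millivolts(samples)
       else samples * 1.0
  dim(X) <- c(nrow(samples), ncol(samples), 1L)
  X
}

labels_to_onehot <- function(label) {
  label <- factor(as.character(label), levels = c("normal", "anomalous"))
  cbind(normal = as.numeric(label == "normal"),
        anomalous = as.numeric(label == "anomalous"))
}
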