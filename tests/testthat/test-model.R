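test_that("conv and pool output lengths match the published trace cells", {
  expect_equal(conv_output_length(5400, 80, 8), 666L)
  expect_equal(conv_output_length(166, 4, 1), 163L)
  expect_equal(pool_output_length(666, 4), 166L)
  expect_equal(pool_output_length(37, 4), 9L)
  expect_equal(pool_output_length(2, 2), 1L)
  expect_equal(conv_output_length(7, 7, 3), 1L)  # kernel spans input
  expect_error(conv_output_length(10, 11, 1), "infeasible")
})

test_that("length formulas agree with sliding-window enumeration", {
  for (L in 1:60) {
    for (k in unique(c(1:min(L, 10), L))) {
      for (s in 1:8) {
        # oracle: enumerate every start position fitting a full window
        starts <- seq(1L, L - k + 1L, by = s)
        expect_equal(conv_output_length(L, k, s), length(starts),
                     info = sprintf("L=%d k=%d s=%d", L, k, s))
      }
    }
    for (p in 1:6) {
      # oracle: non-overlapping full windows (none fit when p > L)
      expected <- if (p > L) 0L else length(seq(1L, L - p + 1L, by = p))
      expect_equal(pool_output_length(L, p), expected,
                   info = sprintf("L=%d p=%d", L, p))
    }
  }
})

table4_trace <- function() {
  list(c(666, 128), c(666, 128), c(166, 128), c(166, 128),
       c(163, 256), c(163, 256), c(40, 256), c(40, 256),
       c(37, 256), c(37, 256), c(9, 256), c(9, 256),
       c(8, 512), c(8, 512), c(2, 512), c(2, 512),
       c(1, 512))
}

test_that("the default configuration reproduces the published shape column", {
  tr <- shape_trace(model_config())
  conv_rows <- tr[!is.na(tr$length), ]
  expected <- table4_trace()
  expect_equal(nrow(conv_rows), length(expected))
  for (i in seq_along(expected)) {
    expect_equal(c(conv_rows$length[i], conv_rows$channels[i]), expected[[i]],
                 info = conv_rows$layer[i], ignore_attr = TRUE)
  }
  expect_equal(tr$channels[tr$layer == "flatten"], 512L)
  expect_equal(tr$channels[tr$layer == "dense"], 2L)
})

test_that("infeasible architectures error naming the collapsing layer", {
  expect_error(
    model_config(input_length = 80,
                 blocks = list(conv_block_spec(80, 8, 128, 4))),
    "max_pool_1")
})

test_that("shape_trace equals stepwise recomputation on random configs", {
  set.seed(11)
  for (i in 1:20) {
    n_blocks <- sample(1:3, 1)
    blocks <- list()
    len <- sample(200:2000, 1)
    L <- len
    ok <- TRUE
    for (b in seq_len(n_blocks)) {
      k <- sample(2:20, 1); s <- sample(1:4, 1)
      f <- sample(c(4, 8, 16), 1); p <- sample(2:4, 1)
      blocks[[b]] <- conv_block_spec(k, s, f, p)
      if (k > L) { ok <- FALSE; break }
      L <- (L - k) %/% s + 1
      L <- L %/% p
      if (L < 1) { ok <- FALSE; break }
    }
    if (!ok || L < 2) next
    cfg <- model_config(input_length = len, blocks = blocks,
                        avg_pool_size = 2)
    tr <- shape_trace(cfg)
    # oracle: final max-pool row equals the stepwise L computed above
    expect_equal(tr$length[tr$layer == sprintf("max_pool_%d", n_blocks)], L)
    expect_equal(tr$length[tr$layer == "avg_pool"], L %/% 2)
  }
})

test_that("forward pass emits probability rows and honors the trace", {
  cfg <- tiny_model_config(seg_len = 240)
  m <- build_model(cfg, seed = 4)
  set.seed(8)
  x <- matrix(sample(0:2047, 3 * 240, TRUE), 3)
  fwd <- ecgscreen:::model_forward(
    m, ecgscreen:::segments_to_input(x, cfg), training = FALSE)
  expect_equal(dim(fwd$probs), c(3, 2))
  expect_true(all(fwd$probs >= 0))
  expect_equal(rowSums(fwd$probs), rep(1, 3), tolerance = 1e-6)
  # per-layer tensor shapes equal the declared trace
  tr <- shape_trace(cfg)
  for (b in seq_along(m$blocks)) {
    got <- dim(fwd$caches[[b]]$conv$Y)
    expect_equal(got[2:3],
                 unlist(tr[tr$layer == sprintf("conv1d_%d", b),
                           c("length", "channels")]),
                 ignore_attr = TRUE)
    got_pool <- dim(fwd$caches[[b]]$mp$Y)
    expect_equal(got_pool[2:3],
                 unlist(tr[tr$layer == sprintf("max_pool_%d", b),
                           c("length", "channels")]),
                 ignore_attr = TRUE)
  }
  expect_equal(ncol(fwd$flat), tr$channels[tr$layer == "flatten"])
})

test_that("softmax on a batch of zeros is uniform and rows sum to one", {
  cfg <- tiny_model_config(seg_len = 240)
  m <- build_model(cfg, seed = 4)
  x <- array(0, c(2, 240, 1))
  fwd <- ecgscreen:::model_forward(m, x, training = FALSE)
  expect_equal(rowSums(fwd$probs), rep(1, 2), tolerance = 1e-9)
  # identical inputs give identical rows
  expect_equal(fwd$probs[1, ], fwd$probs[2, ])
})

test_that("inference is deterministic (dropout off outside training)", {
  cfg <- tiny_model_config(seg_len = 240)
  m <- build_model(cfg, seed = 4)
  set.seed(1)
  x <- ecgscreen:::segments_to_input(
    matrix(sample(0:2047, 2 * 240, TRUE), 2), cfg)
  p1 <- ecgscreen:::model_forward(m, x, training = FALSE)$probs
  p2 <- ecgscreen:::model_forward(m, x, training = FALSE)$probs
  expect_identical(p1, p2)
})

test_that("backward gradients match central finite differences", {
  cfg <- model_config(input_length = 60,
                      blocks = list(conv_block_spec(8, 2, 3, 2),
                                    conv_block_spec(3, 1, 4, 2)),
                      avg_pool_size = 2, dropout_rate = 0,
                      l2_penalty = 0.001)
  m <- build_model(cfg, seed = 7)
  set.seed(42)
  X <- array(rnorm(5 * 60), c(5, 60, 1))
  y <- ecgscreen:::labels_to_onehot(
    c("normal", "anomalous", "normal", "anomalous", "normal"))
  loss_at <- function(mm) {
    fwd <- ecgscreen:::model_forward(mm, X, training = TRUE)
    -sum(y * log(fwd$probs + 1e-12)) / nrow(y) +
      cfg$l2_penalty * sum(mm$dense$W^2)
  }
  fwd <- ecgscreen:::model_forward(m, X, training = TRUE)
  bwd <- ecgscreen:::model_backward(m, fwd, y)
  eps <- 1e-6
  check_param <- function(path, grad) {
    p <- m[[path[1]]]
    if (length(path) == 3) p <- p[[path[2]]][[path[3]]] else p <- p[[path[2]]]
    ii <- sample(length(p), min(5, length(p)))
    for (i in ii) {
      bump <- function(delta) {
        mm <- m
        if (length(path) == 3) mm[[path[1]]][[path[2]]][[path[3]]][i] <-
            mm[[path[1]]][[path[2]]][[path[3]]][i] + delta
        else mm[[path[1]]][[path[2]]][i] <- mm[[path[1]]][[path[2]]][i] + delta
        mm
      }
      num <- (loss_at(bump(eps)) - loss_at(bump(-eps))) / (2 * eps)
      expect_equal(unname(grad[i]), num, tolerance = 1e-4,
                   info = paste(path, collapse = "$"))
    }
  }
  set.seed(9)
  check_param(c("blocks", 1, "W"), bwd$blocks[[1]]$W)
  check_param(c("blocks", 2, "W"), bwd$blocks[[2]]$W)
  check_param(c("blocks", 1, "gamma"), bwd$blocks[[1]]$gamma)
  check_param(c("blocks", 2, "beta"), bwd$blocks[[2]]$beta)
  check_param(c("dense", "W"), bwd$dense$W)
  check_param(c("dense", "b"), bwd$dense$b)
})

test_that("compiled conv kernels agree with direct convolution", {
  set.seed(5)
  n <- 3; L <- 30; C <- 2; k <- 5; s <- 3
  X <- array(rnorm(n * L * C), c(n, L, C))
  W <- matrix(rnorm(k * C * 4), k * C, 4)
  layer <- list(spec = list(kernel_size = k, stride = s), W = W)
  Y <- ecgscreen:::conv_forward(X, layer)$Y
  # oracle: loop over output positions and filters
  Lo <- (L - k) %/% s + 1
  for (i in 1:n) for (t in 1:Lo) for (f in 1:4) {
    patch <- as.vector(X[i, (t - 1) * s + 1:k, ])  # (j, c) order
    expect_equal(Y[i, t, f], sum(patch * W[, f]), tolerance = 1e-12)
  }
})

test_that("compiled max-pool kernel matches blockwise max and routes ties", {
  set.seed(6)
  X <- array(rnorm(2 * 13 * 3), c(2, 13, 3))
  out <- ecgscreen:::maxpool_forward(X, 4)
  expect_equal(dim(out$Y), c(2, 3, 3))
  for (i in 1:2) for (t in 1:3) for (c in 1:3) {
    expect_equal(out$Y[i, t, c], max(X[i, (t - 1) * 4 + 1:4, c]))
  }
  # ties keep the earliest position
  Xt <- array(1, c(1, 4, 1))
  o2 <- ecgscreen:::maxpool_forward(Xt, 4)
  g <- ecgscreen:::maxpool_backward(array(7, c(1, 1, 1)), o2)
  expect_equal(as.vector(g), c(7, 0, 0, 0))
})
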