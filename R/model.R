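# Declarative architecture of the four-block 1D CNN and its layer-shape
# calculus. Convolutions are "valid" (no padding), pooling is non-overlapping
# (stride = pool size); both conventions are forced by the published output
# shapes (5400 -> 666 with kernel 80 / stride 8; 666 -> 166 with pool 4).

#' Output length of a valid (unpadded) 1D convolution
#'
#' @param length input length in samples.
#' @param kernel kernel size; must not exceed `length`.
#' @param stride stride (default 1).
#' @return `floor((length - kernel) / stride) + 1`.
#' @examples
#' conv_output_length(5400, 80, 8)  # 666
#' @export
conv_output_length <- function(length, kernel, stride = 1L) {
  stopifnot(length >= 1, kernel >= 1, stride >= 1)
  if (kernel > length) {
    stop(sprintf("kernel %d exceeds input length %d: architecture infeasible",
                 kernel, length), call. = FALSE)
  }
  as.integer((length - kernel) %/% stride + 1L)
}

#' Output length of non-overlapping 1D pooling
#'
#' @param length input length.
#' @param pool pool size (stride equals pool size).
#' @return `floor(length / pool)`.
#' @examples
#' pool_output_length(666, 4)  # 166
#' @export
pool_output_length <- function(length, pool) {
  stopifnot(length >= 0, pool >= 1)
  as.integer(length %/% pool)
}

#' One convolutional block specification
#'
#' A block is Conv1D -> BatchNorm -> MaxPool -> ReLU, in that order (batch
#' normalization standardizes the convolution output before pooling; the
#' pooling precedes the nonlinearity).
#'
#' @param kernel_size convolution kernel width in samples.
#' @param stride convolution stride (default 1).
#' @param filters number of output channels.
#' @param pool_size max-pool window (pool stride equals pool size).
#' @return An object of class `conv_block_spec`.
#' @export
conv_block_spec <- function(kernel_size, stride = 1L, filters, pool_size) {
  stopifnot(kernel_size >= 1, stride >= 1, filters >= 1, pool_size >= 1)
  structure(list(kernel_size = as.integer(kernel_size),
                 stride = as.integer(stride),
                 filters = as.integer(filters),
                 pool_size = as.integer(pool_size),
                 activation = "relu"),
            class = "conv_block_spec")
}

default_blocks <- function() {
  # block 4 kernel is 2, forced by its published output shape (9 -> 8 under
  # valid convolution); kernel 4 there would collapse the head to length 0
  list(conv_block_spec(80L, 8L, 128L, 4L),
       conv_block_spec(4L, 1L, 256L, 4L),
       conv_block_spec(4L, 1L, 256L, 4L),
       conv_block_spec(2L, 1L, 512L, 4L))
}

#' Full model configuration
#'
#' Defaults reproduce the published four-block architecture for 15-s
#' single-lead segments: input (5400; 1), blocks (80,8,128,4), (4,1,256,4),
#' (4,1,256,4), (2,1,512,4), then AvgPool(2) -> Flatten -> Dropout(0.6) ->
#' Dense(2, L2 = 0.001) with a softmax over (normal, anomalous).
#'
#' @param input_length segment length in samples (default 5400).
#' @param blocks list of [conv_block_spec()]s.
#' @param avg_pool_size head average-pool window (default 2).
#' @param dropout_rate dropout fraction in the dense head (default 0.6).
#' @param l2_penalty L2 weight penalty on the dense layer (default 0.001).
#' @param n_classes number of output classes (default 2).
#' @param input_units `"mv"` to feed millivolt-converted samples (default) or
#'   `"adc"` to feed raw ADC codes; the first batch-norm absorbs scale either
#'   way.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_length = 5400L, blocks = default_blocks(),
                         avg_pool_size = 2L, dropout_rate = 0.6,
                         l2_penalty = 0.001, n_classes = 2L,
                         input_units = c("mv", "adc")) {
  input_units <- match.arg(input_units)
  stopifnot(input_length >= 1, length(blocks) >= 1,
            all(vapply(blocks, inherits, logical(1L), "conv_block_spec")),
            avg_pool_size >= 1, dropout_rate >= 0, dropout_rate < 1,
            l2_penalty >= 0, n_classes >= 2)
  cfg <- structure(list(input_length = as.integer(input_length),
                        input_channels = 1L,
                        blocks = blocks,
                        avg_pool_size = as.integer(avg_pool_size),
                        dropout_rate = dropout_rate,
                        l2_penalty = l2_penalty,
                        n_classes = as.integer(n_classes),
                        input_units = input_units),
                   class = "model_config")
  shape_trace(cfg)  # errors now if any layer collapses to length <= 0
  cfg
}

#' Per-layer (length, channels) trace of a configuration
#'
#' Walks the architecture layer by layer and reports the output shape after
#' every layer, exactly as a framework summary would. Errors (naming the
#' layer) if any intermediate length reaches zero.
#'
#' @param cfg a [model_config()].
#' @return A data frame with columns `layer`, `length`, `channels`; the
#'   flatten and dense rows use `length = NA` and put the width in
#'   `channels`.
#' @export
shape_trace <- function(cfg) {
  stopifnot(inherits(cfg, "model_config") || is.list(cfg))
  len <- cfg$input_length
  ch <- cfg$input_channels
  rows <- list()
  add <- function(layer, length, channels) {
    rows[[length(rows) + 1L]] <<- data.frame(layer = layer, length = length,
                                             channels = channels)
  }
  check <- function(len, layer) {
    if (len < 1L) {
      stop(sprintf("layer '%s' collapses the signal to length %d: %s", layer,
                   len, "architecture infeasible for this input length"),
           call. = FALSE)
    }
    len
  }
  for (b in seq_along(cfg$blocks)) {
    blk <- cfg$blocks[[b]]
    len <- conv_output_length(len, blk$kernel_size, blk$stride)
    ch <- blk$filters
    add(sprintf("conv1d_%d", b), check(len, sprintf("conv1d_%d", b)), ch)
    add(sprintf("batch_norm_%d", b), len, ch)
    len <- check(pool_output_length(len, blk$pool_size),
                 sprintf("max_pool_%d", b))
    add(sprintf("max_pool_%d", b), len, ch)
    add(sprintf("relu_%d", b), len, ch)
  }
  len <- check(pool_output_length(len, cfg$avg_pool_size), "avg_pool")
  add("avg_pool", len, ch)
  add("flatten", NA_integer_, len * ch)
  add("dropout", NA_integer_, len * ch)
  add("dense", NA_integer_, cfg$n_classes)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.model_config <- function(x, ...) {
  tr <- shape_trace(x)
  cat(sprintf("<model_config> input (%d;%d), %d conv blocks, %d classes\n",
              x$input_length, x$input_channels, length(x$blocks), x$n_classes))
  for (i in seq_len(nrow(tr))) {
    shp <- if (is.na(tr$length[i])) sprintf("(%d)", tr$channels[i])
           else sprintf("(%d;%d)", tr$length[i], tr$channels[i])
    cat(sprintf("  %-14s %s\n", tr$layer[i], shp))
  }
  invisible(x)
}

glorot_uniform <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

#' Instantiate a trainable network from a configuration
#'
#' Allocates and seeds all parameters: convolution kernels and biases
#' (Glorot-uniform / zero), batch-norm scale, shift and running moments, and
#' the dense head. The returned handle is consumed by [train_network()] and
#' [predict_segments()].
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `ecg_cnn`.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  shape_trace(cfg)  # validate feasibility
  with_seed(seed, {
    layers <- list()
    ch_in <- cfg$input_channels
    for (b in seq_along(cfg$blocks)) {
      blk <- cfg$blocks[[b]]
      k <- blk$kernel_size
      f <- blk$filters
      # no conv bias: the batch-norm shift that follows absorbs it
      layers[[b]] <- list(
        spec = blk,
        W = glorot_uniform(k * ch_in, f, c(k * ch_in, f)),
        gamma = rep(1, f), beta = numeric(f),
        run_mean = numeric(f), run_var = rep(1, f))
      ch_in <- f
    }
    tr <- shape_trace(cfg)
    flat <- tr$channels[tr$layer == "flatten"]
    dense <- list(W = glorot_uniform(flat, cfg$n_classes,
                                     c(flat, cfg$n_classes)),
                  b = numeric(cfg$n_classes))
    structure(list(config = cfg, blocks = layers, dense = dense,
                   classes = c("normal", "anomalous")[seq_len(min(2L, cfg$n_classes))],
                   seed = seed, trained = FALSE),
              class = "ecg_cnn")
  })
}

#' @export
print.ecg_cnn <- function(x, ...) {
  n_par <- sum(vapply(x$blocks, function(l)
    length(l$W) + 2L * length(l$gamma), numeric(1L))) +
    length(x$dense$W) + length(x$dense$b)
  cat(sprintf("<ecg_cnn> %d conv blocks, %s parameters (%strained)\n",
              length(x$blocks), format(n_par, big.mark = ","),
              if (x$trained) "" else "un"))
  invisible(x)
}
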