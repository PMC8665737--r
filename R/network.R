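## Full base-calling network: C-type blocks, residual blocks and a decoder
## emitting per-frame posteriors over {A, C, G, T, blank}.

BASES <- c("A", "C", "G", "T")
CHANNELS <- c(BASES, "-")   # blank is index 5

#' Model configuration
#'
#' Declarative description of the network: an ordered list of block specs.
#' The `"small"` preset (the training default) is a stride-3 full-convolution
#' C block (`in_channels` to 32 channels, depth 9), two compressed residual
#' blocks (C = 32, D = 15, k = 3, R = 3, ratio 3:2), two separable C blocks
#' and a decoder.  The `"full"` preset follows the three-C/five-residual
#' topology with 64 channels and R = 5.  All values can be overridden by
#' editing the returned object or a YAML file (see [read_model_config()]).
#'
#' @param preset `"small"` (the training default), `"tiny"` (a reduced
#'   stack for quick experiments) or `"full"`.
#' @param in_channels input channels (1 for plain signal, 2 with the
#'   diagnostic event-boundary channel).
#' @param k fat-pointwise depth of the k-blueprint-separable convolutions.
#' @param compression integer pair `c(x, y)`: the depth-to-space ratio.
#' @return an object of class `model_config`.
#' @export
model_config <- function(preset = c("small", "tiny", "full"),
                         in_channels = 1L,
                         k = 3L, compression = c(3L, 2L)) {
  preset <- match.arg(preset)
  x <- as.integer(compression[1L]); y <- as.integer(compression[2L])
  blocks <- if (preset == "tiny") {
    list(list(type = "c", cin = in_channels, cout = 16L, depth = 9L,
              stride = 3L, conv = "full"),
         list(type = "res", channels = 16L, depth = 15L, repeats = 3L,
              compressed = TRUE),
         list(type = "c", cin = 16L, cout = 16L, depth = 9L, stride = 1L,
              conv = "separable"),
         list(type = "decoder", cin = 16L))
  } else if (preset == "small") {
    c(list(list(type = "c", cin = in_channels, cout = 32L, depth = 9L,
                stride = 3L, conv = "full")),
      rep(list(list(type = "res", channels = 32L, depth = 15L, repeats = 3L,
                    compressed = TRUE)), 2L),
      list(list(type = "c", cin = 32L, cout = 32L, depth = 9L, stride = 1L,
                conv = "separable"),
           list(type = "c", cin = 32L, cout = 32L, depth = 5L, stride = 1L,
                conv = "separable"),
           list(type = "decoder", cin = 32L)))
  } else {
    c(list(list(type = "c", cin = in_channels, cout = 64L, depth = 9L,
                stride = 3L, conv = "full")),
      rep(list(list(type = "res", channels = 64L, depth = 15L, repeats = 5L,
                    compressed = TRUE)), 5L),
      list(list(type = "c", cin = 64L, cout = 64L, depth = 11L, stride = 1L,
                conv = "separable"),
           list(type = "c", cin = 64L, cout = 64L, depth = 7L, stride = 1L,
                conv = "separable"),
           list(type = "decoder", cin = 64L)))
  }
  structure(list(k = k, x = x, y = y, in_channels = as.integer(in_channels),
                 blocks = blocks, preset = preset),
            class = "model_config")
}

validate_model_config <- function(cfg) {
  if (length(cfg$blocks) == 0L) stop("model_config: no blocks")
  chain <- cfg$in_channels
  for (i in seq_along(cfg$blocks)) {
    b <- cfg$blocks[[i]]
    cin <- switch(b$type, c = b$cin, res = b$channels, decoder = b$cin,
                  stop(sprintf("model_config: unknown block type '%s' (block %d)",
                               b$type, i)))
    if (cin != chain)
      stop(sprintf(
        "model_config: block %d ('%s') expects %d input channels but receives %d",
        i, b$type, cin, chain))
    chain <- switch(b$type, c = b$cout, res = b$channels, decoder = 5L)
    if (b$type == "decoder" && !is.null(b$out) && b$out != 5L)
      stop("model_config: decoder must emit 5 channels (A, C, G, T, blank)")
    if (b$type == "decoder" && i != length(cfg$blocks))
      stop("model_config: decoder must be the final block")
  }
  last <- cfg$blocks[[length(cfg$blocks)]]
  if (last$type != "decoder")
    stop("model_config: final block must be the decoder (5 output channels)")
  invisible(cfg)
}

#' Read / write a model configuration as YAML
#'
#' @param path file path.
#' @param cfg a [model_config()] object.
#' @return `read_model_config` returns a validated `model_config`.
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- structure(list(k = as.integer(raw$k), x = as.integer(raw$compression[1]),
                        y = as.integer(raw$compression[2]),
                        in_channels = as.integer(raw$in_channels),
                        blocks = raw$blocks, preset = raw$preset %||% "custom"),
                   class = "model_config")
  validate_model_config(cfg)
}

#' @rdname read_model_config
#' @export
write_model_config <- function(cfg, path) {
  yaml::write_yaml(list(k = cfg$k, compression = c(cfg$x, cfg$y),
                        in_channels = cfg$in_channels, preset = cfg$preset,
                        blocks = cfg$blocks), path)
  invisible(path)
}

block_to_tree <- function(b, cfg) {
  switch(b$type,
    c = build_c_block_tree(c_block_config(b$cin, b$cout, b$depth, b$stride,
                                          b$conv, cfg$k)),
    res = build_residual_tree(residual_block_config(
      b$channels, b$depth, b$repeats, k = cfg$k, x = cfg$x, y = cfg$y,
      compressed = isTRUE(b$compressed))),
    decoder = layer_seq(list(layer_pointwise(matrix(0, 5L, b$cin), rep(0, 5L)),
                             layer_logsoftmax())))
}

tree_receptive_radius <- function(layer, stride_in = 1L) {
  ## crude upper bound on the receptive radius in input samples
  r <- 0L
  walk <- function(l, s) {
    if (l$type == "conv") {
      r <<- r + (dim(l$par$W)[2L] %/% 2L) * s
      s * l$stride
    } else if (l$type == "depthwise") {
      r <<- r + (nrow(l$par$W) %/% 2L) * l$dilation * s
      s
    } else if (l$type == "compress") {
      s * l$stride
    } else if (l$type == "decompress") {
      ceiling(s / l$stride)
    } else if (l$type == "seq") {
      for (ll in l$layers) s <- walk(ll, s)
      s
    } else if (l$type == "res") {
      walk(l$main, s)
      s
    } else s
  }
  walk(layer, stride_in)
  r
}

#' Build a base-calling model
#'
#' Instantiates and initializes all parameters of the network described by
#' `cfg`.  The reported parameter count equals the closed-form layer sums of
#' [count_params_and_flops()].  Deterministic given `seed`.
#'
#' @param cfg a [model_config()].
#' @param init an [identity_init_spec()]; disable both families for a pure
#'   Glorot baseline.
#' @param seed integer RNG seed.
#' @return an object of class `basecall_model` with elements `cfg`, `net`
#'   (the parameter tree), `n_params`, `stride` (total down-sampling factor)
#'   and `min_input_len`.
#' @export
build_model <- function(cfg, init = identity_init_spec(), seed = 1L) {
  validate_model_config(cfg)
  trees <- lapply(cfg$blocks, block_to_tree, cfg = cfg)
  net <- layer_seq(trees)
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  net <- init_tree(net, init)
  stride <- 1L
  for (b in cfg$blocks) if (b$type == "c") stride <- stride * b$stride
  ## windows shifted by a multiple of stride * x keep the depth-to-space
  ## grouping phase; chunked inference must respect this period
  lcm2 <- function(a, b) a * b / gcd2(a, b)
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  period <- stride
  for (b in cfg$blocks)
    if (b$type == "res" && isTRUE(b$compressed))
      period <- lcm2(period, stride * cfg$x)
  radius <- tree_receptive_radius(net)
  structure(list(cfg = cfg, net = net,
                 n_params = sum(lengths(collect_params(net))),
                 stride = stride,
                 shift_period = as.integer(period),
                 receptive_radius = radius,
                 min_input_len = max(stride, 2L * radius + 1L)),
            class = "basecall_model")
}

#' @export
print.basecall_model <- function(x, ...) {
  cat(sprintf("<basecall_model> %s preset: %d blocks, %s parameters\n",
              x$cfg$preset, length(x$cfg$blocks),
              format(x$n_params, big.mark = ",")))
  cat(sprintf("  input channels: %d, total stride: %d, receptive radius: ~%d samples\n",
              x$cfg$in_channels, x$stride, x$receptive_radius))
  invisible(x)
}

#' Run the network on a signal window
#'
#' Maps a normalized signal of length `T` to a posterior matrix of
#' `ceiling(T / stride)` rows, each a probability distribution over
#' A, C, G, T, blank (rows sum to 1).
#'
#' @param model a [build_model()] result.
#' @param signal numeric vector (or `(T, in_channels)` matrix) of normalized
#'   signal; see [normalize_signal()].
#' @param mode `"infer"` (stored running batch-norm statistics),
#'   `"instance"` (read-adaptive: statistics of this input, state untouched)
#'   or `"train"` (batch statistics, running state updated).
#' @param log return log-posteriors instead of probabilities.
#' @return a `(T', 5)` matrix; columns named A, C, G, T, `-`.
#' @export
forward_signal <- function(model, signal,
                           mode = c("infer", "instance", "train"),
                           log = FALSE) {
  mode <- match.arg(mode)
  x <- as_time_channel(signal)
  check_channels(x, model$cfg$in_channels, "forward_signal")
  if (nrow(x) < model$min_input_len)
    stop(sprintf("forward_signal: signal length %d below minimum %d",
                 nrow(x), model$min_input_len))
  lp <- layer_forward(model$net, x, training = (mode == "train"),
                      instance = (mode == "instance"))$y
  out <- if (log) lp else exp(lp)
  colnames(out) <- CHANNELS
  out
}

#' Decoder block: logits to posteriors
#'
#' A pointwise convolution to five channels followed by a row-wise softmax.
#' Exposed standalone so the posterior contract can be tested in isolation.
#'
#' @param x `(T', Cin)` matrix of decoder inputs.
#' @param p [pointwise_params()] with 5 output channels.
#' @param log return log-probabilities.
#' @return a `(T', 5)` posterior (or log-posterior) matrix.
#' @export
decoder_block <- function(x, p, log = FALSE) {
  stopifnot(inherits(p, "pointwise_params"), nrow(p$W) == 5L)
  z <- pointwise_conv(x, p)
  m <- apply(z, 1L, max)
  lp <- z - m - log(rowSums(exp(z - m)))
  out <- if (log) lp else exp(lp)
  colnames(out) <- CHANNELS
  out
}

#' Chunked inference for long signals
#'
#' Splits a long signal into overlapping windows, runs [forward_signal()] on
#' each and stitches the posteriors, discarding half of each overlap.  On
#' signals shorter than the window this equals the unchunked forward pass.
#'
#' @param model a [build_model()] result.
#' @param signals a list of numeric signals (a single vector is accepted).
#' @param window window length in samples.  Both the window and the
#'   window-to-window step are rounded to multiples of the model's shift
#'   period (`stride * x`), which keeps the depth-to-space grouping phase
#'   identical across windows.
#' @param overlap overlap between consecutive windows in samples; default 5%
#'   of the window (rounded up to the period).  Must satisfy
#'   `window > 2 * overlap`.
#' @return a list of posterior matrices.
#' @export
batch_forward <- function(model, signals, window = 3000L,
                          overlap = ceiling(0.05 * window)) {
  if (!is.list(signals)) signals <- list(signals)
  s <- model$stride
  per <- model$shift_period
  window <- max(per, as.integer(window %/% per) * per)
  step <- max(per, as.integer((window - overlap) %/% per) * per)
  overlap <- window - step
  if (window <= 2L * overlap)
    stop("batch_forward: window must exceed twice the overlap")
  lapply(signals, function(sig) {
    x <- as_time_channel(sig)
    T_ <- nrow(x)
    if (T_ <= window) return(forward_signal(model, x))
    starts <- seq(1L, T_, by = step)
    starts <- starts[starts <= T_ - overlap | starts == 1L]
    pieces <- list()
    half <- overlap %/% 2L %/% s
    for (ii in seq_along(starts)) {
      a <- starts[ii]
      b <- min(T_, a + window - 1L)
      post <- forward_signal(model, x[a:b, , drop = FALSE])
      lo <- if (ii == 1L) 1L else half + 1L
      hi <- if (b == T_) nrow(post) else nrow(post) - (overlap %/% s - half)
      pieces[[ii]] <- post[lo:hi, , drop = FALSE]
      if (b == T_) break
    }
    do.call(rbind, pieces)
  })
}

## ---- serialization -------------------------------------------------------

#' Save / load model weights
#'
#' Writes a single JSON archive holding every named tensor (trainable
#' parameters and batch-norm running statistics) with a manifest of names,
#' shapes and layer kinds.  Values are printed with 17 significant digits,
#' which round-trips IEEE doubles bit-exactly.
#'
#' @param model a [build_model()] result.
#' @param path output file.
#' @return `load_model` returns the restored `basecall_model`.
#' @export
save_model <- function(model, path) {
  pars <- collect_params(model$net)
  st <- collect_state(model$net)
  all <- c(pars, st)
  manifest <- lapply(names(all), function(nm) {
    v <- all[[nm]]
    list(name = nm, shape = if (is.null(dim(v))) length(v) else dim(v),
         kind = if (grepl("\\.state\\.", nm)) "state" else "param")
  })
  payload <- list(
    format = "nanocallr-weights-v1",
    config = list(k = model$cfg$k, compression = c(model$cfg$x, model$cfg$y),
                  in_channels = model$cfg$in_channels,
                  preset = model$cfg$preset, blocks = model$cfg$blocks),
    manifest = manifest,
    tensors = lapply(all, function(v) sprintf("%.17g", as.numeric(v))))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                                simplifyVector = FALSE)
  if (!identical(payload$format, "nanocallr-weights-v1"))
    stop("load_model: unrecognized weight archive format")
  pc <- payload$config
  cfg <- structure(list(k = as.integer(pc$k),
                        x = as.integer(pc$compression[[1]]),
                        y = as.integer(pc$compression[[2]]),
                        in_channels = as.integer(pc$in_channels),
                        blocks = lapply(pc$blocks, function(b)
                          lapply(b, function(v)
                            if (is.character(v) || is.logical(v)) v
                            else as.integer(v))),
                        preset = pc$preset),
                   class = "model_config")
  model <- build_model(cfg, identity_init_spec(0), seed = 0L)
  values <- lapply(payload$tensors, function(s)
    as.numeric(vapply(s, identity, character(1))))
  model$net <- restore_tree(model$net, values)
  model
}
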