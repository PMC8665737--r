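## Composite network blocks: C-type (conv + batch norm + activation),
## the classical residual block, and the compressed residual block with
## depth-to-space compression, plus identity initialization.

round_to_odd <- function(x) {
  lo <- 2L * floor((x - 1) / 2) + 1L
  hi <- lo + 2L
  if (abs(x - lo) <= abs(hi - x)) max(1L, as.integer(lo)) else as.integer(hi)
}

smallest_odd_geq <- function(x) {
  q <- ceiling(x)
  if (q %% 2L == 0L) q <- q + 1L
  max(1L, as.integer(q))
}

#' C-type block configuration
#'
#' A C-type block is a convolutional layer followed by batch normalization
#' and a Swish activation.  A stride `s` reduces the length to
#' `ceiling(T / s)`.
#'
#' @param Cin,Cout input and output channel counts.
#' @param depth convolution receptive depth `D`.
#' @param stride positive integer stride (full convolutions only).
#' @param conv one of `"full"`, `"separable"`, `"k_blueprint_separable"`.
#' @param k fat-pointwise depth for the k-blueprint-separable kind.
#' @return an object of class `c_block_config`.
#' @export
c_block_config <- function(Cin, Cout, depth, stride = 1L,
                           conv = c("full", "separable",
                                    "k_blueprint_separable"),
                           k = 3L) {
  conv <- match.arg(conv)
  stopifnot(depth >= 1L, stride >= 1L)
  if (conv != "full" && stride != 1L)
    stop("c_block_config: stride > 1 is only supported for full convolutions")
  structure(list(Cin = as.integer(Cin), Cout = as.integer(Cout),
                 depth = as.integer(depth), stride = as.integer(stride),
                 conv = conv, k = as.integer(k)),
            class = "c_block_config")
}

#' Residual block configuration
#'
#' Describes both the classical residual block (`compressed = FALSE`): `R`
#' repeats of a separable-convolution sub-block with a pointwise + batch-norm
#' skip connection; and the compressed variant (`compressed = TRUE`), where
#' the first and last separable convolutions are replaced by a
#' depth-to-space compression/decompression pair with ratio `x:y`
#' (`(T, C)` to `(T/x, C*y)`), the `R - 2` inner convolutions are
#' k-blueprint-separable at the compressed resolution with depth reduced by
#' a factor of `x`, and one depthwise operation precedes the decompression.
#'
#' @param C channel count at the block boundary.
#' @param depth receptive depth `D` at the block's input resolution.
#' @param repeats repeat count `R`; must be `>= 3` when compressed so that
#'   `R - 2 >= 1` inner convolutions remain.
#' @param k fat-pointwise depth of the inner convolutions.
#' @param x,y depth-to-space compression ratio terms (`x` timesteps of `C`
#'   channels become one timestep of `C * y` channels).
#' @param compressed use the compressed design.
#' @return an object of class `residual_block_config`.
#' @export
residual_block_config <- function(C, depth = 15L, repeats = 5L, k = 3L,
                                  x = 3L, y = 2L, compressed = TRUE) {
  stopifnot(x >= 1L, y >= 1L, depth >= 1L)
  if (compressed && repeats < 3L)
    stop("residual_block_config: compressed blocks need repeats >= 3")
  if (!compressed && repeats < 1L)
    stop("residual_block_config: repeats must be >= 1")
  Cy <- C * y
  if (Cy != round(Cy)) stop("residual_block_config: C * y is not an integer")
  structure(list(C = as.integer(C), depth = as.integer(depth),
                 repeats = as.integer(repeats), k = as.integer(k),
                 x = as.integer(x), y = as.integer(y),
                 Cy = as.integer(Cy),
                 ratio = x / y,
                 compressed = isTRUE(compressed)),
            class = "residual_block_config")
}

#' Identity initialization specification
#'
#' Within the compressed main branch, depthwise kernels are initialized to a
#' centred delta (`W[d, j] = 1` iff `d = floor((D/k)/2)`) and fat-pointwise
#' kernels to a centred identity plus uniform noise
#' (`W[j, d, i] = delta(center, d) * (delta(i, j) + U(-epsilon, epsilon))`),
#' with all biases zero, so each inner sub-block starts as a (near-)identity
#' map.  All other layers fall back to Glorot-uniform initialization with
#' bound `sqrt(6 / (Cin + Cout))`.
#'
#' @param epsilon non-negative half-width of the uniform perturbation.
#' @param depthwise,fat_pointwise logical; apply the identity scheme to that
#'   kernel family (disabled families use the Glorot fallback).
#' @return an object of class `identity_init_spec`.
#' @export
identity_init_spec <- function(epsilon = 0.02, depthwise = TRUE,
                               fat_pointwise = TRUE) {
  stopifnot(epsilon >= 0)
  structure(list(epsilon = epsilon,
                 enabled_for = c(depthwise = isTRUE(depthwise),
                                 fat_pointwise = isTRUE(fat_pointwise))),
            class = "identity_init_spec")
}

glorot_bound <- function(Cin, Cout) sqrt(6 / (Cin + Cout))

## ---- layer-tree builders (zero-initialized; init fills weights) ----------

build_conv_layers <- function(kind, Cin, Cout, depth, stride = 1L, k = 3L,
                              role = "plain") {
  switch(kind,
    full = {
      l <- layer_conv(array(0, c(Cout, depth, Cin)), rep(0, Cout), stride)
      l$init_role <- role
      list(l)
    },
    separable = {
      dw <- layer_depthwise(matrix(0, depth, Cin), rep(0, Cin), 1L)
      pw <- layer_pointwise(matrix(0, Cout, Cin), rep(0, Cout))
      dw$init_role <- role; pw$init_role <- role
      list(dw, pw)
    },
    k_blueprint_separable = {
      if (depth %% k != 0L)
        stop(sprintf("k-blueprint-separable depth %d not divisible by k = %d",
                     depth, k))
      fat <- layer_conv(array(0, c(Cout, k, Cin)), rep(0, Cout), 1L)
      dwd <- depth %/% k
      dw <- layer_depthwise(matrix(0, dwd, Cout), rep(0, Cout), k)
      fat$init_role <- if (role == "ksep") "ksep_fat" else role
      dw$init_role <- if (role == "ksep") "ksep_dw" else role
      list(fat, dw)
    },
    stop(sprintf("unknown convolution kind '%s'", kind)))
}

build_c_block_tree <- function(cfg, omit_activation = FALSE) {
  ls <- build_conv_layers(cfg$conv, cfg$Cin, cfg$Cout, cfg$depth,
                          cfg$stride, cfg$k)
  ls <- c(ls, list(layer_bn(cfg$Cout)))
  if (!omit_activation) ls <- c(ls, list(layer_swish()))
  layer_seq(ls)
}

build_residual_tree <- function(cfg) {
  C <- cfg$C
  if (!cfg$compressed) {
    main <- list()
    for (r in seq_len(cfg$repeats)) {
      main <- c(main, build_conv_layers("separable", C, C, cfg$depth))
      main <- c(main, list(layer_bn(C)))
      if (r < cfg$repeats) main <- c(main, list(layer_swish()))
    }
  } else {
    Cy <- cfg$Cy; x <- cfg$x; k <- cfg$k
    ## inner receptive depth: depth reduced by the compression factor x,
    ## rounded to the nearest odd multiple of k from above so D/k stays odd
    inner_depth <- k * smallest_odd_geq(cfg$depth / (x * k))
    predec_depth <- round_to_odd(cfg$depth / x)
    main <- list(layer_compress(array(0, c(Cy, x, C)), rep(0, Cy), x))
    for (r in seq_len(cfg$repeats - 2L)) {
      main <- c(main, build_conv_layers("k_blueprint_separable", Cy, Cy,
                                        inner_depth, k = k, role = "ksep"))
      main <- c(main, list(layer_bn(Cy), layer_swish()))
    }
    pre <- layer_depthwise(matrix(0, predec_depth, Cy), rep(0, Cy), 1L)
    pre$init_role <- "ksep_dw"       # within the compressed main branch
    main <- c(main, list(pre, layer_bn(Cy)))
    main <- c(main, list(layer_decompress(array(0, c(C, x, Cy)), rep(0, C), x),
                         layer_bn(C)))
  }
  skip <- list(layer_pointwise(matrix(0, C, C), rep(0, C)), layer_bn(C))
  layer_res(layer_seq(main), layer_seq(skip))
}

## ---- initialization ------------------------------------------------------

glorot_fill <- function(a, Cin, Cout) {
  b <- glorot_bound(Cin, Cout)
  array(stats::runif(length(a), -b, b), dim = if (is.null(dim(a))) NULL
        else dim(a))
}

init_layer_weights <- function(layer, spec) {
  role <- layer$init_role %||% "plain"
  if (layer$type %in% c("conv", "compress", "decompress")) {
    d <- dim(layer$par$W)
    if (role == "ksep_fat" && spec$enabled_for[["fat_pointwise"]]) {
      Cout <- d[1L]; k <- d[2L]; Cin <- d[3L]
      W <- array(0, d)
      centre <- k %/% 2L + 1L
      m <- min(Cin, Cout)
      eye <- diag(1, Cout, Cin)           # leading-diagonal identity
      U <- matrix(stats::runif(Cout * Cin, -spec$epsilon, spec$epsilon),
                  Cout, Cin)
      W[, centre, ] <- eye + U
      layer$par$W <- W
    } else {
      layer$par$W <- glorot_fill(layer$par$W, d[3L], d[1L])
    }
    layer$par$B <- rep(0, length(layer$par$B))
  } else if (layer$type == "depthwise") {
    depth <- nrow(layer$par$W); C <- ncol(layer$par$W)
    if (role == "ksep_dw" && spec$enabled_for[["depthwise"]]) {
      W <- matrix(0, depth, C)
      W[depth %/% 2L + 1L, ] <- 1
      layer$par$W <- W
    } else {
      layer$par$W <- matrix(stats::runif(depth * C, -glorot_bound(C, C),
                                         glorot_bound(C, C)), depth, C)
    }
    layer$par$B <- rep(0, C)
  } else if (layer$type == "pointwise") {
    d <- dim(layer$par$W)
    layer$par$W <- glorot_fill(layer$par$W, d[2L], d[1L])
    layer$par$B <- rep(0, d[1L])
  } else if (layer$type == "bn") {
    C <- length(layer$par$gamma)
    layer$par$gamma <- rep(1, C)
    layer$par$beta <- rep(0, C)
    layer$state$mean <- rep(0, C)
    layer$state$var <- rep(1 - layer$epsilon, C)
  }
  layer
}

init_tree <- function(layer, spec) {
  layer <- init_layer_weights(layer, spec)
  if (layer$type == "seq") {
    for (i in seq_along(layer$layers))
      layer$layers[[i]] <- init_tree(layer$layers[[i]], spec)
  } else if (layer$type == "res") {
    layer$main <- init_tree(layer$main, spec)
    layer$skip <- init_tree(layer$skip, spec)
  }
  layer
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialize block parameters
#'
#' Draws all parameters for a block configuration: near-identity kernels for
#' the k-blueprint-separable layers of a compressed main branch (when `spec`
#' enables them) and Glorot-uniform weights elsewhere; batch norms start as
#' the identity (`gamma = 1`, `beta = 0`, zero running mean, unit running
#' variance).  Deterministic given `seed`.
#'
#' @param cfg a [c_block_config()] or [residual_block_config()].
#' @param spec an [identity_init_spec()]; pass
#'   `identity_init_spec(depthwise = FALSE, fat_pointwise = FALSE)` for pure
#'   Glorot initialization.
#' @param seed integer RNG seed.
#' @param omit_activation for C-type blocks, build without the trailing Swish.
#' @return an opaque parameter tree consumed by the block forward functions.
#' @export
init_block <- function(cfg, spec = identity_init_spec(), seed = 1L,
                       omit_activation = FALSE) {
  tree <- if (inherits(cfg, "c_block_config"))
    build_c_block_tree(cfg, omit_activation)
  else if (inherits(cfg, "residual_block_config"))
    build_residual_tree(cfg)
  else stop("init_block: unsupported config class")
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  init_tree(tree, spec)
}

#' Re-apply identity initialization to block parameters
#'
#' Re-draws every parameter of an initialized block: k-blueprint-separable
#' kernels inside a compressed main branch get the (near-)identity scheme,
#' all other layers the Glorot-uniform fallback.  With `epsilon = 0` each
#' inner sub-block becomes an exact identity map.  Reproducible given `seed`.
#'
#' @param params parameter tree from [init_block()] (or a built model's).
#' @param spec an [identity_init_spec()].
#' @param seed integer RNG seed.
#' @return the re-initialized parameter tree.
#' @export
identity_init <- function(params, spec = identity_init_spec(), seed = 1L) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  init_tree(params, spec)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
set_rng_state <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
}

## ---- public forward passes ----------------------------------------------

#' Run a C-type block
#'
#' `activation(batch_norm(conv(x)))`; with `omit_activation = TRUE` (the
#' sub-block form used inside residual blocks) the Swish is skipped.
#'
#' @param x time-by-channel input.
#' @param cfg a [c_block_config()].
#' @param params parameters from [init_block()] (built with the matching
#'   `omit_activation`).
#' @param mode `"infer"` or `"train"` (batch-norm statistics source).
#' @return output matrix of shape `(ceiling(T / stride), Cout)`.
#' @export
c_block <- function(x, cfg, params, mode = c("infer", "train")) {
  mode <- match.arg(mode)
  x <- as_time_channel(x)
  check_channels(x, cfg$Cin, "c_block")
  layer_forward(params, x, training = (mode == "train"))$y
}

#' Run a classical residual block
#'
#' Main branch: `R` separable-convolution sub-blocks (conv + batch norm +
#' Swish), the last omitting the activation.  Skip branch: pointwise
#' convolution + batch norm.  Branches are summed and a Swish applied;
#' the output shape equals the input shape `(T, C)`.
#'
#' @inheritParams c_block
#' @param cfg a [residual_block_config()] with `compressed = FALSE`.
#' @return output matrix of shape `(T, C)`.
#' @export
residual_block_bonito <- function(x, cfg, params, mode = c("infer", "train")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "residual_block_config"), !cfg$compressed)
  x <- as_time_channel(x)
  check_channels(x, cfg$C, "residual_block_bonito")
  layer_forward(params, x, training = (mode == "train"))$y
}

#' Run a compressed residual block
#'
#' Drop-in replacement for [residual_block_bonito()] with identical shape
#' contract.  Main branch: depth-to-space compression `(T, C) -> (T/x, C*y)`,
#' `R - 2` k-blueprint-separable sub-blocks at the compressed resolution
#' (each followed by batch norm and Swish), one depthwise operation + batch
#' norm without activation, then strided transposed decompression back to
#' `(T, C)` + batch norm.  Skip branch: pointwise + batch norm at full
#' resolution.  Branches are summed and a Swish applied.  A `T` not
#' divisible by `x` is right-padded with zeros and trimmed after
#' decompression.
#'
#' @inheritParams c_block
#' @param cfg a [residual_block_config()] with `compressed = TRUE`.
#' @return output matrix of shape `(T, C)`.
#' @export
residual_block_compressed <- function(x, cfg, params,
                                      mode = c("infer", "train")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "residual_block_config"), cfg$compressed)
  x <- as_time_channel(x)
  check_channels(x, cfg$C, "residual_block_compressed")
  layer_forward(params, x, training = (mode == "train"))$y
}
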