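## Core 1-D convolution operators on time-by-channel matrices.
##
## All operators act on a real matrix of shape (T, C): rows are timesteps,
## columns are channels.  Stride-1 operators are length-preserving: inputs
## are zero-padded so that out[t] is centred on in[t] (half-open 0-based
## time coordinates throughout).

#' Coerce to a time-by-channel tensor
#'
#' A time-by-channel tensor is a plain numeric matrix with `T >= 1` rows
#' (timesteps) and `C >= 1` columns (channels), all entries finite.
#' Vectors are treated as single-channel series.
#'
#' @param x numeric vector or matrix.
#' @return a numeric matrix of shape `(T, C)`.
#' @export
as_time_channel <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("time-by-channel tensor needs at least one timestep and one channel")
  if (!all(is.finite(x)))
    stop("time-by-channel tensor contains non-finite entries")
  x
}

check_channels <- function(x, expected, what) {
  if (ncol(x) != expected)
    stop(sprintf("%s: input has %d channels, parameters expect %d",
                 what, ncol(x), expected))
  invisible(TRUE)
}

#' Full convolution parameters
#'
#' @param W weight array of shape `(Cout, D, Cin)`; `D` must be odd.
#' @param B bias vector of length `Cout`.
#' @return an object of class `full_conv_params`.
#' @export
full_conv_params <- function(W, B) {
  W <- as_weight_array(W, 3L, "full_conv_params")
  D <- dim(W)[2L]
  if (D %% 2L == 0L)
    stop(sprintf("full convolution requires odd depth, got D = %d", D))
  B <- check_bias(B, dim(W)[1L], "full_conv_params")
  structure(list(W = W, B = B), class = "full_conv_params")
}

#' Depthwise convolution parameters
#'
#' The depthwise operation convolves each channel with its own kernel of
#' length `depth` (the kernel depth, possibly dilated).
#'
#' @param W weight matrix of shape `(depth, C)`.
#' @param B bias vector of length `C`.
#' @param dilation integer step between kernel taps, `>= 1`.
#' @return an object of class `depthwise_params`.
#' @export
depthwise_params <- function(W, B, dilation = 1L) {
  if (is.null(dim(W))) W <- matrix(as.numeric(W), ncol = 1L)
  storage.mode(W) <- "double"
  if (!all(is.finite(W))) stop("depthwise_params: non-finite weights")
  dilation <- as.integer(dilation)
  if (dilation < 1L) stop("depthwise_params: dilation must be >= 1")
  B <- check_bias(B, ncol(W), "depthwise_params")
  structure(list(W = W, B = B, dilation = dilation),
            class = "depthwise_params")
}

#' Pointwise convolution parameters
#'
#' @param W weight matrix of shape `(Cout, Cin)`.
#' @param B bias vector of length `Cout`.
#' @return an object of class `pointwise_params`.
#' @export
pointwise_params <- function(W, B) {
  W <- as.matrix(W); storage.mode(W) <- "double"
  if (!all(is.finite(W))) stop("pointwise_params: non-finite weights")
  B <- check_bias(B, nrow(W), "pointwise_params")
  structure(list(W = W, B = B), class = "pointwise_params")
}

#' Fat-pointwise convolution parameters
#'
#' A fat-pointwise operation is a standard convolution of small odd depth
#' `k` that mixes channels over a width-`k` window; it is the first half of
#' the k-blueprint-separable factorization.
#'
#' @param W weight array of shape `(Cout, k, Cin)`; `k` must be odd.
#' @param B bias vector of length `Cout`.
#' @return an object of class `fat_pointwise_params`.
#' @export
fat_pointwise_params <- function(W, B) {
  W <- as_weight_array(W, 3L, "fat_pointwise_params")
  k <- dim(W)[2L]
  if (k %% 2L == 0L)
    stop(sprintf("fat-pointwise convolution requires odd k, got k = %d", k))
  B <- check_bias(B, dim(W)[1L], "fat_pointwise_params")
  structure(list(W = W, B = B, k = k), class = "fat_pointwise_params")
}

#' Batch normalization parameters
#'
#' @param gamma,beta scale and shift vectors of length `C`.
#' @param running_mean,running_var running statistics of length `C`;
#'   variances must be non-negative.
#' @param epsilon small positive constant guarding the division.
#' @return an object of class `batch_norm_params`.
#' @export
batch_norm_params <- function(gamma, beta,
                              running_mean = rep(0, length(gamma)),
                              running_var = rep(1, length(gamma)),
                              epsilon = 1e-5) {
  C <- length(gamma)
  stopifnot(length(beta) == C, length(running_mean) == C,
            length(running_var) == C)
  if (any(running_var < 0)) stop("batch_norm_params: negative running variance")
  if (epsilon <= 0) stop("batch_norm_params: epsilon must be positive")
  structure(list(gamma = as.numeric(gamma), beta = as.numeric(beta),
                 running_mean = as.numeric(running_mean),
                 running_var = as.numeric(running_var),
                 epsilon = epsilon),
            class = "batch_norm_params")
}

as_weight_array <- function(W, ndim, what) {
  if (!is.array(W) || length(dim(W)) != ndim)
    stop(sprintf("%s: W must be a %d-dimensional array", what, ndim))
  storage.mode(W) <- "double"
  if (!all(is.finite(W))) stop(sprintf("%s: non-finite weights", what))
  W
}

check_bias <- function(B, n, what) {
  B <- as.numeric(B)
  if (length(B) != n)
    stop(sprintf("%s: bias length %d does not match %d output channels",
                 what, length(B), n))
  B
}

## im2col: unfold a padded (T_pad, C) matrix into (T_out, depth * C) where
## column (d-1)*C + i holds xpad[(t-1)*stride + (d-1)*dilation + 1, i].
im2col <- function(xpad, t_out, depth, C, stride = 1L, dilation = 1L) {
  M <- matrix(0, t_out, depth * C)
  base <- (seq_len(t_out) - 1L) * stride + 1L
  for (d in seq_len(depth)) {
    rows <- base + (d - 1L) * dilation
    M[, ((d - 1L) * C + 1L):(d * C)] <- xpad[rows, , drop = FALSE]
  }
  M
}

## Flatten (Cout, depth, Cin) weights to a (depth*Cin, Cout) matrix matching
## im2col column order.
flatten_weights <- function(W) {
  d <- dim(W)
  matrix(aperm(W, c(3L, 2L, 1L)), nrow = d[2L] * d[3L], ncol = d[1L])
}

pad_rows <- function(x, before, after = before) {
  C <- ncol(x)
  rbind(matrix(0, before, C), x, matrix(0, after, C))
}

#' Full 1-D convolution
#'
#' Computes `Y[t, j] = sum_{d, i} Xpad[t + d, i] * W[j, d, i] + B[j]` with
#' the input zero-padded by `floor(D / 2)` on both ends, so the output is
#' length-preserving at stride 1.  With `stride > 1` the output keeps rows
#' `t = 0, s, 2s, ...`, giving `ceiling(T / s)` timesteps.
#'
#' @param x time-by-channel input (vector or `(T, Cin)` matrix).
#' @param p parameters from [full_conv_params()].
#' @param stride positive integer stride.
#' @return a `(ceiling(T / stride), Cout)` matrix.
#' @export
full_conv <- function(x, p, stride = 1L) {
  x <- as_time_channel(x)
  stopifnot(inherits(p, "full_conv_params"))
  dW <- dim(p$W); Cout <- dW[1L]; D <- dW[2L]; Cin <- dW[3L]
  check_channels(x, Cin, "full_conv")
  stride <- as.integer(stride)
  pad <- D %/% 2L
  t_out <- ceiling(nrow(x) / stride)
  xpad <- pad_rows(x, pad, pad + max(0L, (t_out - 1L) * stride + D - 1L -
                                       (nrow(x) + 2L * pad - 1L)))
  M <- im2col(xpad, t_out, D, Cin, stride = stride)
  sweep(M %*% flatten_weights(p$W), 2L, -p$B)
}

#' Dilated depthwise 1-D convolution
#'
#' Works on each channel separately:
#' `Y[t, j] = sum_d Xpad[t + d * dilation, j] * W[d, j] + B[j]`, with the
#' input zero-padded by `floor(depth / 2) * dilation` on both ends.
#'
#' @param x time-by-channel input.
#' @param p parameters from [depthwise_params()].
#' @return a matrix with the same shape as `x`.
#' @export
depthwise_conv <- function(x, p) {
  x <- as_time_channel(x)
  stopifnot(inherits(p, "depthwise_params"))
  C <- ncol(p$W); depth <- nrow(p$W)
  check_channels(x, C, "depthwise_conv")
  T_ <- nrow(x)
  pad <- (depth %/% 2L) * p$dilation
  xpad <- pad_rows(x, pad, pad + max(0L, (depth - 1L) * p$dilation - 2L * pad))
  Y <- matrix(rep(p$B, each = T_), T_, C)
  for (d in seq_len(depth)) {
    rows <- seq_len(T_) + (d - 1L) * p$dilation
    Y <- Y + xpad[rows, , drop = FALSE] * rep(p$W[d, ], each = T_)
  }
  Y
}

#' Pointwise (1x1) convolution
#'
#' Mixes channels at each timestep: `Y[t, j] = sum_i X[t, i] * W[j, i] + B[j]`.
#'
#' @param x time-by-channel input.
#' @param p parameters from [pointwise_params()].
#' @return a `(T, Cout)` matrix.
#' @export
pointwise_conv <- function(x, p) {
  x <- as_time_channel(x)
  stopifnot(inherits(p, "pointwise_params"))
  check_channels(x, ncol(p$W), "pointwise_conv")
  sweep(x %*% t(p$W), 2L, -p$B)
}

#' Separable convolution (depthwise then pointwise)
#'
#' The classical factorization of a full convolution: an undilated depthwise
#' operation followed by a pointwise channel mix.  Reduces per-timestep flops
#' from `Cout * D * Cin` to `D * Cin + Cout * Cin`.
#'
#' @param x time-by-channel input.
#' @param dp depthwise parameters (`dilation` must be 1).
#' @param pp pointwise parameters.
#' @return a `(T, Cout)` matrix.
#' @export
separable_conv <- function(x, dp, pp) {
  stopifnot(inherits(dp, "depthwise_params"))
  if (dp$dilation != 1L)
    stop("separable_conv: depthwise component must have dilation 1")
  pointwise_conv(depthwise_conv(x, dp), pp)
}

#' k-blueprint-separable convolution
#'
#' Factorizes a depth-`D` convolution into a fat-pointwise convolution of
#' depth `k` (channel mixing over a width-`k` window) followed by a
#' `k`-dilated depthwise convolution of depth `D / k`.  The composition
#' retains the receptive field `D` while shrinking the depthwise kernel by a
#' factor of `k`; the case `k = 1` is the ordinary blueprint-separable
#' convolution (pointwise then depthwise).
#'
#' The fat-pointwise stage is padded by `floor(k / 2)`, the depthwise stage
#' by `floor((D / k) / 2) * k`, keeping the output length `T` and the
#' receptive field centred when `D / k` is odd.  An even `D / k` gives an
#' asymmetric receptive field and triggers a warning (the field is
#' symmetric only for `D = k * (2n + 1)`).
#'
#' @param x time-by-channel input.
#' @param fp fat-pointwise parameters with depth `k`.
#' @param dp depthwise parameters with `dilation == k` and depth `D / k`.
#' @return a `(T, Cout)` matrix.
#' @export
k_blueprint_separable_conv <- function(x, fp, dp) {
  stopifnot(inherits(fp, "fat_pointwise_params"),
            inherits(dp, "depthwise_params"))
  k <- fp$k
  if (dp$dilation != k)
    stop(sprintf(
      "k_blueprint_separable_conv: depthwise dilation (%d) must equal k (%d)",
      dp$dilation, k))
  depth <- nrow(dp$W)
  if (depth %% 2L == 0L)
    warning(sprintf(
      "k_blueprint_separable_conv: D/k = %d is even; receptive field is asymmetric (symmetric only for D = k*(2n+1))",
      depth))
  depthwise_conv(full_conv(x, full_conv_params(fp$W, fp$B)), dp)
}

#' Strided depth-to-space compression convolution
#'
#' Converts a `(T, C)` tensor to `(T / x, C * y)` using a strided
#' convolution with both depth and stride set to `x`: each group of `x`
#' consecutive samples of `C` channels becomes one compressed sample of
#' `C * y` channels.  When `T` is not a multiple of `x` the signal is
#' right-padded with zeros to the next multiple (recorded in the
#' `"pad"` attribute of the result).
#'
#' @param x time-by-channel input of `C` channels.
#' @param W weight array of shape `(C * y, x, C)`.
#' @param B bias vector of length `C * y`.
#' @param stride the compression factor `x` (depth equals stride).
#' @return a `(ceiling(T / x), C * y)` matrix with attribute `"pad"`.
#' @export
strided_compress_conv <- function(x, W, B, stride) {
  x <- as_time_channel(x)
  W <- as_weight_array(W, 3L, "strided_compress_conv")
  stride <- as.integer(stride)
  if (dim(W)[2L] != stride)
    stop("strided_compress_conv: kernel depth must equal stride")
  check_channels(x, dim(W)[3L], "strided_compress_conv")
  B <- check_bias(B, dim(W)[1L], "strided_compress_conv")
  T_ <- nrow(x)
  pad <- (stride - T_ %% stride) %% stride
  if (pad > 0L) x <- rbind(x, matrix(0, pad, ncol(x)))
  S <- nrow(x) %/% stride
  ## rows of x regrouped: M[s, (d-1)*C + i] = x[(s-1)*stride + d, i]
  M <- im2col(x, S, stride, ncol(x), stride = stride)
  out <- sweep(M %*% flatten_weights(W), 2L, -B)
  attr(out, "pad") <- pad
  out
}

#' Strided transposed decompression convolution
#'
#' Inverse shape transform of [strided_compress_conv()]: restores `(S, Cy)`
#' to `(S * x, C)` with `out[s * x + d, j] = sum_i Z[s, i] * W[j, d, i] + B[j]`.
#' Because depth equals stride the output slots do not overlap.
#'
#' @param z compressed `(S, Cy)` input.
#' @param W weight array of shape `(C, x, Cy)`.
#' @param B bias vector of length `C`.
#' @param stride the decompression factor `x`.
#' @return a `(S * x, C)` matrix.
#' @export
transposed_decompress_conv <- function(z, W, B, stride) {
  z <- as_time_channel(z)
  W <- as_weight_array(W, 3L, "transposed_decompress_conv")
  stride <- as.integer(stride)
  if (dim(W)[2L] != stride)
    stop("transposed_decompress_conv: kernel depth must equal stride")
  check_channels(z, dim(W)[3L], "transposed_decompress_conv")
  C <- dim(W)[1L]
  B <- check_bias(B, C, "transposed_decompress_conv")
  S <- nrow(z)
  ## Wmat[(d-1)*C + j, i]: output block d, channel j from input channel i
  Wmat <- matrix(aperm(W, c(1L, 2L, 3L)), nrow = C * stride)  # (j,d) x i
  out2 <- z %*% t(Wmat)                       # (S, x*C), col (d-1)*C + j
  A <- array(out2, dim = c(S, C, stride))     # A[s, j, d]
  out <- matrix(aperm(A, c(3L, 1L, 2L)), nrow = S * stride, ncol = C)
  sweep(out, 2L, -B)
}

#' Batch normalization over the time axis
#'
#' In inference mode renormalizes each channel with the stored running
#' statistics: `y = gamma * (x - mean) / sqrt(var + eps) + beta`.  In
#' training mode the batch (time-axis) mean and variance are used instead,
#' and the running statistics are updated by an exponential moving average
#' (returned in the `"params"` attribute).
#'
#' @param x time-by-channel input.
#' @param p parameters from [batch_norm_params()].
#' @param mode `"infer"` or `"train"`.
#' @param momentum EMA weight of the new batch statistic in training mode.
#' @return normalized matrix; in training mode carries updated parameters in
#'   `attr(, "params")`.
#' @export
batch_norm <- function(x, p, mode = c("infer", "train"), momentum = 0.1) {
  x <- as_time_channel(x)
  stopifnot(inherits(p, "batch_norm_params"))
  mode <- match.arg(mode)
  check_channels(x, length(p$gamma), "batch_norm")
  T_ <- nrow(x)
  if (mode == "infer") {
    mu <- p$running_mean; v <- p$running_var
  } else {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2          # biased batch variance
  }
  scale <- p$gamma / sqrt(v + p$epsilon)
  y <- sweep(sweep(x, 2L, mu), 2L, scale, `*`)
  y <- sweep(y, 2L, -p$beta)
  if (mode == "train") {
    p$running_mean <- (1 - momentum) * p$running_mean + momentum * mu
    p$running_var <- (1 - momentum) * p$running_var + momentum * v
    attr(y, "params") <- p
  }
  y
}

#' Swish activation
#'
#' Elementwise `x * sigmoid(x)`.
#'
#' @param x numeric vector, matrix or array.
#' @return same shape as `x`.
#' @export
swish <- function(x) x * stats::plogis(x)

#' Parameter and flop accounting for convolution factorizations
#'
#' Closed-form weight-parameter and per-window flop (multiply) counts:
#' full convolution `Cout * D * Cin` parameters and `T * Cout * D * Cin`
#' flops; separable `D * Cin + Cout * Cin` and `T * (D * Cin + Cout * Cin)`;
#' k-blueprint-separable `Cout * k * Cin + (D / k) * Cout` and
#' `T * (Cout * k * Cin + (D / k) * Cout)`.  A pointwise convolution is the
#' full convolution with `D = 1`.
#'
#' @param kind one of `"full"`, `"pointwise"`, `"depthwise"`, `"separable"`,
#'   `"k_blueprint_separable"`, `"compress"`, `"decompress"`.
#' @param Cin,Cout channel counts.
#' @param D kernel depth (receptive field for factorized kinds).
#' @param k fat-pointwise depth for `"k_blueprint_separable"`.
#' @param T_ number of timesteps for the flop count (flops scale linearly).
#' @param bias include bias terms in the parameter count.
#' @return list with `params` (weights, plus biases if `bias = TRUE`) and
#'   `flops_per_T` (multiplies for `T_` timesteps).
#' @export
count_params_and_flops <- function(kind, Cin, Cout = Cin, D = 1L, k = 1L,
                                   T_ = 1L, bias = FALSE) {
  kind <- match.arg(kind, c("full", "pointwise", "depthwise", "separable",
                            "k_blueprint_separable", "compress", "decompress"))
  w <- switch(kind,
    full = Cout * D * Cin,
    pointwise = Cout * Cin,
    depthwise = D * Cin,
    separable = D * Cin + Cout * Cin,
    k_blueprint_separable = {
      if (D %% k != 0) stop("count_params_and_flops: D must be divisible by k")
      Cout * k * Cin + (D / k) * Cout
    },
    compress = Cout * D * Cin,
    decompress = Cout * D * Cin)
  b <- switch(kind,
    separable = Cin + Cout,
    k_blueprint_separable = 2L * Cout,
    Cout)
  f <- switch(kind,
    full = Cout * D * Cin,
    pointwise = Cout * Cin,
    depthwise = D * Cin,
    separable = D * Cin + Cout * Cin,
    k_blueprint_separable = Cout * k * Cin + (D / k) * Cout,
    compress = Cout * Cin,       # per output timestep T/D it is Cout*D*Cin
    decompress = Cout * Cin)
  list(params = as.integer(w + if (bias) b else 0L),
       flops_per_T = T_ * f)
}
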