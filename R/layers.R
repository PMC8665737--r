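## Internal layer framework: every network is a tree of layer descriptors.
##
## A layer is a list with a $type and, for parametric types, a $par list of
## numeric arrays (trainable) and possibly $state (non-trainable, e.g. batch
## norm running statistics).  Composite types hold sub-trees.  Forward passes
## return caches; backward passes consume them and emit gradient trees that
## mirror the $par structure, so a generic tree walk can drive the optimizer.
##
## Types: conv (full / fat-pointwise, optional stride), depthwise (optional
## dilation), pointwise, compress, decompress, bn, swish, logsoftmax,
## seq (sequence), res (two-branch residual with final activation).

layer_conv <- function(W, B, stride = 1L) {
  list(type = "conv", stride = as.integer(stride),
       par = list(W = W, B = as.numeric(B)))
}
layer_depthwise <- function(W, B, dilation = 1L) {
  list(type = "depthwise", dilation = as.integer(dilation),
       par = list(W = W, B = as.numeric(B)))
}
layer_pointwise <- function(W, B) {
  list(type = "pointwise", par = list(W = W, B = as.numeric(B)))
}
layer_compress <- function(W, B, stride) {
  list(type = "compress", stride = as.integer(stride),
       par = list(W = W, B = as.numeric(B)))
}
layer_decompress <- function(W, B, stride) {
  list(type = "decompress", stride = as.integer(stride),
       par = list(W = W, B = as.numeric(B)))
}
layer_bn <- function(C, epsilon = 1e-5, momentum = 0.1) {
  ## running_var starts at 1 - epsilon so inference-mode normalization is the
  ## exact identity at initialization (gamma / sqrt(var + eps) == 1)
  list(type = "bn", epsilon = epsilon, momentum = momentum,
       par = list(gamma = rep(1, C), beta = rep(0, C)),
       state = list(mean = rep(0, C), var = rep(1 - epsilon, C)))
}
layer_swish <- function() list(type = "swish")
layer_logsoftmax <- function() list(type = "logsoftmax")
layer_seq <- function(layers) list(type = "seq", layers = layers)
layer_res <- function(main, skip) {
  list(type = "res", main = main, skip = skip)
}

## ---- forward -------------------------------------------------------------

## training: batch-norm uses batch statistics and updates the running EMA.
## instance: batch-norm uses the current input's statistics without touching
## state (read-adaptive inference).  Default: stored running statistics.
layer_forward <- function(layer, x, training = FALSE, instance = FALSE) {
  switch(layer$type,
    conv = {
      dW <- dim(layer$par$W); D <- dW[2L]; Cin <- dW[3L]
      stride <- layer$stride
      T_ <- nrow(x)
      pad <- D %/% 2L
      t_out <- ceiling(T_ / stride)
      extra <- max(0L, (t_out - 1L) * stride + D - T_ - pad)
      xpad <- pad_rows(x, pad, extra)
      M <- im2col(xpad, t_out, D, Cin, stride = stride)
      Wmat <- flatten_weights(layer$par$W)
      y <- M %*% Wmat + rep(layer$par$B, each = t_out)
      list(y = y, cache = list(M = M, Wmat = Wmat, T_ = T_, pad = pad,
                               T_pad = nrow(xpad), t_out = t_out),
           layer = layer)
    },
    depthwise = {
      W <- layer$par$W; depth <- nrow(W); C <- ncol(W)
      dil <- layer$dilation
      T_ <- nrow(x)
      pad <- (depth %/% 2L) * dil
      xpad <- pad_rows(x, pad, pad)
      y <- matrix(rep(layer$par$B, each = T_), T_, C)
      for (d in seq_len(depth)) {
        rows <- seq_len(T_) + (d - 1L) * dil
        y <- y + xpad[rows, , drop = FALSE] * rep(W[d, ], each = T_)
      }
      list(y = y, cache = list(xpad = xpad, T_ = T_, pad = pad), layer = layer)
    },
    pointwise = {
      y <- x %*% t(layer$par$W) + rep(layer$par$B, each = nrow(x))
      list(y = y, cache = list(x = x), layer = layer)
    },
    compress = {
      s <- layer$stride
      T_ <- nrow(x); C <- ncol(x)
      padn <- (s - T_ %% s) %% s
      if (padn > 0L) x <- rbind(x, matrix(0, padn, C))
      S <- nrow(x) %/% s
      M <- im2col(x, S, s, C, stride = s)
      Wmat <- flatten_weights(layer$par$W)
      y <- M %*% Wmat + rep(layer$par$B, each = S)
      list(y = y, cache = list(M = M, Wmat = Wmat, T_ = T_, padn = padn,
                               S = S, C = C),
           layer = layer)
    },
    decompress = {
      s <- layer$stride
      W <- layer$par$W; C <- dim(W)[1L]
      S <- nrow(x)
      Wmat <- matrix(W, nrow = C * s)            # row (d-1)*C + j, col i
      out2 <- x %*% t(Wmat)                      # (S, s*C), col (d-1)*C + j
      A <- array(out2, dim = c(S, C, s))
      y <- matrix(aperm(A, c(3L, 1L, 2L)), nrow = S * s, ncol = C)
      y <- y + rep(layer$par$B, each = S * s)
      list(y = y, cache = list(x = x, S = S, C = C), layer = layer)
    },
    bn = {
      T_ <- nrow(x)
      if (training || instance) {
        mu <- colMeans(x)
        v <- colMeans(x^2) - mu^2
        if (training) {
          layer$state$mean <- (1 - layer$momentum) * layer$state$mean +
            layer$momentum * mu
          layer$state$var <- (1 - layer$momentum) * layer$state$var +
            layer$momentum * v
        }
      } else {
        mu <- layer$state$mean
        v <- layer$state$var
      }
      ivar <- 1 / sqrt(v + layer$epsilon)
      xhat <- (x - rep(mu, each = T_)) * rep(ivar, each = T_)
      y <- xhat * rep(layer$par$gamma, each = T_) +
        rep(layer$par$beta, each = T_)
      list(y = y, cache = list(xhat = xhat, ivar = ivar, T_ = T_), layer = layer)
    },
    swish = {
      s <- 1 / (1 + exp(-x))
      list(y = x * s, cache = list(x = x, s = s), layer = layer)
    },
    logsoftmax = {
      m <- apply(x, 1L, max)
      z <- x - m
      lse <- log(rowSums(exp(z)))
      y <- z - lse
      list(y = y, cache = list(p = exp(y)), layer = layer)
    },
    seq = {
      caches <- vector("list", length(layer$layers))
      for (i in seq_along(layer$layers)) {
        fw <- layer_forward(layer$layers[[i]], x, training, instance)
        x <- fw$y
        caches[[i]] <- fw$cache
        layer$layers[[i]] <- fw$layer
      }
      list(y = x, cache = caches, layer = layer)
    },
    res = {
      fm <- layer_forward(layer$main, x, training, instance)
      fs <- layer_forward(layer$skip, x, training, instance)
      ## compression may have right-padded the main branch; trim to skip
      trim <- nrow(fm$y) - nrow(fs$y)
      my <- if (trim > 0L) fm$y[seq_len(nrow(fs$y)), , drop = FALSE] else fm$y
      z <- my + fs$y
      s <- 1 / (1 + exp(-z))
      layer$main <- fm$layer; layer$skip <- fs$layer
      list(y = z * s,
           cache = list(main = fm$cache, skip = fs$cache, z = z, s = s,
                        trim = trim),
           layer = layer)
    },
    stop(sprintf("unknown layer type '%s'", layer$type))
  )
}

## ---- backward ------------------------------------------------------------

## Returns list(gx, grads); grads mirrors the layer's $par tree.
layer_backward <- function(layer, cache, gy) {
  switch(layer$type,
    conv = {
      Wmat <- cache$Wmat
      dW <- dim(layer$par$W); Cout <- dW[1L]; D <- dW[2L]; Cin <- dW[3L]
      gWmat <- crossprod(cache$M, gy)            # (D*Cin, Cout)
      gW <- aperm(array(gWmat, dim = c(Cin, D, Cout)), c(3L, 2L, 1L))
      gB <- colSums(gy)
      gM <- gy %*% t(Wmat)
      gxpad <- matrix(0, cache$T_pad, Cin)
      base <- (seq_len(cache$t_out) - 1L) * layer$stride + 1L
      for (d in seq_len(D)) {
        rows <- base + (d - 1L)
        cols <- ((d - 1L) * Cin + 1L):(d * Cin)
        gxpad[rows, ] <- gxpad[rows, , drop = FALSE] + gM[, cols, drop = FALSE]
      }
      gx <- gxpad[cache$pad + seq_len(cache$T_), , drop = FALSE]
      list(gx = gx, grads = list(W = gW, B = gB))
    },
    depthwise = {
      W <- layer$par$W; depth <- nrow(W); C <- ncol(W)
      dil <- layer$dilation
      T_ <- cache$T_
      gxpad <- matrix(0, nrow(cache$xpad), C)
      gW <- matrix(0, depth, C)
      for (d in seq_len(depth)) {
        rows <- seq_len(T_) + (d - 1L) * dil
        gW[d, ] <- colSums(cache$xpad[rows, , drop = FALSE] * gy)
        gxpad[rows, ] <- gxpad[rows, , drop = FALSE] +
          gy * rep(W[d, ], each = T_)
      }
      gx <- gxpad[cache$pad + seq_len(T_), , drop = FALSE]
      list(gx = gx, grads = list(W = gW, B = colSums(gy)))
    },
    pointwise = {
      list(gx = gy %*% layer$par$W,
           grads = list(W = crossprod(gy, cache$x), B = colSums(gy)))
    },
    compress = {
      s <- layer$stride
      dW <- dim(layer$par$W); Cout <- dW[1L]; C <- dW[3L]
      gWmat <- crossprod(cache$M, gy)
      gW <- aperm(array(gWmat, dim = c(C, s, Cout)), c(3L, 2L, 1L))
      gM <- gy %*% t(cache$Wmat)                     # (S, s*C)
      ## non-overlapping: row (s-1)*stride + d of padded x gets gM[s, block d]
      A <- array(gM, dim = c(cache$S, C, s))         # wrong order; fix below
      ## gM col index (d-1)*C + i -> array(gM, c(S, C, s)) gives [s, i, d]
      gxp <- matrix(aperm(A, c(3L, 1L, 2L)), nrow = cache$S * s, ncol = C)
      gx <- gxp[seq_len(cache$T_), , drop = FALSE]
      list(gx = gx, grads = list(W = gW, B = colSums(gy)))
    },
    decompress = {
      s <- layer$stride
      W <- layer$par$W; C <- dim(W)[1L]; Cy <- dim(W)[3L]
      S <- cache$S
      Wmat <- matrix(W, nrow = C * s)
      gB2 <- array(gy, dim = c(s, S, C))
      gout2 <- matrix(aperm(gB2, c(2L, 3L, 1L)), nrow = S)  # (S, s*C)
      gx <- gout2 %*% Wmat
      gWmat <- crossprod(gout2, cache$x)                    # (s*C, Cy)
      gW <- array(gWmat, dim = c(C, s, Cy))
      ## bias adds to every output row per channel
      list(gx = gx, grads = list(W = gW, B = colSums(gy)))
    },
    bn = {
      T_ <- cache$T_
      xhat <- cache$xhat
      ggamma <- colSums(gy * xhat)
      gbeta <- colSums(gy)
      gxhat <- gy * rep(layer$par$gamma, each = T_)
      sg <- colSums(gxhat)
      sgx <- colSums(gxhat * xhat)
      gx <- (gxhat * T_ - rep(sg, each = T_) - xhat * rep(sgx, each = T_)) *
        rep(cache$ivar / T_, each = T_)
      list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
    },
    swish = {
      s <- cache$s; x <- cache$x
      list(gx = gy * (s * (1 + x * (1 - s))), grads = NULL)
    },
    logsoftmax = {
      list(gx = gy - cache$p * rowSums(gy), grads = NULL)
    },
    seq = {
      n <- length(layer$layers)
      grads <- vector("list", n)
      for (i in rev(seq_len(n))) {
        bw <- layer_backward(layer$layers[[i]], cache[[i]], gy)
        gy <- bw$gx
        grads[i] <- list(bw$grads)   # [[<- would drop NULL entries
      }
      list(gx = gy, grads = grads)
    },
    res = {
      z <- cache$z; s <- cache$s
      gz <- gy * (s * (1 + z * (1 - s)))
      gz_main <- if (cache$trim > 0L)
        rbind(gz, matrix(0, cache$trim, ncol(gz))) else gz
      bm <- layer_backward(layer$main, cache$main, gz_main)
      bs <- layer_backward(layer$skip, cache$skip, gz)
      list(gx = bm$gx + bs$gx, grads = list(main = bm$grads, skip = bs$grads))
    },
    stop(sprintf("unknown layer type '%s'", layer$type))
  )
}

## ---- parameter tree utilities --------------------------------------------

## Collect references to all trainable parameter arrays as flat named list of
## paths; used by the optimizer and by serialization.
collect_params <- function(layer, path = "net") {
  out <- list()
  if (!is.null(layer$par)) {
    for (nm in names(layer$par))
      out[[paste(path, nm, sep = ".")]] <- layer$par[[nm]]
  }
  if (layer$type == "seq") {
    for (i in seq_along(layer$layers))
      out <- c(out, collect_params(layer$layers[[i]],
                                   paste0(path, ".", i)))
  } else if (layer$type == "res") {
    out <- c(out, collect_params(layer$main, paste0(path, ".main")))
    out <- c(out, collect_params(layer$skip, paste0(path, ".skip")))
  }
  out
}

## Collect batch-norm running statistics (non-trainable state).
collect_state <- function(layer, path = "net") {
  out <- list()
  if (!is.null(layer$state)) {
    for (nm in names(layer$state))
      out[[paste(path, "state", nm, sep = ".")]] <- layer$state[[nm]]
  }
  if (layer$type == "seq") {
    for (i in seq_along(layer$layers))
      out <- c(out, collect_state(layer$layers[[i]], paste0(path, ".", i)))
  } else if (layer$type == "res") {
    out <- c(out, collect_state(layer$main, paste0(path, ".main")))
    out <- c(out, collect_state(layer$skip, paste0(path, ".skip")))
  }
  out
}

## Apply fn(par_array, grad_array, key) to every trainable parameter, writing
## the result back.  grads tree mirrors layer structure (may be NULL).
map_params <- function(layer, grads, fn, path = "net") {
  if (!is.null(layer$par)) {
    for (nm in names(layer$par)) {
      g <- if (is.null(grads)) NULL else grads[[nm]]
      layer$par[[nm]] <- fn(layer$par[[nm]], g, paste(path, nm, sep = "."))
    }
  }
  if (layer$type == "seq") {
    for (i in seq_along(layer$layers)) {
      sub <- if (is.null(grads)) NULL else grads[[i]]
      layer$layers[[i]] <- map_params(layer$layers[[i]], sub, fn,
                                      paste0(path, ".", i))
    }
  } else if (layer$type == "res") {
    layer$main <- map_params(layer$main,
                             if (is.null(grads)) NULL else grads$main,
                             fn, paste0(path, ".main"))
    layer$skip <- map_params(layer$skip,
                             if (is.null(grads)) NULL else grads$skip,
                             fn, paste0(path, ".skip"))
  }
  layer
}

set_bn_momentum <- function(layer, m) {
  if (layer$type == "bn") layer$momentum <- m
  if (layer$type == "seq") {
    for (i in seq_along(layer$layers))
      layer$layers[[i]] <- set_bn_momentum(layer$layers[[i]], m)
  } else if (layer$type == "res") {
    layer$main <- set_bn_momentum(layer$main, m)
    layer$skip <- set_bn_momentum(layer$skip, m)
  }
  layer
}

## Recalibrate batch-norm running statistics with frozen weights: forward
## passes in training mode with momentum 1/i accumulate the flat average of
## the batch statistics over the supplied inputs.
calibrate_bn <- function(net, inputs) {
  for (i in seq_along(inputs)) {
    net <- set_bn_momentum(net, 1 / i)
    net <- layer_forward(net, inputs[[i]], training = TRUE)$layer
  }
  set_bn_momentum(net, 0.1)
}

## Set state entries by key (inverse of collect_state), for deserialization.
restore_tree <- function(layer, values, path = "net") {
  if (!is.null(layer$par)) {
    for (nm in names(layer$par)) {
      key <- paste(path, nm, sep = ".")
      if (!is.null(values[[key]])) {
        v <- values[[key]]
        dim(v) <- dim(layer$par[[nm]])
        layer$par[[nm]] <- v
      }
    }
  }
  if (!is.null(layer$state)) {
    for (nm in names(layer$state)) {
      key <- paste(path, "state", nm, sep = ".")
      if (!is.null(values[[key]])) layer$state[[nm]] <- as.numeric(values[[key]])
    }
  }
  if (layer$type == "seq") {
    for (i in seq_along(layer$layers))
      layer$layers[[i]] <- restore_tree(layer$layers[[i]], values,
                                        paste0(path, ".", i))
  } else if (layer$type == "res") {
    layer$main <- restore_tree(layer$main, values, paste0(path, ".main"))
    layer$skip <- restore_tree(layer$skip, values, paste0(path, ".skip"))
  }
  layer
}
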