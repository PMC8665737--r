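# Independent loop-based oracles: direct evaluation of the defining sums,
# deliberately naive so they share no code with the vectorized implementation.

oracle_full_conv <- function(x, W, B, stride = 1L) {
  Cout <- dim(W)[1]; D <- dim(W)[2]; Cin <- dim(W)[3]
  T_ <- nrow(x); pad <- D %/% 2
  lookup <- function(t, i) if (t >= 1 && t <= T_) x[t, i] else 0
  t_out <- ceiling(T_ / stride)
  Y <- matrix(0, t_out, Cout)
  for (t in seq_len(t_out)) for (j in seq_len(Cout)) {
    acc <- B[j]
    for (d in seq_len(D)) for (i in seq_len(Cin))
      acc <- acc + lookup((t - 1) * stride + d - pad, i) * W[j, d, i]
    Y[t, j] <- acc
  }
  Y
}

oracle_depthwise <- function(x, W, B, dilation = 1L) {
  depth <- nrow(W); C <- ncol(W)
  T_ <- nrow(x); pad <- (depth %/% 2) * dilation
  lookup <- function(t, j) if (t >= 1 && t <= T_) x[t, j] else 0
  Y <- matrix(0, T_, C)
  for (t in seq_len(T_)) for (j in seq_len(C)) {
    acc <- B[j]
    for (d in seq_len(depth))
      acc <- acc + lookup(t + (d - 1) * dilation - pad, j) * W[d, j]
    Y[t, j] <- acc
  }
  Y
}

oracle_pointwise <- function(x, W, B) {
  Y <- matrix(0, nrow(x), nrow(W))
  for (t in seq_len(nrow(x))) for (j in seq_len(nrow(W)))
    Y[t, j] <- sum(x[t, ] * W[j, ]) + B[j]
  Y
}

oracle_compress <- function(x, W, B, stride) {
  T_ <- nrow(x); C <- ncol(x); Cy <- dim(W)[1]
  padn <- (stride - T_ %% stride) %% stride
  if (padn > 0) x <- rbind(x, matrix(0, padn, C))
  S <- nrow(x) / stride
  Y <- matrix(0, S, Cy)
  for (s in seq_len(S)) for (j in seq_len(Cy)) {
    acc <- B[j]
    for (d in seq_len(stride)) for (i in seq_len(C))
      acc <- acc + x[(s - 1) * stride + d, i] * W[j, d, i]
    Y[s, j] <- acc
  }
  Y
}

oracle_decompress <- function(z, W, B, stride) {
  S <- nrow(z); C <- dim(W)[1]; Cy <- dim(W)[3]
  Y <- matrix(0, S * stride, C)
  for (s in seq_len(S)) for (d in seq_len(stride)) for (j in seq_len(C))
    Y[(s - 1) * stride + d, j] <- sum(z[s, ] * W[j, d, ]) + B[j]
  Y
}

# quadratic-time Levenshtein DP (unit costs)
oracle_edit_distance <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  dp <- matrix(0, n + 1, m + 1)
  dp[, 1] <- 0:n; dp[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    dp[i + 1, j + 1] <- min(dp[i, j + 1] + 1, dp[i + 1, j] + 1,
                            dp[i, j] + (A[i] != B[j]))
  dp[n + 1, m + 1]
}

random_tc <- function(T_, C, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(T_ * C), T_, C)
}
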