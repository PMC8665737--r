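test_that("full convolution matches hand-enumerated examples and rejects bad shapes", {
  expect_equal(as.numeric(full_conv(c(5, -2, 3),
                                    full_conv_params(array(1, c(1, 1, 1)), 0))),
               c(5, -2, 3))
  expect_equal(as.numeric(full_conv(c(1, 2, 3),
                                    full_conv_params(array(1, c(1, 3, 1)), 0))),
               c(3, 6, 5))
  expect_equal(as.numeric(full_conv(rnorm(4),
                                    full_conv_params(array(0, c(1, 3, 1)), 7))),
               rep(7, 4))
  expect_error(full_conv_params(array(1, c(2, 4, 3)), rep(0, 2)), "odd")
  expect_error(full_conv(matrix(1, 5, 2),
                         full_conv_params(array(1, c(1, 3, 3)), 0)),
               "channels")
})

test_that("depthwise convolution matches examples, including dilation", {
  p_id <- depthwise_params(matrix(1, 1, 3), rep(0, 3))
  x <- random_tc(10, 3, seed = 1)
  expect_equal(depthwise_conv(x, p_id), x)
  expect_equal(as.numeric(depthwise_conv(c(1, 2, 3, 4, 5),
                                         depthwise_params(matrix(1, 3, 1), 0,
                                                          dilation = 2))),
               c(4, 6, 9, 6, 8))
  expect_error(depthwise_conv(matrix(1, 4, 2),
                              depthwise_params(matrix(1, 3, 3), rep(0, 3))),
               "channels")
})

test_that("depthwise at dilation 1 equals a full conv with diagonal channel coupling", {
  set.seed(7)
  x <- random_tc(16, 4)
  Wd <- matrix(rnorm(3 * 4), 3, 4)
  B <- rnorm(4)
  Wfull <- array(0, c(4, 3, 4))
  for (j in 1:4) for (d in 1:3) Wfull[j, d, j] <- Wd[d, j]
  y1 <- depthwise_conv(x, depthwise_params(Wd, B))
  y2 <- full_conv(x, full_conv_params(Wfull, B))
  expect_lt(max(abs(y1 - y2)), 1e-9)
})

test_that("pointwise convolution mixes channels and agrees with full conv at D = 1", {
  x <- random_tc(8, 3, seed = 2)
  expect_equal(pointwise_conv(x, pointwise_params(diag(3), rep(0, 3))), x)
  expect_equal(as.numeric(pointwise_conv(matrix(c(3, 4), 1, 2),
                                         pointwise_params(matrix(1, 1, 2), 0))),
               7)
  W <- matrix(rnorm(5 * 3), 5, 3); B <- rnorm(5)
  y1 <- pointwise_conv(x, pointwise_params(W, B))
  Wfull <- array(W, c(5, 1, 3))
  y2 <- full_conv(x, full_conv_params(Wfull, B))
  expect_lt(max(abs(y1 - y2)), 1e-9)
})

test_that("every factorized operator agrees with direct evaluation of its defining sum", {
  set.seed(11)
  for (rep in 1:50) {
    T_ <- sample(2:32, 1); Cin <- sample(1:8, 1); Cout <- sample(1:8, 1)
    D <- sample(c(1, 3, 5, 7), 1)
    x <- random_tc(T_, Cin)

    W <- array(rnorm(Cout * D * Cin), c(Cout, D, Cin)); B <- rnorm(Cout)
    expect_lt(max(abs(full_conv(x, full_conv_params(W, B)) -
                      oracle_full_conv(x, W, B))), 1e-9)

    dil <- sample(1:3, 1)
    Wd <- matrix(rnorm(D * Cin), D, Cin); Bd <- rnorm(Cin)
    expect_lt(max(abs(depthwise_conv(x, depthwise_params(Wd, Bd, dil)) -
                      oracle_depthwise(x, Wd, Bd, dil))), 1e-9)

    Wp <- matrix(rnorm(Cout * Cin), Cout, Cin); Bp <- rnorm(Cout)
    expect_lt(max(abs(pointwise_conv(x, pointwise_params(Wp, Bp)) -
                      oracle_pointwise(x, Wp, Bp))), 1e-9)

    ## separable = depthwise then pointwise, by definition
    y <- separable_conv(x, depthwise_params(Wd, Bd), pointwise_params(Wp, Bp))
    expect_lt(max(abs(y - oracle_pointwise(oracle_depthwise(x, Wd, Bd),
                                           Wp, Bp))), 1e-9)

    ## k-blueprint-separable: fat-pointwise then dilated depthwise
    k <- 3L; q <- sample(c(1L, 3L), 1)
    Wf <- array(rnorm(Cout * k * Cin), c(Cout, k, Cin)); Bf <- rnorm(Cout)
    Wkd <- matrix(rnorm(q * Cout), q, Cout); Bkd <- rnorm(Cout)
    yk <- k_blueprint_separable_conv(x, fat_pointwise_params(Wf, Bf),
                                     depthwise_params(Wkd, Bkd, dilation = k))
    ref <- oracle_depthwise(oracle_full_conv(x, Wf, Bf), Wkd, Bkd, k)
    expect_lt(max(abs(yk - ref)), 1e-9)

    ## compression / decompression
    xx <- sample(1:4, 1); Cy <- sample(1:6, 1)
    Wc <- array(rnorm(Cy * xx * Cin), c(Cy, xx, Cin)); Bc <- rnorm(Cy)
    yc <- strided_compress_conv(x, Wc, Bc, xx)
    expect_lt(max(abs(yc - oracle_compress(x, Wc, Bc, xx))), 1e-9)
    Wdc <- array(rnorm(Cin * xx * Cy), c(Cin, xx, Cy)); Bdc <- rnorm(Cin)
    z <- matrix(rnorm(5 * Cy), 5, Cy)
    expect_lt(max(abs(transposed_decompress_conv(z, Wdc, Bdc, xx) -
                      oracle_decompress(z, Wdc, Bdc, xx))), 1e-9)
  }
})

test_that("k = 1 reduces to blueprint-separable (pointwise then depthwise)", {
  set.seed(21)
  x <- random_tc(32, 8)
  Wf <- array(rnorm(8 * 1 * 8), c(8, 1, 8)); Bf <- rnorm(8)
  Wd <- matrix(rnorm(5 * 8), 5, 8); Bd <- rnorm(8)
  y1 <- k_blueprint_separable_conv(x, fat_pointwise_params(Wf, Bf),
                                   depthwise_params(Wd, Bd, dilation = 1))
  y2 <- depthwise_conv(pointwise_conv(x, pointwise_params(Wf[, 1, ], Bf)),
                       depthwise_params(Wd, Bd, dilation = 1))
  expect_lt(max(abs(y1 - y2)), 1e-12)
})

test_that("k-blueprint-separable validates D/k and warns on even quotient", {
  x <- random_tc(12, 2, seed = 3)
  fp <- fat_pointwise_params(array(rnorm(2 * 3 * 2), c(2, 3, 2)), rnorm(2))
  dp_even <- depthwise_params(matrix(rnorm(2 * 2), 2, 2), rnorm(2),
                              dilation = 3)
  expect_warning(k_blueprint_separable_conv(x, fp, dp_even), "asymmetric")
  dp_bad_dil <- depthwise_params(matrix(rnorm(3 * 2), 3, 2), rnorm(2),
                                 dilation = 2)
  expect_error(k_blueprint_separable_conv(x, fp, dp_bad_dil), "dilation")
})

test_that("receptive field: perturbations beyond the radius leave output unchanged", {
  ## D = 15, k = 3 -> D/k = 5 (odd); radius floor(D/2) = 7 at the centre
  set.seed(31)
  C <- 3L; k <- 3L; D <- 15L
  x <- random_tc(41, C)
  fp <- fat_pointwise_params(array(rnorm(C * k * C), c(C, k, C)), rnorm(C))
  dp <- depthwise_params(matrix(rnorm(5 * C), 5, C), rnorm(C), dilation = k)
  y0 <- k_blueprint_separable_conv(x, fp, dp)
  t0 <- 21L
  radius <- D %/% 2L   # centred composition: pad_fat + pad_dw = (k-1)/2 + (D-k)/2
  for (dist in c(radius + 1L, radius + 3L)) {
    for (tt in c(t0 - dist, t0 + dist)) {
      xp <- x; xp[tt, ] <- xp[tt, ] + 100
      yp <- k_blueprint_separable_conv(xp, fp, dp)
      expect_identical(yp[t0, ], y0[t0, ])
    }
  }
  inner <- (D - k) %/% 2L
  xp <- x; xp[t0 + inner, ] <- xp[t0 + inner, ] + 100
  yp <- k_blueprint_separable_conv(xp, fp, dp)
  expect_false(all(yp[t0, ] == y0[t0, ]))
})

test_that("operators preserve length at stride 1 and compression divides by exactly x", {
  set.seed(41)
  for (T_ in c(5, 12, 30)) {
    x <- random_tc(T_, 4)
    expect_equal(nrow(full_conv(x, full_conv_params(
      array(rnorm(4 * 5 * 4), c(4, 5, 4)), rnorm(4)))), T_)
    expect_equal(nrow(depthwise_conv(x, depthwise_params(
      matrix(rnorm(3 * 4), 3, 4), rnorm(4), 2))), T_)
  }
  y <- strided_compress_conv(random_tc(12, 4), array(rnorm(8 * 3 * 4),
                                                     c(8, 3, 4)), rnorm(8), 3)
  expect_equal(dim(y), c(4L, 8L))
  ## shape round trip, any weights
  z <- transposed_decompress_conv(y, array(rnorm(4 * 3 * 8), c(4, 3, 8)),
                                  rnorm(4), 3)
  expect_equal(dim(z), c(12L, 4L))
  ## decompress value example and bias-only case
  expect_equal(as.numeric(transposed_decompress_conv(
    matrix(c(1, 2), ncol = 1), array(1, c(1, 3, 1)), 0, 3)),
    c(1, 1, 1, 2, 2, 2))
  expect_equal(as.numeric(transposed_decompress_conv(
    matrix(c(1, 2), ncol = 1), array(0, c(1, 3, 1)), 2, 3)), rep(2, 6))
  ## compress hand enumeration and identity
  expect_equal(as.numeric(strided_compress_conv(
    matrix(1:6, ncol = 1), array(1, c(1, 3, 1)), 0, 3)), c(6, 15))
  expect_equal(strided_compress_conv(x <- random_tc(6, 2),
                                     array(diag(2), c(2, 1, 2)), c(0, 0), 1),
               x, ignore_attr = TRUE)
})

test_that("batch normalization: closed form in inference, moments in training", {
  p <- batch_norm_params(gamma = c(1, 2), beta = c(0, 3),
                         running_mean = c(0, 1), running_var = c(1, 1),
                         epsilon = 1e-12)
  x <- cbind(c(0.5, -1), c(0, 2))
  y <- batch_norm(x, p, "infer")
  expect_equal(y[, 1], c(0.5, -1), tolerance = 1e-9)
  expect_equal(y[, 2], c(1, 5), tolerance = 1e-6)
  set.seed(51)
  x2 <- random_tc(200, 3) * 5 + 2
  p2 <- batch_norm_params(gamma = c(2, 1, 0.5), beta = c(3, 0, -1),
                          epsilon = 1e-10)
  y2 <- batch_norm(x2, p2, "train")
  expect_equal(colMeans(y2), c(3, 0, -1), tolerance = 1e-6)
  expect_equal(apply(y2, 2, function(v) mean(v^2) - mean(v)^2),
               c(4, 1, 0.25), tolerance = 1e-6)
})

test_that("swish matches its closed form and asymptote", {
  expect_equal(swish(0), 0)
  expect_equal(swish(1), 1 / (1 + exp(-1)), tolerance = 1e-9)
  expect_lt(abs(swish(30) / 30 - 1), 1e-9)
})

test_that("parameter/flop closed forms match exhaustive enumeration", {
  expect_equal(count_params_and_flops("full", 128, 128, 3)$params, 49152L)
  expect_equal(count_params_and_flops("separable", 128, 128, 15,
                                      T_ = 1000)$flops_per_T, 18304000)
  ## pointwise equals full with D = 1
  expect_equal(count_params_and_flops("pointwise", 32, 48)$params,
               count_params_and_flops("full", 32, 48, 1)$params)
  ## k-separable count and the ~k-fold ratio at D=15, k=3, C=128
  ks <- count_params_and_flops("k_blueprint_separable", 128, 128, 15, k = 3)
  expect_equal(ks$params, 49792L)
  expect_equal(count_params_and_flops("k_blueprint_separable", 128, 128, 15,
                                      k = 3, bias = TRUE)$params, 49792L + 256L)
  sep <- count_params_and_flops("separable", 128, 128, 15)
  expect_equal(sep$params, 18304L)
  expect_equal(ks$params / sep$params, 2.72, tolerance = 0.01)

  set.seed(61)
  for (i in 1:10) {
    Cin <- sample(1:64, 1); Cout <- sample(1:64, 1)
    k <- 3L; D <- k * sample(c(1, 3, 5), 1)
    W <- array(0, c(Cout, D, Cin))
    expect_equal(count_params_and_flops("full", Cin, Cout, D)$params,
                 length(W))
    expect_equal(count_params_and_flops("separable", Cin, Cin, D)$params,
                 length(matrix(0, D, Cin)) + length(matrix(0, Cin, Cin)))
    expect_equal(count_params_and_flops("k_blueprint_separable", Cin, Cout,
                                        D, k)$params,
                 length(array(0, c(Cout, k, Cin))) +
                   length(matrix(0, D / k, Cout)))
  }
})
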