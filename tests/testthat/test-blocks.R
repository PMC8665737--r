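test_that("C-type block composes conv, batch norm and Swish", {
  cfg <- c_block_config(1, 1, 1, conv = "full")
  params <- init_block(cfg, seed = 1)
  ## force identity conv + identity BN, check activation componentwise
  params <- nanocallr:::restore_tree(params, list(`net.1.W` = array(1, c(1, 1, 1)),
                                                  `net.1.B` = 0))
  x <- matrix(c(-1, 0, 2), ncol = 1)
  expect_equal(c_block(x, cfg, params), swish(x), tolerance = 1e-12)
  ## omit-activation flag: BN(conv(x)) only
  params2 <- init_block(cfg, seed = 1, omit_activation = TRUE)
  params2 <- nanocallr:::restore_tree(params2, list(`net.1.W` = array(1, c(1, 1, 1)),
                                                    `net.1.B` = 0))
  expect_equal(c_block(x, cfg, params2), x, tolerance = 1e-12)
  ## stride 3 on T = 12 gives 4 output frames
  cfg3 <- c_block_config(1, 4, 9, stride = 3, conv = "full")
  p3 <- init_block(cfg3, seed = 2)
  expect_equal(dim(c_block(matrix(rnorm(12), ncol = 1), cfg3, p3)), c(4L, 4L))
})

test_that("classical residual block: branch isolation and shape contract", {
  cfg <- residual_block_config(C = 4, depth = 5, repeats = 3,
                               compressed = FALSE)
  set.seed(3)
  x <- random_tc(20, 4)
  ## all weights zero -> swish(0) = 0 everywhere
  params <- init_block(cfg, seed = 1)
  zeroed <- nanocallr:::map_params(params, NULL, function(w, g, k) 0 * w)
  expect_equal(residual_block_bonito(x, cfg, zeroed),
               matrix(0, 20, 4), ignore_attr = TRUE)
  ## main branch zeroed: output = swish(BN(pointwise(x)))
  skip_only <- nanocallr:::map_params(params, NULL, function(w, g, k) {
    if (grepl("\\.main\\.", k)) 0 * w else w
  })
  skipW <- nanocallr:::collect_params(params$skip)[["net.1.W"]]
  skipB <- nanocallr:::collect_params(params$skip)[["net.1.B"]]
  expect_equal(residual_block_bonito(x, cfg, skip_only),
               swish(pointwise_conv(x, pointwise_params(skipW, skipB))),
               tolerance = 1e-9)
  ## shape contract over random configs
  for (i in 1:5) {
    C <- sample(2:6, 1); T_ <- sample(10:40, 1)
    cfg_i <- residual_block_config(C, depth = 5, repeats = sample(3:4, 1),
                                   compressed = FALSE)
    y <- residual_block_bonito(random_tc(T_, C), cfg_i,
                               init_block(cfg_i, seed = i))
    expect_equal(dim(y), c(T_, C))
  }
})

test_that("compressed residual block is a drop-in shape replacement", {
  for (T_ in c(30, 31, 32)) {     # including T not divisible by x
    cfg <- residual_block_config(C = 4, depth = 15, repeats = 3, k = 3,
                                 x = 3, y = 2, compressed = TRUE)
    y <- residual_block_compressed(random_tc(T_, 4, seed = T_), cfg,
                                   init_block(cfg, seed = 1))
    expect_equal(dim(y), c(T_, 4L))
  }
  ## intermediate main-branch tensors: (30, 4) compressed at 3:2 is (10, 8)
  z <- strided_compress_conv(random_tc(30, 4, seed = 9),
                             array(rnorm(8 * 3 * 4), c(8, 3, 4)),
                             rnorm(8), 3)
  expect_equal(dim(z), c(10L, 8L))
  ## pointwise flop factor y^2 / x = 4/3 at 3:2
  base <- count_params_and_flops("pointwise", 4, 4, T_ = 30)$flops_per_T
  comp <- count_params_and_flops("pointwise", 8, 8, T_ = 10)$flops_per_T
  expect_equal(comp / base, 4 / 3)
})

test_that("identity initialization makes k-separable sub-blocks exact identities", {
  ## epsilon = 0: a single initialized k-separable conv is the identity map
  C <- 5L; k <- 3L
  spec0 <- identity_init_spec(epsilon = 0)
  cfg <- residual_block_config(C = C, depth = 9, repeats = 3, k = k,
                               x = 1, y = 1, compressed = TRUE)
  params <- init_block(cfg, spec0, seed = 4)
  ## extract the inner fat + depthwise pair and run it standalone
  fat <- params$main$layers[[2]]
  dw <- params$main$layers[[3]]
  x <- random_tc(24, C, seed = 5)
  y <- k_blueprint_separable_conv(x, fat_pointwise_params(fat$par$W, fat$par$B),
                                  depthwise_params(dw$par$W, dw$par$B, k))
  expect_equal(y, x, tolerance = 1e-14, ignore_attr = TRUE)

  ## whole compressed main branch with x = y = 1 and identity compress /
  ## decompress: every parameterized layer (compression, k-separable convs,
  ## pre-decompression depthwise, batch norms, decompression) is an exact
  ## identity, so the branch with the fixed activations skipped reproduces
  ## the input exactly
  params <- nanocallr:::restore_tree(params, list(
    `net.main.1.W` = array(diag(C), c(C, 1, C)), `net.main.1.B` = rep(0, C),
    `net.main.8.W` = array(diag(C), c(C, 1, C)), `net.main.8.B` = rep(0, C)))
  cur <- x
  for (l in params$main$layers)
    if (l$type != "swish") cur <- nanocallr:::layer_forward(l, cur)$y
  expect_identical(cur, x)
  ## with the skip branch zeroed the block reduces to its main branch plus
  ## the final activation
  params$skip <- nanocallr:::map_params(params$skip, NULL,
                                        function(w, g, key) 0 * w)
  main_out <- nanocallr:::layer_forward(params$main, x)$y
  expect_equal(residual_block_compressed(x, cfg, params), swish(main_out),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identity init with noise keeps off-centre slices zero and centre near identity", {
  spec <- identity_init_spec(epsilon = 0.02)
  cfg <- residual_block_config(C = 6, depth = 27, repeats = 3, k = 3,
                               compressed = TRUE)
  params <- init_block(cfg, spec, seed = 7)
  fat <- params$main$layers[[2]]$par$W     # (Cy, k, Cy)
  expect_true(all(fat[, 1, ] == 0))
  expect_true(all(fat[, 3, ] == 0))
  expect_lte(max(abs(fat[, 2, ] - diag(dim(fat)[1]))), 0.02)
  dw <- params$main$layers[[3]]$par$W
  expect_true(all(dw[2, ] == 1))
  expect_true(all(dw[-2, ] == 0))
  ## reproducible: same seed, bitwise-identical parameters
  params2 <- init_block(cfg, spec, seed = 7)
  expect_identical(nanocallr:::collect_params(params),
                   nanocallr:::collect_params(params2))
  ## re-initialization via identity_init is equivalent
  params3 <- identity_init(init_block(cfg, identity_init_spec(0), seed = 1),
                           spec, seed = 7)
  expect_identical(nanocallr:::collect_params(params3),
                   nanocallr:::collect_params(params))
})

test_that("Glorot fallback respects the sqrt(6 / (Cin + Cout)) bound", {
  spec <- identity_init_spec(depthwise = FALSE, fat_pointwise = FALSE)
  cfg <- residual_block_config(C = 8, depth = 9, repeats = 4, k = 3,
                               compressed = TRUE)
  params <- init_block(cfg, spec, seed = 8)
  flat <- nanocallr:::collect_params(params)
  for (key in names(flat)) {
    w <- flat[[key]]
    if (grepl("\\.B$|beta|gamma", key)) next
    d <- dim(w)
    bound <- if (length(d) == 3) sqrt(6 / (d[3] + d[1]))
             else if (is.null(d) || length(d) < 2) Inf
             else if (grepl("skip", key)) sqrt(6 / (d[2] + d[1]))
             else sqrt(6 / (2 * d[2]))   # depthwise: Cin = Cout = C
    expect_lte(max(abs(w)), bound + 1e-12)
  }
})
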