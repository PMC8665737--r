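test_that("read accuracy matches its worked examples and floors at zero", {
  expect_equal(read_accuracy("ACGT", "ACGT"), 1.0)
  expect_equal(read_accuracy("ACGT", "AGT"), 0.75)
  expect_equal(read_accuracy("AAAA", "TTTT"), 0.0)
  expect_true(is.na(read_accuracy("", "ACGT")))
  ## denominator is the call length, not the reference length
  expect_equal(read_accuracy("AC", "ACGTACGT"), 0)   # distance 6 > |call|
  expect_equal(read_accuracy("ACGTAC", "ACGT"), 1 - 2 / 6)
})

test_that("read accuracy agrees with an independent DP edit distance on 1000 pairs", {
  set.seed(1)
  for (i in 1:1000) {
    a <- random_sequence(sample(1:12, 1), seed = 2 * i)
    b <- random_sequence(sample(0:12, 1), seed = 2 * i + 1)
    if (nchar(a) == 0) next
    expect_equal(read_accuracy(a, b),
                 max(0, 1 - oracle_edit_distance(a, b) / nchar(a)))
  }
})

test_that("accuracy report computes median over mapped reads and mapped fraction", {
  rep_ <- accuracy_report(c("ACGT", "", "AGT"), c("ACGT", "ACGT", "ACT"))
  expect_equal(rep_$mapped_fraction, 2 / 3)
  expect_equal(rep_$median, stats::median(c(1, 1 - 1 / 3)))
  expect_true(all(rep_$per_read >= 0 & rep_$per_read <= 1, na.rm = TRUE))
})

## a deliberately tiny architecture keeps the training tests fast
tiny_cfg <- function() {
  cfg <- model_config("small")
  cfg$blocks <- list(
    list(type = "c", cin = 1L, cout = 12L, depth = 9L, stride = 3L,
         conv = "full"),
    list(type = "res", channels = 12L, depth = 27L, repeats = 3L,
         compressed = TRUE),
    list(type = "c", cin = 12L, cout = 12L, depth = 9L, stride = 1L,
         conv = "separable"),
    list(type = "decoder", cin = 12L))
  cfg
}

test_that("one training step with zero learning rate leaves parameters unchanged", {
  reads <- simulate_dataset(12, c(60, 80), pore_model(), seed = 2)
  fit <- train_basecaller(reads, tiny_cfg(),
                          train_config(lr = 0, steps = 1L, batch_size = 2L,
                                       seed = 3L))
  ref <- build_model(fit$model_config, identity_init_spec(0.02), seed = 3L)
  expect_equal(nanocallr:::collect_params(fit$model$net),
               nanocallr:::collect_params(ref$net), tolerance = 1e-12)
})

test_that("identity-initialized model starts with finite loss and near-uniform posteriors", {
  reads <- simulate_dataset(6, c(60, 80), pore_model(), seed = 4)
  m <- build_model(tiny_cfg(), identity_init_spec(0.02), seed = 5)
  post <- forward_signal(m, normalize_signal(reads[[1]]$signal))
  ## decoder is Glorot-initialized with small weights: no frame is confident
  ## and the average posterior stays close to uniform
  expect_lt(max(apply(post, 1, max)), 0.9)
  expect_lt(max(abs(colMeans(post) - 0.2)), 0.25)
  lp <- forward_signal(m, normalize_signal(reads[[1]]$signal), log = TRUE)
  nll <- ctc_loss(lp, reads[[1]]$sequence)$neg_log_prob
  expect_true(is.finite(nll))
})

test_that("a short training run reduces the CTC loss on the default task", {
  reads <- simulate_dataset(40, c(60, 100), pore_model(), seed = 6)
  fit <- train_basecaller(reads, tiny_cfg(),
                          train_config(steps = 25L, batch_size = 8L,
                                       seed = 7L))
  first <- mean(fit$loss_curve[1:5])
  last <- mean(utils::tail(fit$loss_curve, 5))
  expect_lt(last, first)
  expect_true(all(is.finite(fit$loss_curve)))
})

test_that("ablation machinery is deterministic (A/A) and reports n_seeds per arm", {
  reads <- simulate_dataset(16, c(60, 80), pore_model(), seed = 8)
  cfg <- train_config(steps = 3L, batch_size = 4L, seed = 9L)
  ab <- ablation_identity_init(reads, tiny_cfg(), cfg, n_seeds = 2L)
  expect_length(ab$identity, 2L)
  expect_length(ab$glorot, 2L)
  ## identical seeds and init give identical results
  run1 <- train_basecaller(reads, tiny_cfg(), cfg)
  run2 <- train_basecaller(reads, tiny_cfg(), cfg)
  expect_identical(run1$loss_curve, run2$loss_curve)
  expect_identical(run1$heldout$median, run2$heldout$median)
})

test_that("boundary channel of all zeros matches the baseline loss at initialization", {
  reads <- simulate_dataset(6, c(60, 80), pore_model(), seed = 10)
  cfg2 <- tiny_cfg(); cfg2$in_channels <- 2L; cfg2$blocks[[1]]$cin <- 2L
  m2 <- build_model(cfg2, identity_init_spec(0.02), seed = 11)
  r <- reads[[1]]
  x2 <- cbind(normalize_signal(r$signal), 0)
  ## compare against an identically-seeded 1-channel model whose first-layer
  ## kernel equals the signal slice of the 2-channel model
  lp2 <- forward_signal(m2, x2, log = TRUE)
  m1 <- m2
  m1$cfg$in_channels <- 1L
  m1$cfg$blocks[[1]]$cin <- 1L
  W2 <- m2$net$layers[[1]]$layers[[1]]$par$W
  m1$net$layers[[1]]$layers[[1]]$par$W <- W2[, , 1, drop = FALSE]
  lp1 <- forward_signal(m1, matrix(x2[, 1], ncol = 1), log = TRUE)
  expect_equal(lp1, lp2, tolerance = 1e-12)
})

test_that("purine probe separates on ground-truth events and collapses under shuffling", {
  reads <- simulate_dataset(20, c(100, 150), pore_model(), seed = 12)
  res <- experiment_purine_probe(reads, seed = 13)
  expect_gte(res$accuracy, 0.9)
  null <- experiment_purine_probe(reads, seed = 13, shuffle_labels = TRUE)
  n_test <- null$n_events - null$n_events %/% 2
  expect_lt(abs(null$accuracy - 0.5), 3 * sqrt(0.25 / n_test) + 0.02)
  ## noiseless simulator: perfectly separable by construction
  clean <- simulate_dataset(10, c(100, 120), pore_model(noise_sd = 1e-6),
                            seed = 14)
  expect_equal(experiment_purine_probe(clean, seed = 15)$accuracy, 1.0,
               tolerance = 0.02)
  one_class <- list(simulate_squiggle(strrep("A", 30),
                                      pore_model(context_length = 5),
                                      seed = 16))
  expect_error(experiment_purine_probe(one_class), "single-class")
})

test_that("training loss decreases in moving average on the default task", {
  reads <- simulate_dataset(40, c(60, 100), pore_model(), seed = 17)
  fit <- train_basecaller(reads, tiny_cfg(),
                          train_config(steps = 30L, batch_size = 8L,
                                       seed = 18L))
  w <- 10L
  ma <- stats::filter(fit$loss_curve, rep(1 / w, w), sides = 1)
  ma <- ma[!is.na(ma)]
  ## overall downward trend of the smoothed curve
  expect_lt(utils::tail(ma, 1), ma[1])
})
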